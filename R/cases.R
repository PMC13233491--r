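# Seeded stratified generator of structured dosing scenarios.

#' Generation configuration
#'
#' Study-design parameters of the synthetic scenario set: 100 cases per
#' stratum (subtherapeutic / therapeutic / supratherapeutic), troughs on a
#' 0.1 ng/mL grid spanning 2.5-15.4 ng/mL, total daily doses on a 0.5-mg
#' grid from 1.0 to 12.0 mg/day, scenarios repeated one to five times, and
#' 12 out-of-protocol cases (target 10-12 ng/mL) included for exclusion
#' testing. Out-of-protocol cases count toward their stratum, allocated
#' 10 below / 0 within / 2 above so the retained set stratifies 90/100/98.
#'
#' @param n_per_stratum cases per stratum (default 100 each).
#' @param trough_bounds ng/mL pair, inclusive (default `c(2.5, 15.4)`).
#' @param trough_step trough grid resolution in ng/mL (default 0.1).
#' @param tdd_choices mg/day grid for current total daily dose.
#' @param repeat_distribution named or plain probability vector over
#'   repetition counts 1..5. The default weights singleton scenarios at
#'   0.56 so that roughly 211 of the 288 retained instances belong to
#'   repeated scenarios.
#' @param n_out_of_protocol number of cases carrying the unsupported
#'   target range (default 12).
#' @param out_of_protocol_range the unsupported range (default 10-12).
#' @param out_of_protocol_strata allocation of the out-of-protocol cases
#'   across strata, named `below`/`within`/`above`.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#' @return list of class `generation_config`.
#' @export
generation_config <- function(n_per_stratum = c(below = 100, within = 100,
                                                above = 100),
                              trough_bounds = c(2.5, 15.4),
                              trough_step = 0.1,
                              tdd_choices = seq(1, 12, by = 0.5),
                              repeat_distribution = c(0.56, 0.11, 0.11,
                                                      0.11, 0.11),
                              n_out_of_protocol = 12,
                              out_of_protocol_range = target_range(10, 12),
                              out_of_protocol_strata = c(below = 10,
                                                         within = 0,
                                                         above = 2),
                              seed = NULL) {
  if (length(n_per_stratum) == 1)
    n_per_stratum <- c(below = n_per_stratum, within = n_per_stratum,
                       above = n_per_stratum)
  stopifnot(all(n_per_stratum >= 0), n_out_of_protocol >= 0,
            trough_bounds[1] > 0, trough_bounds[1] < trough_bounds[2],
            trough_step > 0, all(tdd_choices > 0),
            length(repeat_distribution) == 5,
            all(repeat_distribution >= 0), sum(repeat_distribution) > 0)
  if (n_out_of_protocol != sum(out_of_protocol_strata))
    stop("out_of_protocol_strata must allocate exactly n_out_of_protocol cases")
  stopifnot(all(out_of_protocol_strata <= n_per_stratum))
  structure(list(n_per_stratum = n_per_stratum,
                 trough_bounds = trough_bounds, trough_step = trough_step,
                 tdd_choices = tdd_choices,
                 repeat_distribution = repeat_distribution /
                   sum(repeat_distribution),
                 n_out_of_protocol = n_out_of_protocol,
                 out_of_protocol_range = out_of_protocol_range,
                 out_of_protocol_strata = out_of_protocol_strata,
                 seed = seed),
            class = "generation_config")
}

# trough grid (ng/mL, on the configured step) for one stratum of one range
stratum_grid <- function(stratum, range, config) {
  s <- round(config$trough_step * 10)
  lo <- round(config$trough_bounds[1] * 10)
  hi <- round(config$trough_bounds[2] * 10)
  rl <- round(range$low * 10); rh <- round(range$high * 10)
  g <- switch(stratum,
              below = if (rl - s >= lo) seq(lo, rl - s, by = s) else integer(0),
              within = seq(max(lo, rl), min(hi, rh), by = s),
              above = if (rh + s <= hi) seq(rh + s, hi, by = s) else integer(0))
  g / 10
}

#' Generate a synthetic case set
#'
#' Draws a stratified, seeded set of dosing scenarios. Within each stratum,
#' scenario repetition counts are drawn from `repeat_distribution` until
#' the stratum quota is filled (the last scenario is truncated to fit);
#' each scenario samples a supported target range uniformly, a trough
#' uniformly on the grid of the stratum-appropriate interval for that
#' range, and a total daily dose uniformly from `tdd_choices`. Repeated
#' instances of a scenario are exact copies of the (trough, dose, range)
#' triple. Out-of-protocol cases are singleton scenarios carrying the
#' unsupported range. In the supratherapeutic stratum the generator
#' guarantees, when feasible, at least one case at/above and one below the
#' hold threshold so both the hold and the percentage-decrease paths are
#' exercised. Case order is a seeded shuffle of all strata.
#'
#' @param config a [generation_config()].
#' @param protocol protocol whose supported ranges the scenarios use.
#' @return a `case_set`: data.frame with columns `case_id`, `scenario_key`,
#'   `trough_ng_ml`, `current_tdd_mg`, `target_low`, `target_high`,
#'   `stratum`, with the config and seed attached as attributes.
#' @examples
#' cs <- generate_cases(generation_config(seed = 1))
#' table(cs$stratum)
#' @export
generate_cases <- function(config = generation_config(),
                           protocol = default_protocol()) {
  with_seed(config$seed, {
    rows <- list()
    for (stratum in c("below", "within", "above")) {
      n_total <- config$n_per_stratum[[stratum]]
      n_oop <- config$out_of_protocol_strata[[stratum]]
      n_supp <- n_total - n_oop
      grids <- lapply(protocol$ranges, stratum_grid, stratum = stratum,
                      config = config)
      usable <- names(grids)[vapply(grids, length, 0L) > 0]
      if (n_supp > 0 && length(usable) == 0)
        stop("configuration error: no admissible trough interval for the ",
             stratum, " stratum")
      filled <- 0; s_idx <- 0
      while (filled < n_supp) {
        s_idx <- s_idx + 1
        k <- sample.int(5, 1, prob = config$repeat_distribution)
        k <- min(k, n_supp - filled)
        key <- names(grids)[sample.int(length(grids), 1)]
        while (!key %in% usable)
          key <- names(grids)[sample.int(length(grids), 1)]
        range <- protocol$ranges[[key]]
        trough <- grids[[key]][sample.int(length(grids[[key]]), 1)]
        tdd <- config$tdd_choices[sample.int(length(config$tdd_choices), 1)]
        rows[[length(rows) + 1]] <- data.frame(
          scenario_key = sprintf("S-%s-%03d", stratum, s_idx),
          trough_ng_ml = rep(trough, k), current_tdd_mg = tdd,
          target_low = range$low, target_high = range$high,
          stratum = stratum)
        filled <- filled + k
      }
      if (n_oop > 0) {
        oor <- config$out_of_protocol_range
        g <- stratum_grid(stratum, oor, config)
        if (length(g) == 0)
          stop("configuration error: no admissible trough interval for ",
               "out-of-protocol cases in the ", stratum, " stratum")
        for (j in seq_len(n_oop)) {
          rows[[length(rows) + 1]] <- data.frame(
            scenario_key = sprintf("S-%s-oop-%03d", stratum, j),
            trough_ng_ml = g[sample.int(length(g), 1)],
            current_tdd_mg = config$tdd_choices[
              sample.int(length(config$tdd_choices), 1)],
            target_low = oor$low, target_high = oor$high, stratum = stratum)
        }
      }
    }
    cases <- do.call(rbind, rows)
    if (is.null(cases))
      return(structure(
        cbind(case_id = character(0),
              data.frame(scenario_key = character(0),
                         trough_ng_ml = numeric(0),
                         current_tdd_mg = numeric(0),
                         target_low = numeric(0), target_high = numeric(0),
                         stratum = character(0))),
        config = config, seed = config$seed,
        class = c("case_set", "data.frame")))

    # guarantee both decrease and hold paths in the above stratum
    supp <- !grepl("-oop-", cases$scenario_key)
    above <- which(cases$stratum == "above" & supp)
    if (length(above) > 0) {
      thr <- protocol$hold_thresholds[
        sprintf("%s-%s", num_chr(cases$target_low[above]),
                num_chr(cases$target_high[above]))]
      is_hold <- cases$trough_ng_ml[above] >= thr - .DOSE_TOL
      retarget <- function(idx, want_hold) {
        key <- sprintf("%s-%s", num_chr(cases$target_low[idx]),
                       num_chr(cases$target_high[idx]))
        g <- stratum_grid("above", protocol$ranges[[key]], config)
        g <- if (want_hold) g[g >= protocol$hold_thresholds[[key]] - .DOSE_TOL]
        else g[g < protocol$hold_thresholds[[key]] - .DOSE_TOL]
        if (length(g) > 0) {
          sel <- cases$scenario_key == cases$scenario_key[idx]
          cases$trough_ng_ml[sel] <<- g[sample.int(length(g), 1)]
        }
      }
      hold_feasible <- any(vapply(protocol$ranges, function(r) {
        g <- stratum_grid("above", r, config)
        any(g >= protocol$hold_thresholds[[range_key(r)]] - .DOSE_TOL)
      }, TRUE))
      if (!any(is_hold) && hold_feasible) {
        # move the last above scenario onto a range where a hold is possible
        idx <- above[length(above)]
        key <- names(protocol$ranges)[vapply(protocol$ranges, function(r) {
          g <- stratum_grid("above", r, config)
          any(g >= protocol$hold_thresholds[[range_key(r)]] - .DOSE_TOL)
        }, TRUE)][1]
        sel <- cases$scenario_key == cases$scenario_key[idx]
        cases$target_low[sel] <- protocol$ranges[[key]]$low
        cases$target_high[sel] <- protocol$ranges[[key]]$high
        retarget(idx, want_hold = TRUE)
      }
      if (all(is_hold)) retarget(above[1], want_hold = FALSE)
    }

    cases <- cases[sample.int(nrow(cases)), , drop = FALSE]
    cases <- cbind(case_id = sprintf("C%04d", seq_len(nrow(cases))), cases)
    rownames(cases) <- NULL
    structure(cases, config = config, seed = config$seed,
              class = c("case_set", "data.frame"))
  })
}

#' Split a case set into protocol-supported and excluded cases
#'
#' Cases whose target range the protocol does not support carry no dosing
#' guidance and are excluded from analysis; under the default study design
#' 12 of the 300 generated cases carry the 10-12 ng/mL range, leaving 288
#' retained.
#'
#' @param cases a `case_set` (or compatible data.frame).
#' @param protocol a [tac_protocol()].
#' @return list with `retained` and `excluded` case sets (input order
#'   preserved in each).
#' @export
filter_supported <- function(cases, protocol) {
  keys <- sprintf("%s-%s", num_chr(cases$target_low),
                  num_chr(cases$target_high))
  ok <- keys %in% names(protocol$ranges)
  list(retained = cases[ok, , drop = FALSE],
       excluded = cases[!ok, , drop = FALSE])
}

#' Group case ids by scenario
#'
#' @param cases a `case_set`.
#' @return named list mapping `scenario_key` to the character vector of
#'   `case_id`s of its instances (sizes 1..5); the groups partition the
#'   case set.
#' @export
repetition_groups <- function(cases) {
  split(cases$case_id, cases$scenario_key)
}

#' Read / write case sets as CSV
#'
#' Cases round-trip through a plain CSV with a `# seed:` metadata header
#' line recording the generation seed.
#'
#' @param cases a `case_set`.
#' @param path CSV file path.
#' @return `read_cases()` returns the case data.frame (seed in
#'   `attr(, "seed")`); `write_cases()` returns `path` invisibly.
#' @export
write_cases <- function(cases, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cases, "seed")
  writeLines(sprintf("# seed: %s", if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(as.data.frame(cases), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  first <- readLines(path, n = 1)
  seed <- if (grepl("^# seed:", first)) {
    v <- trimws(sub("^# seed:", "", first))
    if (v == "NA") NULL else as.integer(v)
  } else NULL
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(case_id = "character",
                                       scenario_key = "character"))
  structure(df, seed = seed, class = c("case_set", "data.frame"))
}
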