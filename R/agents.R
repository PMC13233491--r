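# Recommendation sources standing in for the language model: a perfect
# protocol oracle, a seeded error-injecting agent, and the five-field
# structured output formatter/parser.

.OUT_FIELDS <- c("case_id", "reported_tdd", "action", "pct_low", "pct_high",
                 "range_low", "range_high", "final_tdd", "am_dose", "pm_dose",
                 "recheck_low", "recheck_high", "parse_status")

empty_output <- function(case_id = NA_character_,
                         parse_status = "missing") {
  data.frame(case_id = case_id, reported_tdd = NA_real_,
             action = NA_character_, pct_low = NA_real_, pct_high = NA_real_,
             range_low = NA_real_, range_high = NA_real_,
             final_tdd = NA_real_, am_dose = NA_real_, pm_dose = NA_real_,
             recheck_low = NA_real_, recheck_high = NA_real_,
             parse_status = parse_status)
}

rec_to_output <- function(rec, case) {
  out <- empty_output(case$case_id, parse_status = "complete")
  out$reported_tdd <- case$current_tdd_mg
  for (f in c("action", "pct_low", "pct_high", "range_low", "range_high",
              "final_tdd", "am_dose", "pm_dose", "recheck_low",
              "recheck_high"))
    out[[f]] <- rec[[f]]
  out
}

#' Error-injection profile
#'
#' Per-error-type probabilities used by [error_injecting_agent()] to
#' perturb the oracle answer, emulating the error classes of the
#' evaluation taxonomy. Each probability applies independently per case,
#' except that at most one sentinel-class perturbation is applied per
#' output (priority hold-omission > directional flip > excessive dose >
#' categorization) so the hierarchical primary category stays predictable;
#' lower-severity perturbations may co-occur.
#'
#' @param p_directional flip the adjustment direction.
#' @param p_hold_omit replace a mandated hold with a percentage decrease.
#' @param p_categorization misreport the action class.
#' @param p_excessive scale the final dose beyond doubling / below halving.
#' @param p_percent shift the reported percentage interval off-band.
#' @param p_range shift the reported dose range.
#' @param p_rounding push the final dose just outside the dose range.
#' @param p_split corrupt the AM/PM split.
#' @param p_missing blank required fields (incomplete output).
#' @param seed optional seed applied by [run_agent()] for the whole run.
#' @return list of class `error_profile`.
#' @seealso [phase1_profile()], [phase2_profile()], [zero_profile()]
#' @export
error_profile <- function(p_directional = 0, p_hold_omit = 0,
                          p_categorization = 0, p_excessive = 0,
                          p_percent = 0, p_range = 0, p_rounding = 0,
                          p_split = 0, p_missing = 0, seed = NULL) {
  p <- c(p_directional = p_directional, p_hold_omit = p_hold_omit,
         p_categorization = p_categorization, p_excessive = p_excessive,
         p_percent = p_percent, p_range = p_range, p_rounding = p_rounding,
         p_split = p_split, p_missing = p_missing)
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(p = p, seed = seed), class = "error_profile")
}

#' @rdname error_profile
#' @details `zero_profile()` injects nothing (agent output equals the
#'   oracle); `phase1_profile()` and `phase2_profile()` are illustrative
#'   presets whose expected granular error rates approximate a noisier
#'   baseline agent and a refined agent respectively. They characterize
#'   the grader and report plumbing, not any particular language model.
#' @export
zero_profile <- function(seed = NULL) error_profile(seed = seed)

#' @rdname error_profile
#' @export
phase1_profile <- function(seed = NULL) {
  error_profile(p_directional = 0.056, p_hold_omit = 0.40,
                p_categorization = 0.055, p_excessive = 0.069,
                p_percent = 0.139, p_range = 0.08, p_rounding = 0.024,
                p_split = 0.003, p_missing = 0.08, seed = seed)
}

#' @rdname error_profile
#' @export
phase2_profile <- function(seed = NULL) {
  error_profile(p_directional = 0, p_hold_omit = 0.07,
                p_categorization = 0.007, p_excessive = 0.004,
                p_percent = 0.024, p_range = 0.024, p_rounding = 0.111,
                p_split = 0.01, p_missing = 0.031, seed = seed)
}

#' Oracle agent
#'
#' Faithful serialization of the protocol recommendation for one case: the
#' reference answer source every output is graded against.
#'
#' @param case one-row case data.frame.
#' @param protocol a [tac_protocol()].
#' @return one-row structured-output data.frame, `parse_status`
#'   `"complete"`.
#' @export
oracle_agent <- function(case, protocol) {
  rec_to_output(recommend(case = case, protocol = protocol), case)
}

#' Error-injecting agent
#'
#' Starts from the oracle answer and applies seeded perturbations per the
#' profile probabilities (see [error_profile()] for the catalogue and the
#' sentinel-priority rule). Draws are consumed in a fixed order so runs
#' are reproducible instance-by-instance under a fixed seed.
#'
#' @inheritParams oracle_agent
#' @param profile an [error_profile()].
#' @return one-row structured-output data.frame.
#' @export
error_injecting_agent <- function(case, protocol, profile) {
  out <- oracle_agent(case, protocol)
  p <- profile$p
  u <- stats::runif(10)          # 9 error draws + 1 auxiliary choice draw
  names(u) <- c(names(p), "aux")
  inc <- protocol$dose_increment
  tdd <- case$current_tdd_mg

  is_adj <- function(a) a %in% c("increase", "decrease")
  resplit <- function(out) {
    sp <- split_bid(out$final_tdd, inc)
    out$am_dose <- sp[["am"]]; out$pm_dose <- sp[["pm"]]
    out
  }
  apply_band <- function(out, direction, p_low, p_high) {
    out$action <- direction
    out$pct_low <- p_low; out$pct_high <- p_high
    dr <- compute_dose_range(tdd, data.frame(direction = direction,
                                             p_low = p_low, p_high = p_high))
    out$range_low <- dr$low; out$range_high <- dr$high
    out$final_tdd <- choose_final_dose(dr, inc, protocol$adherence_margin)
    out$recheck_low <- NA_real_; out$recheck_high <- NA_real_
    resplit(out)
  }

  # at most one sentinel-class perturbation, by severity priority
  if (u[["p_hold_omit"]] < p[["p_hold_omit"]] && out$action == "hold") {
    b <- if (u[["aux"]] < 0.5) c(0.20, 0.30) else c(0.30, 0.40)
    out <- apply_band(out, "decrease", b[1], b[2])
  } else if (u[["p_directional"]] < p[["p_directional"]] &&
             is_adj(out$action)) {
    flip <- if (out$action == "increase") "decrease" else "increase"
    out <- apply_band(out, flip, out$pct_low, out$pct_high)
  } else if (u[["p_excessive"]] < p[["p_excessive"]] && is_adj(out$action)) {
    fac <- if (out$action == "increase") 2.5 else 0.3
    out$final_tdd <- round_to_increment(fac * tdd, inc)
    out <- resplit(out)
  } else if (u[["p_categorization"]] < p[["p_categorization"]] &&
             out$action != "hold") {
    if (is_adj(out$action)) {
      out$action <- "maintain"
      out$pct_low <- NA_real_; out$pct_high <- NA_real_
      out$range_low <- NA_real_; out$range_high <- NA_real_
    } else {
      out$action <- "increase"
    }
  }

  if (u[["p_percent"]] < p[["p_percent"]] && !is.na(out$pct_low)) {
    out$pct_low <- out$pct_low + 0.1
    out$pct_high <- out$pct_high + 0.1
  }
  if (u[["p_range"]] < p[["p_range"]] && !is.na(out$range_low)) {
    out$range_low <- out$range_low + inc
    out$range_high <- out$range_high + inc
  }
  if (u[["p_rounding"]] < p[["p_rounding"]] && is_adj(out$action) &&
      !is.na(out$range_high) && !is.na(out$final_tdd)) {
    out$final_tdd <- (floor(out$range_high / inc + .FRAC_TOL) + 1) * inc
    out <- resplit(out)
  }
  if (u[["p_split"]] < p[["p_split"]] && !is.na(out$am_dose)) {
    out$am_dose <- out$am_dose + inc
  }
  if (u[["p_missing"]] < p[["p_missing"]]) {
    out$final_tdd <- NA_real_
    out$am_dose <- NA_real_; out$pm_dose <- NA_real_
    out$parse_status <- "incomplete"
  }
  out
}

#' Run an agent over a case set
#'
#' @param cases a `case_set` (supported cases only).
#' @param protocol a [tac_protocol()].
#' @param agent `"oracle"`, an [error_profile()], or a function
#'   `(case, protocol) -> structured output` for external adapters.
#' @param seed seed for the whole run (defaults to the profile's own seed
#'   when the agent is a profile).
#' @return data.frame of structured outputs, one row per case, in case
#'   order.
#' @export
run_agent <- function(cases, protocol, agent = "oracle", seed = NULL) {
  fn <- if (identical(agent, "oracle")) {
    oracle_agent
  } else if (inherits(agent, "error_profile")) {
    if (is.null(seed)) seed <- agent$seed
    function(case, protocol) error_injecting_agent(case, protocol, agent)
  } else if (is.function(agent)) {
    agent
  } else stop("agent must be \"oracle\", an error_profile, or a function")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cases)),
                   function(i) fn(cases[i, , drop = FALSE], protocol))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# ---- structured five-field text format ------------------------------------

#' Format a structured output as text
#'
#' Canonical line-oriented template with the five reported fields in
#' protocol order: current total daily dose, percentage adjustment,
#' adjustment range, final total daily dose, and AM/PM split (a hold
#' replaces the dose fields with a hold/recheck marker).
#'
#' @param out one-row structured output with `parse_status == "complete"`.
#' @return single string (lines joined by `"\n"`).
#' @export
format_output <- function(out) {
  if (!identical(out$parse_status, "complete"))
    stop("cannot format an incomplete output")
  lines <- c(sprintf("current total daily dose: %s mg",
                     num_chr(out$reported_tdd)),
             sprintf("action: %s", out$action))
  if (out$action == "hold") {
    lines <- c(lines,
               "percentage adjustment: none (hold)",
               "dose range: none (hold)",
               sprintf("final total daily dose: hold one dose; recheck trough in %s-%s h",
                       num_chr(out$recheck_low), num_chr(out$recheck_high)),
               "AM/PM split: none (hold)")
  } else {
    pct <- if (is.na(out$pct_low)) "0% (no change)" else
      sprintf("%s-%s%%", num_chr(100 * out$pct_low),
              num_chr(100 * out$pct_high))
    rng <- if (is.na(out$range_low)) "none" else
      sprintf("%s-%s mg", num_chr(out$range_low), num_chr(out$range_high))
    lines <- c(lines,
               sprintf("percentage adjustment: %s", pct),
               sprintf("dose range: %s", rng),
               sprintf("final total daily dose: %s mg",
                       num_chr(out$final_tdd)),
               sprintf("AM/PM split: %s mg / %s mg",
                       num_chr(out$am_dose), num_chr(out$pm_dose)))
  }
  paste(lines, collapse = "\n")
}

.parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Parse structured output text
#'
#' Tolerant inverse of [format_output()]: never raises on bad input.
#' Missing text yields `parse_status = "missing"`, unparseable numerics
#' `"malformed"`, absent required fields `"incomplete"`, otherwise
#' `"complete"` with all values preserved.
#'
#' @param text raw agent text (single string; may be multi-line).
#' @param case_id id to attach to the parsed record.
#' @return one-row structured-output data.frame.
#' @export
parse_output <- function(text, case_id = NA_character_) {
  out <- empty_output(case_id)
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    return(out)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  grab <- function(prefix) {
    hit <- grep(paste0("^\\s*", prefix, "\\s*:"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    trimws(sub("^[^:]*:", "", hit[1]))
  }
  malformed <- FALSE
  need_num <- function(s) {
    v <- .parse_num(s)
    if (!is.na(s) && is.na(v)) malformed <<- TRUE
    v
  }
  tdd_s <- grab("current total daily dose")
  out$reported_tdd <- need_num(sub("\\s*mg.*$", "", tdd_s))
  action <- grab("action")
  if (!is.na(action) && action %in% c("maintain", "increase", "decrease",
                                      "hold"))
    out$action <- action
  else if (!is.na(action)) malformed <- TRUE

  pct_s <- grab("percentage adjustment")
  rng_s <- grab("dose range")
  fin_s <- grab("final total daily dose")
  spl_s <- grab("AM/PM split")

  if (!is.na(out$action) && out$action == "hold") {
    m <- regmatches(fin_s, regexec(
      "recheck trough in\\s*([0-9.]+)\\s*-\\s*([0-9.]+)\\s*h", fin_s))[[1]]
    if (length(m) == 3) {
      out$recheck_low <- need_num(m[2]); out$recheck_high <- need_num(m[3])
    }
    required <- c(out$reported_tdd, out$recheck_low, out$recheck_high)
    out$parse_status <- if (malformed) "malformed"
    else if (anyNA(required)) "incomplete" else "complete"
    return(out)
  }

  if (!is.na(pct_s) && !grepl("no change|none", pct_s)) {
    m <- regmatches(pct_s, regexec(
      "([0-9.]+)\\s*-\\s*([0-9.]+)\\s*%", pct_s))[[1]]
    if (length(m) == 3) {
      out$pct_low <- need_num(m[2]) / 100
      out$pct_high <- need_num(m[3]) / 100
    } else malformed <- TRUE
  }
  if (!is.na(rng_s) && !grepl("^none", rng_s)) {
    m <- regmatches(rng_s, regexec(
      "(-?[0-9.]+)\\s*-\\s*(-?[0-9.]+)\\s*mg", rng_s))[[1]]
    if (length(m) == 3) {
      out$range_low <- need_num(m[2]); out$range_high <- need_num(m[3])
    } else malformed <- TRUE
  }
  if (!is.na(fin_s)) out$final_tdd <- need_num(sub("\\s*mg.*$", "", fin_s))
  if (!is.na(spl_s)) {
    m <- regmatches(spl_s, regexec(
      "([0-9.]+)\\s*mg\\s*/\\s*([0-9.]+)\\s*mg", spl_s))[[1]]
    if (length(m) == 3) {
      out$am_dose <- need_num(m[2]); out$pm_dose <- need_num(m[3])
    } else malformed <- TRUE
  }
  required <- list(out$reported_tdd, out$action, out$final_tdd,
                   out$am_dose, out$pm_dose)
  if (!is.na(out$action) && out$action %in% c("increase", "decrease"))
    required <- c(required, list(out$pct_low, out$range_low))
  out$parse_status <- if (malformed) "malformed"
  else if (any(vapply(required, function(v) length(v) == 0 || is.na(v), TRUE)))
    "incomplete" else "complete"
  out
}

#' Read / write agent transcripts
#'
#' Transcripts are JSONL records `{"case_id": ..., "raw_text": ...}`, the
#' interchange format for grading externally recorded agent outputs
#' offline.
#'
#' @param outputs structured-output data.frame (rows with
#'   `parse_status == "complete"` are serialized via [format_output()]).
#' @param path JSONL file path.
#' @return `read_transcripts()` returns a structured-output data.frame
#'   (one parsed row per record); `write_transcripts()` returns `path`
#'   invisibly.
#' @export
write_transcripts <- function(outputs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(outputs))) {
    row <- outputs[i, , drop = FALSE]
    txt <- if (identical(row$parse_status, "complete")) format_output(row)
    else ""
    writeLines(jsonlite::toJSON(list(case_id = row$case_id, raw_text = txt),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  out <- do.call(rbind, lapply(recs, function(r)
    parse_output(r$raw_text, case_id = r$case_id)))
  rownames(out) <- NULL
  out
}

#' Adapter for grading a pre-recorded transcript file
#'
#' Returns an agent function for [run_agent()] that looks cases up in a
#' transcript file instead of computing recommendations; cases absent from
#' the transcript grade as missing output.
#'
#' @param path JSONL transcript file (see [write_transcripts()]).
#' @return function `(case, protocol) -> structured output`.
#' @export
transcript_agent <- function(path) {
  parsed <- read_transcripts(path)
  function(case, protocol) {
    hit <- which(parsed$case_id == case$case_id)
    if (length(hit) == 0) return(empty_output(case$case_id))
    parsed[hit[1], , drop = FALSE]
  }
}
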