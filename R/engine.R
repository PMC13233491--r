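# Deterministic protocol engine: trough classification, band selection,
# dose-range arithmetic, hold override, increment rounding, BID splitting.

#' Classify a trough relative to its target range
#'
#' @param trough measured trough concentration (ng/mL), must be positive.
#' @param range a [target_range()].
#' @return `"below"`, `"within"` or `"above"`. Membership is inclusive at
#'   both bounds.
#' @examples
#' classify_trough(5.0, target_range(4, 6)) # "within"
#' classify_trough(6.0, target_range(4, 6)) # "within" (inclusive bound)
#' @export
classify_trough <- function(trough, range) {
  if (!is.numeric(trough) || length(trough) != 1 || is.na(trough) ||
      trough <= 0)
    stop("trough must be a positive concentration (ng/mL)")
  if (trough < range$low - .DOSE_TOL) "below"
  else if (trough > range$high + .DOSE_TOL) "above"
  else "within"
}

# Condition-based error so the exclusion filter can target it.
unsupported_target_error <- function(range) {
  structure(class = c("tacsim_unsupported_target", "error", "condition"),
            list(message = sprintf(
              "target range %s ng/mL is not supported by the protocol",
              range_key(range)), call = NULL))
}

#' Select the protocol action for a trough
#'
#' Applies the protocol decision rule: within-range troughs are maintained;
#' supratherapeutic troughs at or above the range's hold threshold mandate
#' a dose hold; every other out-of-range trough selects the unique
#' percentage band whose deviation interval contains the distance from the
#' violated target bound.
#'
#' @inheritParams classify_trough
#' @param protocol a [tac_protocol()].
#' @return `"maintain"`, `"hold"`, or a one-row data.frame (the matching
#'   adjustment band).
#' @examples
#' p <- default_protocol()
#' select_adjustment(15.4, target_range(8, 10), p) # "hold"
#' select_adjustment(5.0, target_range(6, 8), p)   # 10-20% increase band
#' @export
select_adjustment <- function(trough, range, protocol) {
  if (!range_key(range) %in% names(protocol$ranges))
    stop(unsupported_target_error(range))
  cls <- classify_trough(trough, range)
  if (cls == "within") return("maintain")
  if (cls == "above" &&
      trough >= protocol$hold_thresholds[[range_key(range)]] - .DOSE_TOL)
    return("hold")
  direction <- if (cls == "below") "increase" else "decrease"
  deviation <- if (cls == "below") range$low - trough else trough - range$high
  b <- protocol$bands
  hit <- b$direction == direction &
    deviation > b$dev_low + .DOSE_TOL &
    deviation <= b$dev_high + .DOSE_TOL
  if (sum(hit) != 1)
    stop("protocol configuration error: deviation ", deviation,
         " ng/mL matches ", sum(hit), " ", direction, " bands")
  b[hit, , drop = FALSE]
}

#' Percentage band applied to the total daily dose
#'
#' @param tdd current total daily dose (mg/day), positive.
#' @param band one-row adjustment band as returned by [select_adjustment()].
#' @return list with `low`, `high` (mg/day), the protocol-derived dose
#'   range.
#' @examples
#' b <- data.frame(direction = "increase", dev_low = 1, dev_high = 2,
#'                 p_low = 0.2, p_high = 0.3)
#' compute_dose_range(3.0, b) # [3.6, 3.9]
#' @export
compute_dose_range <- function(tdd, band) {
  stopifnot(is.numeric(tdd), length(tdd) == 1, tdd > 0)
  if (band$direction == "increase") {
    list(low = tdd * (1 + band$p_low), high = tdd * (1 + band$p_high))
  } else {
    list(low = tdd * (1 - band$p_high), high = tdd * (1 - band$p_low))
  }
}

#' Round a dose to the available increment
#'
#' Returns the multiple of `increment` nearest to `dose`; exact ties round
#' up (half-up convention, so 3.75 mg with 0.5-mg increments gives 4.0 mg).
#'
#' @param dose computed dose (mg), positive.
#' @param increment available dose step (mg), positive.
#' @return rounded dose in mg.
#' @examples
#' round_to_increment(4.8, 0.5) # 5.0
#' round_to_increment(3.6, 0.5) # 3.5
#' @export
round_to_increment <- function(dose, increment) {
  stopifnot(dose > 0, increment > 0)
  floor(dose / increment + 0.5 + .FRAC_TOL) * increment
}

#' Feasible discrete doses inside a dose range
#'
#' All multiples of `increment` lying in `[low, high]`; possibly empty
#' (narrow ranges can fall strictly between consecutive dose strengths).
#'
#' @param range list with `low`, `high` in mg.
#' @param increment dose step (mg).
#' @return increasing numeric vector (possibly length 0).
#' @examples
#' feasible_doses(list(low = 3.6, high = 3.9), 0.5) # numeric(0)
#' feasible_doses(list(low = 8.0, high = 9.0), 0.5) # 8.0 8.5 9.0
#' @export
feasible_doses <- function(range, increment) {
  stopifnot(range$low > 0, range$low <= range$high, increment > 0)
  k <- seq(ceiling(range$low / increment - .FRAC_TOL),
           floor(range$high / increment + .FRAC_TOL))
  k <- k[k * increment >= range$low - .DOSE_TOL &
           k * increment <= range$high + .DOSE_TOL]
  k * increment
}

#' Reference dose selection inside (or nearest to) a dose range
#'
#' Selection policy of the protocol oracle: if the range contains feasible
#' doses, take the one closest to the range midpoint (ties toward the lower
#' dose); otherwise take the increment multiple nearest to the midpoint
#' (again ties toward the lower dose), which is the within-margin dose when
#' one exists.
#'
#' @inheritParams feasible_doses
#' @param margin adherence margin in mg (recorded for documentation; the
#'   selection itself is margin-free).
#' @return chosen dose (mg).
#' @examples
#' choose_final_dose(list(low = 3.6, high = 3.9), 0.5, 0.1) # 3.5
#' @export
choose_final_dose <- function(range, increment, margin = 0.1) {
  mid <- (range$low + range$high) / 2
  cand <- feasible_doses(range, increment)
  if (length(cand) == 0)
    cand <- unique(c(floor(mid / increment + .FRAC_TOL),
                     ceiling(mid / increment - .FRAC_TOL),
                     floor(mid / increment + .FRAC_TOL) + 1)) * increment
  cand <- cand[cand > 0]
  d <- abs(cand - mid)
  best <- cand[d <= min(d) + .DOSE_TOL]
  min(best)
}

#' Split a total daily dose into twice-daily doses
#'
#' AM + PM always equals the total; the two doses differ by at most one
#' increment, and when they must differ the larger portion is placed in the
#' AM slot (fixed convention).
#'
#' @param tdd total daily dose (mg/day); must be a positive multiple of
#'   `increment`.
#' @param increment dose step (mg).
#' @return named numeric `c(am = , pm = )`.
#' @examples
#' split_bid(8.5, 0.5) # am 4.5, pm 4.0
#' @export
split_bid <- function(tdd, increment) {
  stopifnot(tdd > 0, increment > 0)
  k <- tdd / increment
  if (abs(k - round(k)) > .FRAC_TOL)
    stop("tdd ", tdd, " mg is not a multiple of the ", increment,
         " mg increment")
  am <- ceiling(round(k) / 2) * increment
  c(am = am, pm = tdd - am)
}

#' Protocol recommendation for one scenario
#'
#' Composes the full decision path: classify the trough, select the action
#' (maintain / hold / percentage band), derive the dose range, choose a
#' discrete final dose, and split it into AM/PM doses. A hold leaves the
#' maintenance dose unmodified (no dose range, no new total daily dose) and
#' carries the protocol recheck window.
#'
#' @param trough trough concentration (ng/mL).
#' @param tdd current total daily dose (mg/day).
#' @param range the case's [target_range()]; must be supported by
#'   `protocol`, otherwise an unsupported-target error is raised (the
#'   condition that drives case exclusion).
#' @param protocol a [tac_protocol()].
#' @param case alternative interface: a one-row case data.frame (as in a
#'   [generate_cases()] case set) supplying `trough_ng_ml`,
#'   `current_tdd_mg`, `target_low`, `target_high`.
#' @return object of class `protocol_rec`: list with `action`
#'   (`maintain`/`increase`/`decrease`/`hold`), `pct_low`/`pct_high`
#'   (fractions, NA for maintain/hold), `range_low`/`range_high` (mg, NA
#'   unless a band applies), `final_tdd`, `am_dose`, `pm_dose` (NA for
#'   hold), `recheck_low`/`recheck_high` (hours, hold only).
#' @examples
#' recommend(7.0, 8.0, target_range(6, 8), default_protocol())
#' @export
recommend <- function(trough, tdd, range, protocol, case = NULL) {
  if (!is.null(case)) {
    trough <- case$trough_ng_ml
    tdd <- case$current_tdd_mg
    range <- target_range(case$target_low, case$target_high)
  }
  sel <- select_adjustment(trough, range, protocol)
  rec <- list(action = NA_character_, pct_low = NA_real_, pct_high = NA_real_,
              range_low = NA_real_, range_high = NA_real_,
              final_tdd = NA_real_, am_dose = NA_real_, pm_dose = NA_real_,
              recheck_low = NA_real_, recheck_high = NA_real_)
  if (identical(sel, "hold")) {
    rec$action <- "hold"
    rec$recheck_low <- protocol$recheck_window[1]
    rec$recheck_high <- protocol$recheck_window[2]
  } else if (identical(sel, "maintain")) {
    rec$action <- "maintain"
    rec$final_tdd <- tdd
    sp <- split_bid(tdd, protocol$dose_increment)
    rec$am_dose <- sp[["am"]]; rec$pm_dose <- sp[["pm"]]
  } else {
    rec$action <- sel$direction
    rec$pct_low <- sel$p_low; rec$pct_high <- sel$p_high
    dr <- compute_dose_range(tdd, sel)
    rec$range_low <- dr$low; rec$range_high <- dr$high
    rec$final_tdd <- choose_final_dose(dr, protocol$dose_increment,
                                       protocol$adherence_margin)
    sp <- split_bid(rec$final_tdd, protocol$dose_increment)
    rec$am_dose <- sp[["am"]]; rec$pm_dose <- sp[["pm"]]
  }
  structure(rec, class = "protocol_rec")
}

#' @export
print.protocol_rec <- function(x, ...) {
  cat("protocol recommendation:", x$action, "\n")
  if (!is.na(x$pct_low))
    cat(sprintf("  adjust by %d-%d%% of TDD -> range %.2f-%.2f mg\n",
                round(100 * x$pct_low), round(100 * x$pct_high),
                x$range_low, x$range_high))
  if (!is.na(x$final_tdd))
    cat(sprintf("  final TDD %.1f mg (AM %.1f / PM %.1f)\n",
                x$final_tdd, x$am_dose, x$pm_dose))
  if (x$action == "hold")
    cat(sprintf("  hold one dose; recheck trough in %d-%d h\n",
                x$recheck_low, x$recheck_high))
  invisible(x)
}
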