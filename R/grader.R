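# Hierarchical grading of structured outputs against the protocol oracle:
# adherence judgment, granular error detection, severity-ranked primary
# category, and component-level final-dose accuracy.

#' Granular error taxonomy
#'
#' The eleven granular error types recorded by [detect_errors()], grouped
#' by severity class for [assign_primary()]: sentinel errors (holding,
#' directional, categorization, excessive dose), calculation/dosing errors
#' (incorrect dose, percentage, dosing range, rounding, calculation),
#' administration errors (AM/PM splitting) and missing-output/formatting
#' errors.
#'
#' @format character vector of error names.
#' @export
granular_errors <- function() {
  c("holding_error", "directional_error", "categorization_error",
    "excessive_dose", "incorrect_dose", "percentage_error",
    "dosing_range_error", "rounding_error", "calculation_error",
    "administration_error", "missing_or_format_error")
}

.SENTINEL <- c("holding_error", "directional_error", "categorization_error",
               "excessive_dose")
.CALC <- c("incorrect_dose", "percentage_error", "dosing_range_error",
           "rounding_error", "calculation_error")

# dose interval the final TDD must fall in (before the adherence margin):
# the protocol dose range for adjustments, the unchanged dose for maintain,
# nothing for a hold.
target_interval <- function(rec, case) {
  switch(rec$action,
         maintain = c(case$current_tdd_mg, case$current_tdd_mg),
         hold = NULL,
         c(rec$range_low, rec$range_high))
}

#' Judge protocol adherence of one output
#'
#' An output is adherent when it classifies the adjustment correctly
#' (increase / decrease / maintain, or recommends the mandated hold),
#' reports the protocol percentage band, and lands the final total daily
#' dose inside the protocol-derived dose range or within the clinically
#' insignificant rounding margin (default +-0.1 mg) of it.
#'
#' @param out one-row structured output.
#' @param rec the oracle [recommend()] answer for the same case.
#' @param case the one-row case.
#' @param protocol a [tac_protocol()].
#' @return logical.
#' @export
judge_adherence <- function(out, rec, case, protocol) {
  if (!identical(out$parse_status, "complete")) return(FALSE)
  if (rec$action == "hold") return(identical(out$action, "hold"))
  if (!identical(out$action, rec$action)) return(FALSE)
  if (rec$action %in% c("increase", "decrease")) {
    if (is.na(out$pct_low) || is.na(out$pct_high) ||
        abs(out$pct_low - rec$pct_low) > .FRAC_TOL ||
        abs(out$pct_high - rec$pct_high) > .FRAC_TOL) return(FALSE)
  }
  iv <- target_interval(rec, case)
  m <- protocol$adherence_margin
  !is.na(out$final_tdd) &&
    out$final_tdd >= iv[1] - m - .DOSE_TOL &&
    out$final_tdd <= iv[2] + m + .DOSE_TOL
}

#' Detect granular errors in one output
#'
#' Each detector fires independently of the others (an output can
#' contribute to several granular counts):
#' \describe{
#'   \item{holding_error}{a mandated hold not given, or a hold given when
#'     none is mandated.}
#'   \item{directional_error}{increase reported where the protocol
#'     decreases, or vice versa.}
#'   \item{categorization_error}{the action class differs from the
#'     protocol's.}
#'   \item{excessive_dose}{final dose beyond doubling or below halving the
#'     current dose, or an implied change exceeding twice the largest
#'     protocol percentage.}
#'   \item{percentage_error}{reported percentage interval differs from the
#'     protocol band (or a band is reported where none applies).}
#'   \item{dosing_range_error}{reported dose range differs from the
#'     protocol-derived range (or a range is reported where none
#'     applies).}
#'   \item{rounding_error}{direction, percentage and range all correct but
#'     the final dose falls outside the computed range - the discrete
#'     dose-increment artifact; it can coexist with adherence via the
#'     margin rule.}
#'   \item{incorrect_dose}{final dose outside the protocol range +- margin
#'     (or a recalculated dose reported for a mandated hold), regardless
#'     of cause - the component-level outcome.}
#'   \item{calculation_error}{final dose inconsistent with the output's own
#'     reported percentage applied to its reported current dose, beyond
#'     one rounding step (one increment).}
#'   \item{administration_error}{AM + PM doses not summing to the final
#'     dose, or differing by more than one increment.}
#'   \item{missing_or_format_error}{output absent, incomplete or
#'     structurally malformed.}
#' }
#' Detectors whose required fields are absent do not fire (the absence is
#' captured by `missing_or_format_error`).
#'
#' @inheritParams judge_adherence
#' @return character vector of fired error names (possibly empty).
#' @export
detect_errors <- function(out, rec, case, protocol) {
  errs <- character(0)
  fire <- function(e) errs <<- c(errs, e)
  inc <- protocol$dose_increment
  m <- protocol$adherence_margin
  tdd <- case$current_tdd_mg
  adj <- c("increase", "decrease")

  if (!identical(out$parse_status, "complete"))
    fire("missing_or_format_error")

  a <- out$action
  if (!is.na(a)) {
    if (xor(rec$action == "hold", a == "hold")) fire("holding_error")
    if (rec$action %in% adj && a %in% adj && a != rec$action)
      fire("directional_error")
    if (a != rec$action) fire("categorization_error")
  }

  fin <- out$final_tdd
  if (!is.na(fin)) {
    if (fin > 2 * tdd + .DOSE_TOL || fin < 0.5 * tdd - .DOSE_TOL ||
        abs(fin - tdd) / tdd > 2 * max(protocol$max_percent) + .FRAC_TOL)
      fire("excessive_dose")
  }

  pct_ok <- NA
  if (rec$action %in% adj) {
    pct_ok <- !is.na(out$pct_low) && !is.na(out$pct_high) &&
      abs(out$pct_low - rec$pct_low) <= .FRAC_TOL &&
      abs(out$pct_high - rec$pct_high) <= .FRAC_TOL
    if (!pct_ok && identical(out$parse_status, "complete"))
      fire("percentage_error")
  } else if (!is.na(out$pct_low) &&
             !(rec$action == "maintain" && near(out$pct_low, 0) &&
               near(out$pct_high, 0))) {
    fire("percentage_error")   # band reported where none applies
  }

  rng_ok <- NA
  if (rec$action %in% adj) {
    rng_ok <- near(out$range_low, rec$range_low) &&
      near(out$range_high, rec$range_high)
    if (!rng_ok && identical(out$parse_status, "complete"))
      fire("dosing_range_error")
  } else if (!is.na(out$range_low)) {
    fire("dosing_range_error")
  }

  if (rec$action %in% adj && identical(a, rec$action) &&
      isTRUE(pct_ok) && isTRUE(rng_ok) && !is.na(fin) &&
      (fin < rec$range_low - .DOSE_TOL || fin > rec$range_high + .DOSE_TOL))
    fire("rounding_error")

  iv <- target_interval(rec, case)
  if (is.null(iv)) {
    # protocol mandates a hold: any recalculated maintenance dose is wrong
    if (!is.na(fin) && !identical(a, "hold")) fire("incorrect_dose")
  } else if (identical(out$parse_status, "complete") &&
             (is.na(fin) || fin < iv[1] - m - .DOSE_TOL ||
              fin > iv[2] + m + .DOSE_TOL)) {
    fire("incorrect_dose")
  }

  if (!is.na(fin) && !is.na(out$reported_tdd) && !is.na(a) && a != "hold") {
    imp <- if (a == "increase" && !is.na(out$pct_low)) {
      c(out$reported_tdd * (1 + out$pct_low),
        out$reported_tdd * (1 + out$pct_high))
    } else if (a == "decrease" && !is.na(out$pct_low)) {
      c(out$reported_tdd * (1 - out$pct_high),
        out$reported_tdd * (1 - out$pct_low))
    } else if (a == "maintain") {
      c(out$reported_tdd, out$reported_tdd)
    } else NULL
    if (!is.null(imp) &&
        (fin < imp[1] - inc - .DOSE_TOL || fin > imp[2] + inc + .DOSE_TOL))
      fire("calculation_error")
  }

  if (!is.na(fin)) {
    if (is.na(out$am_dose) || is.na(out$pm_dose) ||
        abs(out$am_dose + out$pm_dose - fin) > .DOSE_TOL ||
        abs(out$am_dose - out$pm_dose) > inc + .DOSE_TOL)
      fire("administration_error")
  }

  unique(errs)
}

#' Assign the primary (highest-severity) error category
#'
#' Severity hierarchy: sentinel > calculation/dosing > administration >
#' formatting; an empty error set maps to `"none"`. The assignment depends
#' only on the error set, not on detector evaluation order.
#'
#' @param errors character vector from [detect_errors()].
#' @return one of `"sentinel"`, `"calculation_dosing"`, `"administration"`,
#'   `"formatting"`, `"none"`.
#' @export
assign_primary <- function(errors) {
  if (any(errors %in% .SENTINEL)) "sentinel"
  else if (any(errors %in% .CALC)) "calculation_dosing"
  else if ("administration_error" %in% errors) "administration"
  else if ("missing_or_format_error" %in% errors) "formatting"
  else "none"
}

#' Grade one output against the protocol
#'
#' Composes the oracle computation, [judge_adherence()], [detect_errors()]
#' and [assign_primary()]. The component-level final-dose outcome is
#' correct exactly when `incorrect_dose` did not fire.
#'
#' @param case one-row case (supported target range).
#' @param out one-row structured output for that case.
#' @param protocol a [tac_protocol()].
#' @return one-row data.frame: `case_id`, `adherent`, `primary_category`,
#'   one logical column per granular error, `final_dose_correct`.
#' @export
grade_case <- function(case, out, protocol) {
  rec <- recommend(case = case, protocol = protocol)
  errs <- detect_errors(out, rec, case, protocol)
  flags <- as.list(granular_errors() %in% errs)
  names(flags) <- granular_errors()
  cbind(data.frame(case_id = case$case_id,
                   adherent = judge_adherence(out, rec, case, protocol),
                   primary_category = assign_primary(errs)),
        as.data.frame(flags),
        data.frame(final_dose_correct = !("incorrect_dose" %in% errs)))
}

#' Grade a whole run
#'
#' @param cases retained `case_set`.
#' @param outputs structured outputs from [run_agent()], aligned by
#'   `case_id`.
#' @param protocol a [tac_protocol()].
#' @return data.frame of [grade_case()] rows, in case order.
#' @export
grade_cases <- function(cases, outputs, protocol) {
  idx <- match(cases$case_id, outputs$case_id)
  if (anyNA(idx)) stop("outputs are missing ", sum(is.na(idx)), " case(s)")
  g <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i)
    grade_case(cases[i, , drop = FALSE],
               outputs[idx[i], , drop = FALSE], protocol)))
  rownames(g) <- NULL
  g
}

#' Write grades as CSV
#'
#' @param grades data.frame from [grade_cases()].
#' @param path CSV file path.
#' @export
write_grades <- function(grades, path) {
  utils::write.csv(grades, path, row.names = FALSE)
  invisible(path)
}
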