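# Reproducibility and paired-comparison statistics.

# canonical identity key of a structured output: exact field equality
# after parsing (numerics rounded well below any dose resolution), so
# formatting whitespace can never break agreement.
output_key <- function(outputs) {
  num <- c("reported_tdd", "pct_low", "pct_high", "range_low", "range_high",
           "final_tdd", "am_dose", "pm_dose", "recheck_low", "recheck_high")
  cols <- c(list(outputs$action, outputs$parse_status),
            lapply(outputs[num], function(v) num_chr(v)))
  do.call(paste, c(cols, sep = "|"))
}

#' Agreement rate of repeated outputs
#'
#' The frequency of the most common output divided by the number of
#' repetitions: a scenario answered three times with two identical outputs
#' has agreement 2/3; fully identical outputs have agreement 1; pairwise
#' distinct outputs have agreement 1/n.
#'
#' @param outputs structured-output data.frame: the outputs of one scenario
#'   across its repetitions (at least one row).
#' @return fraction in (0, 1].
#' @export
agreement_rate <- function(outputs) {
  if (is.null(outputs) || nrow(outputs) == 0)
    stop("agreement rate is undefined for an empty output list")
  k <- table(output_key(outputs))
  max(k) / nrow(outputs)
}

#' Reproducibility over repeated scenarios
#'
#' Computes both reproducibility readings over scenarios with at least two
#' instances: `mean_agreement`, the unweighted mean of per-scenario
#' agreement rates, and `identical_fraction`, the share of repeated-case
#' instances matching their scenario's modal output (163 of 211 matching
#' instances give 77.3%).
#'
#' @param outputs structured-output data.frame for a whole run.
#' @param cases the matching `case_set` (supplies `scenario_key`).
#' @return list of class `reproducibility_result`: `per_scenario_agreement`
#'   (named vector), `mean_agreement`, `identical_fraction`,
#'   `n_repeated_instances`, `n_scenarios`. With no repeated scenarios the
#'   means are `NaN` and `undefined` is `TRUE`.
#' @export
reproducibility <- function(outputs, cases) {
  idx <- match(cases$case_id, outputs$case_id)
  if (anyNA(idx)) stop("outputs are missing some cases")
  keys <- output_key(outputs[idx, , drop = FALSE])
  groups <- split(keys, cases$scenario_key)
  groups <- groups[vapply(groups, length, 0L) >= 2]
  modal <- vapply(groups, function(g) max(table(g)), 0)
  sizes <- vapply(groups, length, 0L)
  n_rep <- sum(sizes)
  structure(list(
    per_scenario_agreement = if (length(groups)) modal / sizes else
      stats::setNames(numeric(0), character(0)),
    mean_agreement = if (length(groups)) mean(modal / sizes) else NaN,
    identical_fraction = if (n_rep > 0) sum(modal) / n_rep else NaN,
    n_repeated_instances = n_rep,
    n_scenarios = length(groups),
    undefined = length(groups) == 0), class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  cat(sprintf(paste0("reproducibility over %d repeated instances in %d",
                     " scenarios:\n"), x$n_repeated_instances, x$n_scenarios))
  cat(sprintf("  mean per-scenario agreement: %.3f\n", x$mean_agreement))
  cat(sprintf("  instances matching scenario mode: %.1f%%\n",
              100 * x$identical_fraction))
  invisible(x)
}

#' McNemar paired test on dichotomous outcomes
#'
#' Compares paired pass/fail outcomes of two runs on the same cases using
#' the discordant cells b (first passes only) and c (second passes only).
#' For b + c < 25 the exact two-sided binomial test (b successes in b + c
#' trials at probability 1/2, small tails doubled) is used; otherwise the
#' continuity-corrected chi-square statistic `(|b - c| - 1)^2 / (b + c)`
#' on 1 df. No discordance gives p = 1.
#'
#' @param pass1,pass2 logical vectors of equal length (one element per
#'   case).
#' @return list of class `paired_comparison`: `n_pairs`, `both_pass`,
#'   `both_fail`, `only_first`, `only_second`, `statistic`, `p_value`,
#'   `method` (`"exact_binomial"` or `"chi_square_cc"`).
#' @examples
#' mcnemar(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
mcnemar <- function(pass1, pass2) {
  stopifnot(length(pass1) == length(pass2), length(pass1) >= 1,
            is.logical(pass1), is.logical(pass2), !anyNA(pass1),
            !anyNA(pass2))
  b <- sum(pass1 & !pass2)
  cc <- sum(!pass1 & pass2)
  n <- b + cc
  if (n < 25) {
    p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    res <- list(statistic = min(b, cc), p_value = p,
                method = "exact_binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    res <- list(statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi_square_cc")
  }
  structure(c(list(n_pairs = length(pass1),
                   both_pass = sum(pass1 & pass2),
                   both_fail = sum(!pass1 & !pass2),
                   only_first = b, only_second = cc), res),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("McNemar paired comparison (%s): b = %d, c = %d, p = %.4g\n",
              x$method, x$only_first, x$only_second, x$p_value))
  invisible(x)
}

#' Paired t-test on continuous deviation metrics
#'
#' Two-sided paired t-test on per-case deviation metrics (see
#' [dose_range_deviation()] for the metric used by the pipeline: distance
#' from the final dose to the nearest bound of the protocol dose range, 0
#' inside it). Identical vectors give t = 0, p = 1; a non-zero constant
#' difference has zero variance and is flagged degenerate with an
#' undefined p.
#'
#' @param dev1,dev2 numeric vectors of equal length >= 2.
#' @return list with `t`, `p_value`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_deviation_test <- function(dev1, dev2) {
  stopifnot(length(dev1) == length(dev2))
  if (length(dev1) < 2) stop("paired t-test needs at least 2 pairs")
  d <- dev2 - dev1
  if (stats::sd(d) < 1e-10) {
    if (all(abs(d) < 1e-10))
      return(list(t = 0, p_value = 1, mean_diff = 0, n = length(d),
                  degenerate = FALSE))
    return(list(t = NA_real_, p_value = NA_real_, mean_diff = mean(d),
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(dev2, dev1, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(d), degenerate = FALSE)
}

#' Deviation of final doses from the protocol dose range
#'
#' The continuous deviation metric: distance (mg) from the reported final
#' total daily dose to the nearest bound of the protocol-derived dose
#' range (the unchanged dose for maintain cases), 0 inside the range. Hold
#' cases and outputs without a final dose yield `NA`.
#'
#' @param cases retained `case_set`.
#' @param outputs structured outputs aligned by `case_id`.
#' @param protocol a [tac_protocol()].
#' @return numeric vector, one value per case.
#' @export
dose_range_deviation <- function(cases, outputs, protocol) {
  idx <- match(cases$case_id, outputs$case_id)
  vapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, , drop = FALSE]
    out <- outputs[idx[i], , drop = FALSE]
    rec <- recommend(case = case, protocol = protocol)
    iv <- target_interval(rec, case)
    if (is.null(iv) || is.na(out$final_tdd)) return(NA_real_)
    max(0, iv[1] - out$final_tdd, out$final_tdd - iv[2])
  }, 0)
}
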