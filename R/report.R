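# Evaluation report: stratified adherence, error tables, reproducibility
# and paired comparisons between two graded runs.

count_row <- function(count, denom) {
  data.frame(count = count, denom = denom, pct = display_pct(count, denom))
}

arm_summary <- function(cases, outputs, grades, protocol) {
  n <- nrow(grades)
  primary <- factor(grades$primary_category,
                    levels = c("sentinel", "calculation_dosing",
                               "administration", "formatting", "none"))
  prim <- as.data.frame(table(primary), stringsAsFactors = FALSE)
  names(prim) <- c("category", "count")
  prim$pct <- display_pct(prim$count, n)

  gran <- data.frame(error = granular_errors(),
                     count = vapply(granular_errors(),
                                    function(e) sum(grades[[e]]), 0L))
  gran$pct <- display_pct(gran$count, n)
  rownames(gran) <- NULL

  strata <- lapply(split(grades$adherent, cases$stratum), function(a)
    count_row(sum(a), length(a)))
  by_stratum <- do.call(rbind, strata)
  by_stratum <- cbind(stratum = names(strata), by_stratum)
  rownames(by_stratum) <- NULL

  # two tallies of the calculation/dosing occurrence sum: the taxonomy
  # leaves it open whether excessive-dose occurrences (a sentinel subtype
  # numerically) are also counted there, so both are reported, labeled.
  calc_sum <- sum(gran$count[gran$error %in% .CALC])
  list(n = n,
       adherence = count_row(sum(grades$adherent), n),
       deviations = count_row(sum(!grades$adherent), n),
       by_stratum = by_stratum,
       primary = prim,
       granular = gran,
       calc_dosing_occurrences = count_row(calc_sum, n),
       calc_dosing_occurrences_incl_excessive =
         count_row(calc_sum + sum(grades$excessive_dose), n),
       final_dose_incorrect = count_row(sum(!grades$final_dose_correct), n),
       reproducibility = reproducibility(outputs, cases))
}

comparison_row <- function(name, pass1, pass2) {
  if (!any(pass1) && !any(pass2)) {
    # degenerate row: the outcome is never observed in either arm, so the
    # paired test is undefined and the report prints "-"
    return(data.frame(outcome = name, only_first = 0, only_second = 0,
                      statistic = NA_real_, p_value = NA_real_,
                      method = "none"))
  }
  m <- mcnemar(pass1, pass2)
  data.frame(outcome = name, only_first = m$only_first,
             only_second = m$only_second, statistic = m$statistic,
             p_value = m$p_value, method = m$method)
}

#' Build the evaluation report for two graded runs
#'
#' Produces the stratified adherence/error tables, both reproducibility
#' metrics, and McNemar paired comparisons per outcome row (overall
#' adherence, per-stratum adherence, each primary category and each
#' granular error). All rates are stored as count/denominator pairs with
#' display percentages to one decimal; rows with no discordant pairs carry
#' a suppressed test (`method = "none"`).
#'
#' @param cases retained `case_set` (identical for both runs).
#' @param outputs1,outputs2 structured outputs of the two runs.
#' @param grades1,grades2 matching [grade_cases()] results.
#' @param protocol a [tac_protocol()].
#' @param labels length-2 character, display names of the runs.
#' @return list of class `evaluation_report`.
#' @export
build_report <- function(cases, outputs1, outputs2, grades1, grades2,
                         protocol, labels = c("run1", "run2")) {
  stopifnot(setequal(grades1$case_id, cases$case_id),
            setequal(grades2$case_id, cases$case_id))
  g1 <- grades1[match(cases$case_id, grades1$case_id), , drop = FALSE]
  g2 <- grades2[match(cases$case_id, grades2$case_id), , drop = FALSE]

  comps <- list(comparison_row("adherence", g1$adherent, g2$adherent))
  for (s in unique(cases$stratum)) {
    sel <- cases$stratum == s
    comps[[length(comps) + 1]] <-
      comparison_row(paste0("adherence_", s), g1$adherent[sel],
                     g2$adherent[sel])
  }
  for (cat in c("sentinel", "calculation_dosing", "administration",
                "formatting"))
    comps[[length(comps) + 1]] <-
      comparison_row(paste0("primary_", cat),
                     g1$primary_category == cat, g2$primary_category == cat)
  for (e in granular_errors())
    comps[[length(comps) + 1]] <- comparison_row(e, g1[[e]], g2[[e]])

  arm1 <- arm_summary(cases, outputs1, g1, protocol)
  arm2 <- arm_summary(cases, outputs2, g2, protocol)

  # paired comparison of instance-level reproducibility (does an instance
  # match its scenario's modal output?) over repeated instances
  rep_cmp <- {
    keys1 <- output_key(outputs1[match(cases$case_id, outputs1$case_id), ,
                                 drop = FALSE])
    keys2 <- output_key(outputs2[match(cases$case_id, outputs2$case_id), ,
                                 drop = FALSE])
    match_mode <- function(keys) {
      unlist(lapply(split(seq_len(nrow(cases)), cases$scenario_key),
                    function(ii) {
                      if (length(ii) < 2) return(NULL)
                      tab <- table(keys[ii])
                      stats::setNames(keys[ii] == names(tab)[which.max(tab)],
                                      cases$case_id[ii])
                    }))
    }
    m1 <- match_mode(keys1); m2 <- match_mode(keys2)
    ids <- intersect(names(m1), names(m2))
    if (length(ids) >= 1) comparison_row("reproducibility_instance",
                                         m1[ids], m2[ids]) else NULL
  }
  if (!is.null(rep_cmp)) comps[[length(comps) + 1]] <- rep_cmp

  dev1 <- dose_range_deviation(cases, outputs1, protocol)
  dev2 <- dose_range_deviation(cases, outputs2, protocol)
  ok <- !is.na(dev1) & !is.na(dev2)
  dev_test <- if (sum(ok) >= 2) paired_deviation_test(dev1[ok], dev2[ok])
  else NULL

  structure(list(labels = labels, n_cases = nrow(cases),
                 arms = stats::setNames(list(arm1, arm2), labels),
                 comparisons = do.call(rbind, comps),
                 deviation_test = dev_test),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a1 <- x$arms[[1]]; a2 <- x$arms[[2]]
  cat(sprintf("Evaluation over %d cases: %s vs %s\n", x$n_cases,
              x$labels[1], x$labels[2]))
  line <- function(label, r1, r2)
    cat(sprintf("  %-22s %3d/%3d (%.1f%%)  vs  %3d/%3d (%.1f%%)\n", label,
                r1$count, r1$denom, r1$pct, r2$count, r2$denom, r2$pct))
  line("protocol adherence", a1$adherence, a2$adherence)
  line("protocol deviations", a1$deviations, a2$deviations)
  s1 <- a1$primary[a1$primary$category == "sentinel", ]
  line("sentinel (primary)", count_row(s1$count, a1$n),
       count_row(a2$primary$count[a2$primary$category == "sentinel"], a2$n))
  cat(sprintf("  %-22s %.1f%%  vs  %.1f%%  (instances matching mode)\n",
              "reproducibility",
              100 * a1$reproducibility$identical_fraction,
              100 * a2$reproducibility$identical_fraction))
  adh <- x$comparisons[x$comparisons$outcome == "adherence", ]
  cat(sprintf("  McNemar on adherence: b = %d, c = %d, p = %.4g (%s)\n",
              adh$only_first, adh$only_second, adh$p_value, adh$method))
  invisible(x)
}

#' Write an evaluation report
#'
#' Serializes a report as machine-readable JSON plus CSV tables (primary
#' categories and granular subcategories as rows; per-run count and
#' display percentage columns; the McNemar p of the row), and a short
#' plain-text summary.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "csv", "text")`.
#' @return invisible character vector of files written.
#' @export
write_report <- function(report, dir, formats = c("json", "csv", "text")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    written <- c(written, f)
  }
  if ("csv" %in% formats) {
    a1 <- report$arms[[1]]; a2 <- report$arms[[2]]
    cmp <- report$comparisons
    p_of <- function(outcome) {
      hit <- cmp$p_value[cmp$outcome == outcome]
      if (length(hit) == 0) NA_real_ else hit[1]
    }
    tab <- rbind(
      data.frame(row = paste0("primary_", a1$primary$category),
                 n1 = a1$primary$count, pct1 = a1$primary$pct,
                 n2 = a2$primary$count, pct2 = a2$primary$pct,
                 p_value = vapply(paste0("primary_", a1$primary$category),
                                  p_of, 0)),
      data.frame(row = a1$granular$error,
                 n1 = a1$granular$count, pct1 = a1$granular$pct,
                 n2 = a2$granular$count, pct2 = a2$granular$pct,
                 p_value = vapply(a1$granular$error, p_of, 0)))
    names(tab)[2:5] <- c(paste0(report$labels[1], c("_n", "_pct")),
                         paste0(report$labels[2], c("_n", "_pct")))
    f <- file.path(dir, "report_table.csv")
    utils::write.csv(tab, f, row.names = FALSE, na = "-")
    written <- c(written, f)
  }
  if ("text" %in% formats) {
    f <- file.path(dir, "report.txt")
    con <- file(f, "w")
    sink(con); print(report); sink()
    close(con)
    written <- c(written, f)
  }
  invisible(written)
}
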