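p <- default_protocol()

grade1 <- function(case, out) grade_case(case, out, p)
oracle_out <- function(case) oracle_agent(case, p)

test_that("oracle outputs grade adherent, with errors only in the discrete-increment regime", {
  cs <- filter_supported(default_case_set(seed = 1), p)$retained
  o <- run_agent(cs, p, "oracle")
  g <- grade_cases(cs, o, p)
  infeasible <- infeasible_range_flags(cs, p)

  # rounding errors fire exactly where no feasible in-range dose exists
  expect_equal(g$rounding_error, infeasible)
  # every other error class is silent for the oracle
  for (e in setdiff(granular_errors(), c("rounding_error", "incorrect_dose")))
    expect_equal(sum(g[[e]]), 0)
  # adherence can only be lost to the margin on infeasible ranges
  expect_true(all(g$adherent[!infeasible]))
  expect_true(all(!g$adherent | g$primary_category %in%
                    c("none", "calculation_dosing")))
  # errors empty  <=>  adherent, non-adherent cases carry a category
  none <- g$primary_category == "none"
  expect_true(all(g$adherent[none]))
  expect_true(all(g$primary_category[!g$adherent] != "none"))
})

test_that("adherence honors the rounding margin at the range boundary", {
  case <- make_case(4.9, 3.0)  # 6-8 target, deviation 1.1 -> +20-30%
  rec <- recommend(case = case, protocol = p)
  expect_equal(c(rec$range_low, rec$range_high), c(3.6, 3.9))

  out <- oracle_out(case)
  for (final in c(3.5, 4.0)) {   # range.low - 0.1 and range.high + 0.1
    out$final_tdd <- final
    out$am_dose <- ceiling(final / 0.5 / 2) * 0.5
    out$pm_dose <- final - out$am_dose
    g <- grade1(case, out)
    expect_true(g$adherent)
    expect_true(g$rounding_error)     # outside the exact computed range
    expect_true(g$final_dose_correct) # within range +- margin
    expect_equal(g$primary_category, "calculation_dosing")
  }
  out$final_tdd <- 4.5; out$am_dose <- 2.5; out$pm_dose <- 2.0
  g <- grade1(case, out)
  expect_false(g$adherent)
  expect_true(g$incorrect_dose)
})

test_that("a suppressed hold grades as a sentinel holding error", {
  case <- make_case(15.2, 6.0, 8, 10)  # hold mandated
  out <- oracle_out(case)
  out$action <- "decrease"
  out$pct_low <- 0.2; out$pct_high <- 0.3
  out$range_low <- 4.2; out$range_high <- 4.8
  out$final_tdd <- 4.5; out$am_dose <- 2.5; out$pm_dose <- 2.0
  out$recheck_low <- NA_real_; out$recheck_high <- NA_real_
  g <- grade1(case, out)
  expect_false(g$adherent)
  expect_true(g$holding_error)
  expect_true(g$incorrect_dose)  # no recalculated dose is protocol-correct
  expect_equal(g$primary_category, "sentinel")

  # the opposite direction: holding when no hold is mandated
  case2 <- make_case(9.0, 6.0, 6, 8)
  out2 <- oracle_out(make_case(15.2, 6.0, 8, 10))
  out2$case_id <- case2$case_id
  g2 <- grade1(case2, out2)
  expect_true(g2$holding_error)
  expect_equal(g2$primary_category, "sentinel")
})

test_that("granular detectors fire on their signature deviations", {
  case <- make_case(5.0, 4.0)  # +10-20%, range [4.4, 4.8], oracle 4.5
  base <- oracle_out(case)

  flip <- base
  flip$action <- "decrease"
  flip$range_low <- 3.2; flip$range_high <- 3.6
  flip$final_tdd <- 3.5; flip$am_dose <- 2.0; flip$pm_dose <- 1.5
  g <- grade1(case, flip)
  expect_true(g$directional_error && g$categorization_error)
  expect_equal(g$primary_category, "sentinel")

  wrong_pct <- base
  wrong_pct$pct_low <- 0.2; wrong_pct$pct_high <- 0.3
  g <- grade1(case, wrong_pct)
  expect_true(g$percentage_error)
  expect_false(g$rounding_error)  # rounding requires the percent correct

  wrong_rng <- base
  wrong_rng$range_low <- 4.9; wrong_rng$range_high <- 5.3
  g <- grade1(case, wrong_rng)
  expect_true(g$dosing_range_error)

  doubled <- base
  doubled$final_tdd <- 8.5; doubled$am_dose <- 4.5; doubled$pm_dose <- 4.0
  g <- grade1(case, doubled)
  expect_true(g$excessive_dose)
  expect_true(g$incorrect_dose)
  expect_equal(g$primary_category, "sentinel")

  bad_split <- base
  bad_split$am_dose <- bad_split$am_dose + 0.5
  g <- grade1(case, bad_split)
  expect_true(g$administration_error)
  expect_equal(g$primary_category, "administration")

  self_inconsistent <- base
  self_inconsistent$final_tdd <- 6.0   # not 10-20% above 4.0 by any rounding
  self_inconsistent$am_dose <- 3.0; self_inconsistent$pm_dose <- 3.0
  g <- grade1(case, self_inconsistent)
  expect_true(g$calculation_error)
  expect_true(g$incorrect_dose)

  empty <- parse_output("", case$case_id)
  g <- grade1(case, empty)
  expect_true(g$missing_or_format_error)
  expect_equal(g$primary_category, "formatting")
  expect_false(g$adherent)
})

test_that("primary assignment follows the severity hierarchy, order-free", {
  expect_equal(assign_primary(c("directional_error", "percentage_error")),
               "sentinel")
  expect_equal(assign_primary(c("percentage_error", "directional_error")),
               "sentinel")
  expect_equal(assign_primary("rounding_error"), "calculation_dosing")
  expect_equal(assign_primary(c("administration_error",
                                "missing_or_format_error")),
               "administration")
  expect_equal(assign_primary("missing_or_format_error"), "formatting")
  expect_equal(assign_primary(character(0)), "none")
  # invariant under any permutation of a mixed set
  errs <- c("rounding_error", "holding_error", "administration_error")
  for (i in 1:6)
    expect_equal(assign_primary(sample(errs)), "sentinel")
})

test_that("a fully directional agent grades sentinel on every adjustment case", {
  cs <- filter_supported(default_case_set(seed = 6), p)$retained
  adj <- cs[cs$stratum != "within", ]
  recs <- lapply(seq_len(nrow(adj)), function(i)
    recommend(case = adj[i, , drop = FALSE], protocol = p))
  adj <- adj[vapply(recs, function(r) r$action != "hold", TRUE), ]
  out <- run_agent(adj, p, error_profile(p_directional = 1), seed = 5)
  g <- grade_cases(adj, out, p)
  expect_true(all(g$directional_error))
  expect_true(all(g$primary_category == "sentinel"))
  expect_true(all(!g$adherent))
})
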