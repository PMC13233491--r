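p <- default_protocol()

test_that("trough classification handles interior, boundary and extreme values", {
  r46 <- target_range(4, 6)
  expect_equal(classify_trough(5.0, r46), "within")
  expect_equal(classify_trough(2.5, r46), "below")
  expect_equal(classify_trough(6.0, r46), "within")
  expect_equal(classify_trough(6.1, r46), "above")
  expect_equal(classify_trough(3.9999999, r46), "within") # inside tolerance
})

test_that("action selection: maintain, hold override, and band lookup", {
  expect_equal(select_adjustment(7.0, target_range(6, 8), p), "maintain")
  expect_equal(select_adjustment(15.4, target_range(8, 10), p), "hold")
  expect_equal(select_adjustment(15.0, target_range(8, 10), p), "hold")
  b <- select_adjustment(5.0, target_range(6, 8), p) # deviation exactly 1.0
  expect_equal(c(b$p_low, b$p_high), c(0.10, 0.20))
  b <- select_adjustment(4.9, target_range(6, 8), p) # deviation 1.1
  expect_equal(c(b$p_low, b$p_high), c(0.20, 0.30))
  b <- select_adjustment(14.9, target_range(8, 10), p) # below hold, dev > 2
  expect_equal(b$direction, "decrease")
  expect_equal(c(b$p_low, b$p_high), c(0.30, 0.40))
  expect_error(select_adjustment(5.0, target_range(10, 12), p),
               class = "tacsim_unsupported_target")
})

test_that("dose-range arithmetic matches the percentage band", {
  inc23 <- data.frame(direction = "increase", p_low = 0.2, p_high = 0.3)
  expect_equal(compute_dose_range(3.0, inc23), list(low = 3.6, high = 3.9))
  dec12 <- data.frame(direction = "decrease", p_low = 0.1, p_high = 0.2)
  expect_equal(compute_dose_range(10.0, dec12), list(low = 8.0, high = 9.0))
  ident <- data.frame(direction = "increase", p_low = 0, p_high = 0)
  expect_equal(compute_dose_range(7.5, ident), list(low = 7.5, high = 7.5))
})

test_that("increment rounding is nearest with ties up", {
  expect_equal(round_to_increment(4.8, 0.5), 5.0)
  expect_equal(round_to_increment(3.6, 0.5), 3.5)
  expect_equal(round_to_increment(3.75, 0.5), 4.0)   # tie rounds up
  expect_equal(round_to_increment(2.25, 0.5), 2.5)   # tie rounds up
  expect_equal(round_to_increment(7.0, 0.5), 7.0)
  # property: result is always the nearest multiple, on a fine grid
  for (d in seq(0.1, 12, by = 0.1)) {
    r <- round_to_increment(d, 0.5)
    expect_true(abs(r - d) <= 0.25 + 1e-9)
    expect_equal(r %% 0.5, 0, tolerance = 1e-9)
  }
})

test_that("feasible dose enumeration covers empty, multiple and degenerate ranges", {
  expect_length(feasible_doses(list(low = 3.6, high = 3.9), 0.5), 0)
  expect_equal(feasible_doses(list(low = 8.0, high = 9.0), 0.5),
               c(8.0, 8.5, 9.0))
  expect_equal(feasible_doses(list(low = 4.0, high = 4.0), 0.5), 4.0)
  expect_equal(feasible_doses(list(low = 3.3, high = 3.6), 0.5), 3.5)
})

test_that("final dose selection prefers in-range doses near the midpoint", {
  expect_equal(choose_final_dose(list(low = 8.0, high = 9.0), 0.5, 0.1), 8.5)
  # no feasible option: nearest multiple to the midpoint, tie toward lower
  expect_equal(choose_final_dose(list(low = 3.6, high = 3.9), 0.5, 0.1), 3.5)
  expect_equal(choose_final_dose(list(low = 4.9, high = 5.1), 0.5, 0.1), 5.0)
  # in-range tie also resolves toward the lower dose
  expect_equal(choose_final_dose(list(low = 8.0, high = 8.5), 0.5, 0.1), 8.0)
})

test_that("BID splitting conserves the TDD with the larger half in AM", {
  expect_equal(split_bid(9.0, 0.5), c(am = 4.5, pm = 4.5))
  expect_equal(split_bid(8.5, 0.5), c(am = 4.5, pm = 4.0))
  expect_equal(split_bid(1.0, 0.5), c(am = 0.5, pm = 0.5))
  expect_error(split_bid(8.3, 0.5), "multiple")
  for (tdd in seq(0.5, 12, by = 0.5)) {
    sp <- split_bid(tdd, 0.5)
    expect_equal(unname(sum(sp)), tdd)
    expect_true(sp[["am"]] >= sp[["pm"]])
    expect_true(sp[["am"]] - sp[["pm"]] <= 0.5 + 1e-9)
  }
})

test_that("recommend composes the decision path for all three actions", {
  r <- recommend(7.0, 8.0, target_range(6, 8), p)
  expect_equal(r$action, "maintain")
  expect_equal(r$final_tdd, 8.0)
  expect_equal(c(r$am_dose, r$pm_dose), c(4.0, 4.0))

  r <- recommend(15.4, 6.0, target_range(8, 10), p)
  expect_equal(r$action, "hold")
  expect_true(is.na(r$final_tdd) && is.na(r$range_low))
  expect_equal(c(r$recheck_low, r$recheck_high), c(24, 48))

  # custom config whose matching band is +20-30% at deviation 1.0
  bands <- data.frame(direction = rep(c("increase", "decrease"), each = 2),
                      dev_low = rep(c(0, 1.5), 2),
                      dev_high = rep(c(1.5, Inf), 2),
                      p_low = rep(c(0.2, 0.3), 2),
                      p_high = rep(c(0.3, 0.4), 2))
  p23 <- tac_protocol(list(target_range(6, 8)), bands,
                      hold_thresholds = c("6-8" = 13))
  r <- recommend(5.0, 3.0, target_range(6, 8), p23)
  expect_equal(r$action, "increase")
  expect_equal(c(r$range_low, r$range_high), c(3.6, 3.9))
  expect_equal(r$final_tdd, 3.5) # midpoint 3.75, tie toward lower
})

test_that("recommendations are deterministic and conserve the AM/PM sum", {
  set.seed(11)
  for (i in 1:50) {
    trough <- round(stats::runif(1, 2.5, 15.4), 1)
    tdd <- sample(seq(1, 12, 0.5), 1)
    rng <- p$ranges[[sample(3, 1)]]
    r1 <- recommend(trough, tdd, rng, p)
    r2 <- recommend(trough, tdd, rng, p)
    expect_identical(r1, r2)
    if (!is.na(r1$final_tdd)) {
      expect_equal(r1$am_dose + r1$pm_dose, r1$final_tdd)
      expect_equal(r1$final_tdd %% 0.5, 0, tolerance = 1e-9)
    }
  }
})

test_that("adjustments are direction-consistent and bounded", {
  inc <- p$dose_increment
  for (trough in seq(2.5, 15.4, by = 0.3)) {
    for (tdd in seq(1, 12, by = 1.5)) {
      for (rng in p$ranges) {
        r <- recommend(round(trough, 1), tdd, rng, p)
        if (r$action == "increase")
          expect_true(r$final_tdd >= tdd - p$adherence_margin - 1e-9)
        if (r$action == "decrease")
          expect_true(r$final_tdd <= tdd + p$adherence_margin + 1e-9)
        if (!is.na(r$final_tdd)) {
          expect_true(r$final_tdd <= (1 + max(p$max_percent)) * tdd + inc)
          expect_true(r$final_tdd >= (1 - max(p$max_percent)) * tdd - inc)
        }
        # hold supremacy
        if (classify_trough(round(trough, 1), rng) == "above" &&
            round(trough, 1) >= p$hold_thresholds[[paste0(rng$low, "-",
                                                          rng$high)]])
          expect_equal(r$action, "hold")
      }
    }
  }
})

test_that("recommend agrees with a brute-force band enumeration on a dense grid", {
  for (trough in seq(2.5, 15.4, by = 0.1)) {
    trough <- round(trough, 1)
    for (tdd in seq(1, 12, by = 0.5)) {
      for (rng in p$ranges) {
        r <- recommend(trough, tdd, rng, p)
        bf <- brute_force_recommend(trough, tdd, rng$low, rng$high)
        expect_equal(r$action, bf$action,
                     info = sprintf("trough %.1f tdd %.1f range %s-%s",
                                    trough, tdd, rng$low, rng$high))
        if (bf$action %in% c("increase", "decrease")) {
          expect_equal(c(r$pct_low, r$pct_high), bf$pct)
          expect_equal(c(r$range_low, r$range_high), bf$range)
          expect_equal(r$final_tdd, bf$final)
          expect_equal(c(r$am_dose, r$pm_dose), c(bf$am, bf$pm))
        }
        if (bf$action == "maintain") expect_equal(r$final_tdd, tdd)
      }
    }
  }
})
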