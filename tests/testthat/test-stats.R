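p <- default_protocol()

# n structurally distinct complete outputs for agreement fixtures
distinct_outputs <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i)
    oracle_agent(make_case(7.0, i * 0.5 + 4, id = sprintf("C%03d", i)), p)))
}

test_that("agreement rate is the modal share of repeated outputs", {
  two_of_three <- distinct_outputs(2)[c(1, 1, 2), ]
  expect_equal(agreement_rate(two_of_three), 2 / 3)
  expect_equal(agreement_rate(distinct_outputs(1)[rep(1, 5), ]), 1.0)
  expect_equal(agreement_rate(distinct_outputs(4)), 0.25)
  expect_error(agreement_rate(distinct_outputs(1)[0, ]), "empty")
})

test_that("reproducibility reports both scenario-mean and instance-level metrics", {
  # two scenarios: one fully identical (agreement 1), one 1-of-2 (0.5)
  outs <- rbind(distinct_outputs(1)[c(1, 1), ], distinct_outputs(2))
  outs$case_id <- sprintf("C%03d", 1:4)
  cases <- rbind(make_case(7, 4, id = "C001", key = "A"),
                 make_case(7, 4, id = "C002", key = "A"),
                 make_case(7, 4, id = "C003", key = "B"),
                 make_case(7, 4, id = "C004", key = "B"))
  r <- reproducibility(outs, cases)
  expect_equal(r$mean_agreement, 0.75)
  expect_equal(r$identical_fraction, 3 / 4)
  expect_equal(r$n_repeated_instances, 4)

  # singleton scenarios do not contribute
  cases$scenario_key <- c("A", "A", "B", "C")
  r <- reproducibility(outs, cases)
  expect_equal(r$n_repeated_instances, 2)
  expect_equal(r$mean_agreement, 1.0)

  # no repeated scenarios at all
  cases$scenario_key <- c("A", "B", "C", "D")
  r <- reproducibility(outs, cases)
  expect_true(r$undefined)
  expect_equal(r$n_repeated_instances, 0)
})

test_that("identical-output fractions reproduce the reference arithmetic", {
  # 23 scenarios of 5 identical outputs (115 instances) plus 48 discordant
  # pairs: 163 of 211 repeated instances match their scenario mode
  base <- distinct_outputs(2)
  outs <- list(); cases <- list(); k <- 0
  add <- function(out_rows, key) {
    for (j in seq_len(nrow(out_rows))) {
      k <<- k + 1
      row <- out_rows[j, , drop = FALSE]
      row$case_id <- sprintf("C%04d", k)
      outs[[k]] <<- row
      cases[[k]] <<- make_case(7, 4, id = row$case_id, key = key)
    }
  }
  for (s in 1:23) add(base[rep(1, 5), ], sprintf("ident%02d", s))
  for (s in 1:48) add(base, sprintf("pair%02d", s))
  outs <- do.call(rbind, outs); cases <- do.call(rbind, cases)
  r <- reproducibility(outs, cases)
  expect_equal(r$n_repeated_instances, 211)
  expect_equal(r$identical_fraction, 163 / 211)
  expect_equal(display_pct(163, 211), 77.3)
  expect_equal(display_pct(183, 211), 86.7)
})

test_that("mcnemar switches between exact binomial and corrected chi-square", {
  no_disc <- mcnemar(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(no_disc$p_value, 1.0)
  expect_equal(no_disc$method, "exact_binomial")
  expect_equal(no_disc$only_first + no_disc$only_second, 0)

  # b = 10, c = 0: exact p = 2 * (1/2)^10
  ex <- mcnemar(rep(c(TRUE, FALSE), c(10, 2)), rep(FALSE, 12))
  expect_equal(ex$only_first, 10)
  expect_equal(ex$only_second, 0)
  expect_equal(ex$p_value, 2 * 0.5^10)
  expect_equal(ex$method, "exact_binomial")

  # b = 30, c = 5: continuity-corrected chi-square (|25| - 1)^2 / 35
  p1 <- rep(c(TRUE, FALSE, TRUE), c(30, 5, 7))
  p2 <- rep(c(FALSE, TRUE, TRUE), c(30, 5, 7))
  ch <- mcnemar(p1, p2)
  expect_equal(ch$method, "chi_square_cc")
  expect_equal(ch$statistic, 24^2 / 35)
  expect_equal(ch$p_value, pchisq(24^2 / 35, 1, lower.tail = FALSE))
  # independent check against the base-R implementation
  ref <- mcnemar.test(table(factor(p1, c(FALSE, TRUE)),
                            factor(p2, c(FALSE, TRUE))))
  expect_equal(ch$statistic, unname(ref$statistic))
  expect_equal(ch$p_value, ref$p.value)
})

test_that("the exact branch matches brute-force enumeration and is symmetric", {
  enumerate_p <- function(b, cc) {
    n <- b + cc
    if (n == 0) return(1)
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[abs(0:n - n / 2) >= abs(b - n / 2) - 1e-12])
  }
  for (n in 0:24) {
    for (b in 0:n) {
      cc <- n - b
      pass1 <- rep(c(TRUE, FALSE, TRUE), c(b, cc, 1))
      pass2 <- rep(c(FALSE, TRUE, TRUE), c(b, cc, 1))
      m <- mcnemar(pass1, pass2)
      expect_equal(m$method, "exact_binomial")
      expect_equal(m$p_value, enumerate_p(b, cc),
                   info = sprintf("b=%d c=%d", b, cc))
      m_swap <- mcnemar(pass2, pass1)
      expect_equal(m_swap$p_value, m$p_value)
      # independent oracle: the exact binomial test at p = 1/2
      if (n > 0)
        expect_equal(m$p_value, binom.test(b, n, 0.5)$p.value)
    }
  }
})

test_that("the paired deviation test matches its closed form", {
  d1 <- c(0.0, 0.1, 0.3, 0.0, 0.2)
  same <- paired_deviation_test(d1, d1)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  shifted <- paired_deviation_test(d1, d1 + c(0.1, 0.3, 0.2, 0.1, 0.3))
  delta <- c(0.1, 0.3, 0.2, 0.1, 0.3)
  expect_equal(shifted$t, mean(delta) / (sd(delta) / sqrt(5)))
  expect_equal(shifted$p_value,
               2 * pt(abs(shifted$t), df = 4, lower.tail = FALSE))

  const <- paired_deviation_test(d1, d1 + 0.2)
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))

  expect_error(paired_deviation_test(0.1, 0.2), "at least 2")
})

test_that("dose-range deviation is zero inside the protocol range", {
  cases <- rbind(make_case(7.0, 8.0, id = "C001"),   # maintain
                 make_case(5.0, 4.0, id = "C002"),   # +10-20% -> [4.4, 4.8]
                 make_case(15.2, 6.0, 8, 10, id = "C003")) # hold
  outs <- run_agent(cases, p, "oracle")
  dev <- dose_range_deviation(cases, outs, p)
  expect_equal(dev[1:2], c(0, 0))
  expect_true(is.na(dev[3]))
  outs$final_tdd[2] <- 5.0; outs$am_dose[2] <- 2.5; outs$pm_dose[2] <- 2.5
  expect_equal(dose_range_deviation(cases, outs, p)[2], 0.2)
})

test_that("displayed percentages recompute from count/denominator pairs", {
  expect_equal(display_pct(210, 288), 72.9)
  expect_equal(display_pct(2, 3), 66.7)
  expect_equal(display_pct(1, 288), 0.3)
  expect_equal(display_pct(225, 288), 78.1)  # exact .x25 tie
  expect_equal(display_pct(9, 288), 3.1)     # exact .x25 tie
})
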