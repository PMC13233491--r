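# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk.

make_case <- function(trough, tdd, low = 6, high = 8,
                      id = "C0001", key = "S-test-001",
                      stratum = NULL) {
  if (is.null(stratum))
    stratum <- classify_trough(trough, target_range(low, high))
  data.frame(case_id = id, scenario_key = key, trough_ng_ml = trough,
             current_tdd_mg = tdd, target_low = low, target_high = high,
             stratum = stratum)
}

# n copies of a template row with unique ids (rows cycle over templates)
make_pool <- function(templates, n) {
  idx <- rep_len(seq_len(nrow(templates)), n)
  pool <- templates[idx, , drop = FALSE]
  pool$case_id <- sprintf("P%05d", seq_len(n))
  pool$scenario_key <- sprintf("SP%05d", seq_len(n))
  rownames(pool) <- NULL
  list(pool = pool, template_idx = idx)
}

# Independent brute-force reimplementation of the protocol decision rule
# for the shipped default configuration: literal threshold comparisons and
# dose enumeration, sharing no code path with recommend().
brute_force_recommend <- function(trough, tdd, low, high) {
  hold_at <- high + 5
  if (trough >= low && trough <= high) {
    am <- ceiling(tdd / 0.5 / 2) * 0.5
    return(list(action = "maintain", final = tdd, am = am, pm = tdd - am))
  }
  if (trough > high && trough >= hold_at) return(list(action = "hold"))
  dev <- if (trough < low) low - trough else trough - high
  pl <- if (dev <= 1) 0.10 else if (dev <= 2) 0.20 else 0.30
  ph <- pl + 0.10
  if (trough < low) {
    lo <- tdd * (1 + pl); hi <- tdd * (1 + ph); action <- "increase"
  } else {
    lo <- tdd * (1 - ph); hi <- tdd * (1 - pl); action <- "decrease"
  }
  grid <- seq(0.5, 40, by = 0.5)
  inside <- grid[grid >= lo - 1e-9 & grid <= hi + 1e-9]
  cand <- if (length(inside) > 0) inside else grid
  mid <- (lo + hi) / 2
  d <- abs(cand - mid)
  final <- min(cand[d <= min(d) + 1e-9])
  am <- ceiling(final / 0.5 / 2) * 0.5
  list(action = action, pct = c(pl, ph), range = c(lo, hi),
       final = final, am = am, pm = final - am)
}

default_case_set <- function(seed = 1) {
  generate_cases(generation_config(seed = seed), default_protocol())
}

# indices of retained cases whose protocol dose range has no feasible
# 0.5-mg option (the discrete-increment degenerate regime)
infeasible_range_flags <- function(cases, protocol) {
  vapply(seq_len(nrow(cases)), function(i) {
    rec <- recommend(case = cases[i, , drop = FALSE], protocol = protocol)
    if (!rec$action %in% c("increase", "decrease")) return(FALSE)
    length(feasible_doses(list(low = rec$range_low, high = rec$range_high),
                          protocol$dose_increment)) == 0
  }, TRUE)
}
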