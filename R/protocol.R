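#' Target trough range
#'
#' A patient-specific tacrolimus target range in ng/mL. Membership is
#' inclusive at both bounds, so a trough exactly on a bound counts as
#' therapeutic.
#'
#' @param low,high range bounds in ng/mL; `0 < low < high`.
#' @return an object of class `target_range` (list with `low`, `high`).
#' @examples
#' target_range(6, 8)
#' @export
target_range <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1,
            length(high) == 1, low > 0, low < high)
  structure(list(low = low, high = high), class = "target_range")
}

#' @export
print.target_range <- function(x, ...) {
  cat(sprintf("target trough range %s ng/mL\n", range_key(x)))
  invisible(x)
}

#' @export
format.target_range <- function(x, ...) range_key(x)

# canonical "low-high" key used to index ranges in protocol tables
range_key <- function(range) {
  sprintf("%s-%s", num_chr(range$low), num_chr(range$high))
}

range_equal <- function(a, b) near(a$low, b$low) && near(a$high, b$high)

#' Institutional dose-adjustment protocol
#'
#' Encodes an institutional tacrolimus adjustment protocol: the supported
#' target ranges, the percentage adjustment bands (stratified by deviation
#' of the trough from the violated target bound), absolute hold thresholds
#' that override percentage adjustments for markedly supratherapeutic
#' troughs, the discrete dose increment, and the adherence rounding margin.
#'
#' Deviation intervals are lower-exclusive and upper-inclusive (a deviation
#' of exactly 1.0 ng/mL falls in the band whose interval ends at 1.0); an
#' out-of-range trough always has strictly positive deviation, so the bands
#' of each direction tile the whole deviation domain below the hold
#' threshold.
#'
#' @param ranges list of [target_range()] objects the protocol supports.
#' @param bands data.frame with columns `direction` ("increase"/"decrease"),
#'   `dev_low`, `dev_high` (ng/mL deviation interval, `(dev_low, dev_high]`),
#'   `p_low`, `p_high` (fractional percentage interval, e.g. 0.10, 0.20).
#' @param hold_thresholds named numeric, absolute trough (ng/mL) at or above
#'   which a dose hold is mandated, named by the `"low-high"` key of each
#'   supported range; each threshold must exceed the range's upper bound.
#' @param recheck_window hours within which the trough is rechecked after a
#'   held dose (default 24-48 h).
#' @param dose_increment smallest available dose step in mg (default 0.5).
#' @param adherence_margin clinically insignificant rounding margin in mg
#'   applied around the protocol dose range when judging adherence
#'   (default 0.1).
#' @return object of class `tac_protocol`.
#' @seealso [default_protocol()], [read_protocol()], [write_protocol()]
#' @export
tac_protocol <- function(ranges, bands, hold_thresholds,
                         recheck_window = c(24, 48),
                         dose_increment = 0.5,
                         adherence_margin = 0.1) {
  stopifnot(length(ranges) >= 1, is.data.frame(bands),
            all(c("direction", "dev_low", "dev_high", "p_low", "p_high")
                %in% names(bands)),
            dose_increment > 0, adherence_margin >= 0,
            length(recheck_window) == 2,
            recheck_window[1] < recheck_window[2])
  stopifnot(all(bands$direction %in% c("increase", "decrease")),
            all(bands$p_low >= 0), all(bands$p_high <= 1),
            all(bands$p_low <= bands$p_high),
            all(bands$dev_low >= 0), all(bands$dev_low < bands$dev_high))
  keys <- vapply(ranges, range_key, "")
  stopifnot(!anyDuplicated(keys), all(keys %in% names(hold_thresholds)))
  for (r in ranges) {
    thr <- hold_thresholds[[range_key(r)]]
    if (!is.finite(thr) || thr <= r$high)
      stop("hold threshold for range ", range_key(r),
           " must exceed the range upper bound")
  }
  # band coverage: per direction, intervals must tile (0, max] without
  # overlap; deviations above the largest dev_high only occur beyond the
  # hold threshold for decreases, and are a configuration error otherwise.
  for (dir in c("increase", "decrease")) {
    b <- bands[bands$direction == dir, , drop = FALSE]
    if (nrow(b) == 0) stop("no bands for direction ", dir)
    b <- b[order(b$dev_low), , drop = FALSE]
    if (!near(b$dev_low[1], 0))
      stop("bands for ", dir, " must start at deviation 0")
    if (nrow(b) > 1 &&
        !all(near(b$dev_low[-1], b$dev_high[-nrow(b)])))
      stop("bands for ", dir, " must tile the deviation domain")
  }
  names(ranges) <- keys
  structure(list(ranges = ranges, bands = bands,
                 hold_thresholds = hold_thresholds,
                 recheck_window = recheck_window,
                 dose_increment = dose_increment,
                 adherence_margin = adherence_margin,
                 max_percent = c(
                   increase = max(bands$p_high[bands$direction == "increase"]),
                   decrease = max(bands$p_high[bands$direction == "decrease"]))),
            class = "tac_protocol")
}

#' Shipped default protocol
#'
#' The default protocol configuration: target ranges 4-6, 6-8 and 8-10
#' ng/mL; symmetric adjustment bands of 10-20% (deviation up to 1 ng/mL),
#' 20-30% (1-2 ng/mL) and 30-40% (beyond 2 ng/mL); a dose hold whenever the
#' trough reaches 5 ng/mL above the target upper bound, with a 24-48 h
#' recheck; 0.5-mg dose increments and a 0.1-mg adherence margin. The exact
#' institutional band cut-points are site-specific; these defaults are
#' consistent with every percentage band the protocol framework uses and
#' are fully replaceable via [read_protocol()].
#'
#' The 10-12 ng/mL range is deliberately unsupported: scenarios carrying it
#' have no dosing guidance and are excluded from analysis by
#' [filter_supported()].
#'
#' @param hold_offset ng/mL above the target upper bound at which the hold
#'   applies (default 5).
#' @return a `tac_protocol`.
#' @examples
#' prot <- default_protocol()
#' recommend(trough = 5.0, tdd = 4.0, range = target_range(6, 8), prot)
#' @export
default_protocol <- function(hold_offset = 5) {
  ranges <- list(target_range(4, 6), target_range(6, 8), target_range(8, 10))
  bands <- data.frame(
    direction = rep(c("increase", "decrease"), each = 3),
    dev_low  = rep(c(0, 1, 2), 2),
    dev_high = rep(c(1, 2, Inf), 2),
    p_low    = rep(c(0.10, 0.20, 0.30), 2),
    p_high   = rep(c(0.20, 0.30, 0.40), 2))
  holds <- vapply(ranges, function(r) r$high + hold_offset, 0)
  names(holds) <- vapply(ranges, range_key, "")
  tac_protocol(ranges, bands, holds)
}

#' @export
print.tac_protocol <- function(x, ...) {
  cat("Tacrolimus dose-adjustment protocol\n")
  cat("  supported target ranges (ng/mL): ",
      paste(names(x$ranges), collapse = ", "), "\n", sep = "")
  b <- x$bands
  for (i in seq_len(nrow(b))) {
    hi <- if (is.finite(b$dev_high[i])) sprintf("%.1f", b$dev_high[i]) else "Inf"
    cat(sprintf("  %-8s deviation (%.1f, %s] ng/mL -> %d-%d%%\n",
                b$direction[i], b$dev_low[i], hi,
                round(100 * b$p_low[i]), round(100 * b$p_high[i])))
  }
  for (k in names(x$hold_thresholds))
    cat(sprintf("  hold for range %s at trough >= %.1f ng/mL (recheck %d-%d h)\n",
                k, x$hold_thresholds[[k]],
                x$recheck_window[1], x$recheck_window[2]))
  cat(sprintf("  dose increment %.1f mg, adherence margin %.1f mg\n",
              x$dose_increment, x$adherence_margin))
  invisible(x)
}

protocol_to_list <- function(protocol) {
  list(
    ranges = lapply(protocol$ranges, function(r) c(r$low, r$high)),
    bands = lapply(seq_len(nrow(protocol$bands)), function(i) {
      b <- protocol$bands[i, ]
      list(direction = b$direction,
           deviation = c(b$dev_low, b$dev_high),
           percent = c(b$p_low, b$p_high))
    }),
    hold_thresholds = as.list(protocol$hold_thresholds),
    recheck_window = protocol$recheck_window,
    dose_increment = protocol$dose_increment,
    adherence_margin = protocol$adherence_margin)
}

#' Read / write a protocol file
#'
#' Protocols are serialized as YAML (or JSON) with keys `ranges`, `bands`
#' (each with `direction`, `deviation`, `percent`), `hold_thresholds`,
#' `recheck_window`, `dose_increment` and `adherence_margin`. The shipped
#' default is installed at
#' `system.file("extdata", "default_protocol.yaml", package = "tacsim")`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_protocol()` returns a `tac_protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  ranges <- lapply(raw$ranges, function(v) {
    v <- as.numeric(unlist(v)); target_range(v[1], v[2])
  })
  bands <- do.call(rbind, lapply(raw$bands, function(b) {
    dev <- as.numeric(unlist(b$deviation))
    pct <- as.numeric(unlist(b$percent))
    # YAML has no Inf literal; accept .inf, "Inf" or null upper bound
    if (is.na(dev[2])) dev[2] <- Inf
    data.frame(direction = b$direction, dev_low = dev[1], dev_high = dev[2],
               p_low = pct[1], p_high = pct[2])
  }))
  tac_protocol(ranges, bands,
               hold_thresholds = unlist(raw$hold_thresholds),
               recheck_window = as.numeric(unlist(raw$recheck_window)),
               dose_increment = as.numeric(raw$dose_increment),
               adherence_margin = as.numeric(raw$adherence_margin))
}

#' @rdname read_protocol
#' @param protocol a `tac_protocol` to serialize.
#' @export
write_protocol <- function(protocol, path) {
  x <- protocol_to_list(protocol)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
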