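#' Windowed heart-rate variability from three R-R intervals
#'
#' HRV is the standard deviation of the three most recent R-R intervals
#' (RRIs), `sqrt(sum((x - mean(x))^2) / n)` with `n = 3` (population
#' divisor). The heart-rate monitor emits RRIs in packets of three beats,
#' so the window size is fixed at 3.
#'
#' @param window numeric vector of exactly 3 RRIs in milliseconds.
#' @param sd_type `"population"` (divisor `n`, default) or `"sample"`
#'   (divisor `n - 1`).
#' @param apply_sqrt take the square root (default `TRUE`, a true standard
#'   deviation); `FALSE` returns the mean squared deviation instead.
#' @return HRV in milliseconds (ms^2 when `apply_sqrt = FALSE`).
#' @export
#' @examples
#' hrv_from_window(c(800, 810, 790))  # sqrt(200/3) ~= 8.165
hrv_from_window <- function(window, sd_type = c("population", "sample"),
                            apply_sqrt = TRUE) {
  sd_type <- match.arg(sd_type)
  if (length(window) != 3 || !is.numeric(window)) {
    abort("`window` must contain exactly 3 RRIs.")
  }
  denom <- if (sd_type == "population") 3 else 2
  msd <- sum((window - mean(window))^2) / denom
  if (apply_sqrt) sqrt(msd) else msd
}

#' Homeostatic inversion of an HRV value
#'
#' The counterbalance transform: `mu_b_raw / hrv`, i.e. the reciprocal HRV
#' rescaled by the raw baseline mean so the result stays on the baseline's
#' scale. A zero HRV is clamped at `eps` to keep the inversion finite.
#'
#' @param hrv HRV value(s) in ms.
#' @param mu_b_raw mean of the raw baseline HRVs (> 0).
#' @param eps clamp for zero HRV, default `1e-6` ms.
#' @return Inverted HRV (same length as `hrv`).
#' @export
invert_hrv <- function(hrv, mu_b_raw, eps = 1e-6) {
  if (!is.numeric(mu_b_raw) || length(mu_b_raw) != 1 || mu_b_raw <= 0) {
    abort("`mu_b_raw` must be a single number > 0.")
  }
  mu_b_raw / pmax(hrv, eps)
}

#' Baseline statistics for HRV standardization
#'
#' Computes the mean and SD of a relaxed-state baseline window of HRV
#' values, against which task-time HRVs are standardized. By default the
#' 15th-64th HRV samples (1-based, inclusive: 50 values) of the baseline
#' session are used; the first 14 are discarded as settling time. In
#' counterbalance mode each baseline value is first inverted with
#' [invert_hrv()] (using the raw window mean), and the statistics are taken
#' on the inverted values; the raw mean is stored either way because the
#' task-time inversion needs it.
#'
#' @param hrvs numeric vector of baseline HRV values, at least
#'   `max(indices)` long.
#' @param mode `"sync"` or `"counterbalance"`.
#' @param indices which baseline samples form the window (default `15:64`).
#' @param sd_type divisor for the SD, `"population"` (default) or
#'   `"sample"`.
#' @return A `baseline_stats` object with fields `mu_b`, `sd_b`,
#'   `mu_b_raw`, `mode`, `n`.
#' @export
#' @examples
#' baseline_stats(rnorm(64, 25, 5), mode = "sync")
#' baseline_stats(c(8, 10, 12), mode = "sync", indices = 1:3)
baseline_stats <- function(hrvs, mode = c("sync", "counterbalance"),
                           indices = 15:64,
                           sd_type = c("population", "sample")) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  if (length(hrvs) < max(indices)) {
    abort(paste0("Need at least ", max(indices), " baseline HRV samples, got ",
                 length(hrvs), "."))
  }
  vals <- hrvs[indices]
  mu_raw <- mean(vals)
  if (mode == "counterbalance") {
    if (mu_raw <= 0) abort("Raw baseline mean must be > 0 to invert.")
    vals <- invert_hrv(vals, mu_raw)
  }
  sdev <- if (sd_type == "population") sd_pop(vals) else sd(vals)
  if (sdev == 0) abort("Degenerate baseline: zero HRV variance.")
  structure(
    list(mu_b = mean(vals), sd_b = sdev, mu_b_raw = mu_raw, mode = mode,
         n = length(vals)),
    class = "baseline_stats"
  )
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats mode=%s n=%d> mu_b=%.4f sd_b=%.4f mu_b_raw=%.4f\n",
              x$mode, x$n, x$mu_b, x$sd_b, x$mu_b_raw))
  invisible(x)
}

#' @rdname baseline_stats
#' @param x a `baseline_stats` object.
#' @param ... unused.
#' @method tidy baseline_stats
#' @export
tidy.baseline_stats <- function(x, ...) {
  tibble(mu_b = x$mu_b, sd_b = x$sd_b, mu_b_raw = x$mu_b_raw,
         mode = x$mode, n = x$n)
}

#' Standardize a value against baseline statistics
#'
#' The z-score `(value - mu_b) / sd_b` relative to the (possibly inverted)
#' baseline window.
#'
#' @param value HRV value(s), already inverted in counterbalance mode.
#' @param stats a [baseline_stats()] object.
#' @return z-score(s).
#' @export
standardize <- function(value, stats) {
  stopifnot(inherits(stats, "baseline_stats"))
  (value - stats$mu_b) / stats$sd_b
}

#' Map a z-score to the activation-noise scale
#'
#' `s = max(z + 0.5, 0)`: an offset of 0.5 so that baseline-level arousal
#' yields moderate noise, clipped at zero.
#'
#' @param z z-score(s).
#' @return Noise scale(s) `s >= 0`.
#' @export
noise_param <- function(z) {
  pmax(z + 0.5, 0)
}

#' Convert an RRI stream into a noise-parameter stream
#'
#' Splits the RRI stream into non-overlapping 3-beat packets (the monitor
#' sends one signal every three beats) and runs each packet through the
#' pipeline HRV -> (inversion, counterbalance mode only) -> z-score ->
#' noise scale. A trailing partial packet is dropped.
#'
#' @param rri a data frame with columns `time` (seconds) and `rri`
#'   (milliseconds, > 0); see [gen_rri_stream()] and [read_rri()].
#' @param stats a [baseline_stats()] object; its `mode` selects sync vs
#'   counterbalance processing.
#' @inheritParams hrv_from_window
#' @return A tibble with one row per packet: `time` (packet-end time),
#'   `hrv`, `transformed` (equals `hrv` in sync mode), `z`, `s`.
#' @export
process_stream <- function(rri, stats, sd_type = c("population", "sample"),
                           apply_sqrt = TRUE) {
  stopifnot(inherits(stats, "baseline_stats"))
  sd_type <- match.arg(sd_type)
  rri <- as_tibble(rri)
  stopifnot(all(c("time", "rri") %in% names(rri)))
  n_packets <- nrow(rri) %/% 3
  if (n_packets == 0) {
    return(tibble(time = numeric(), hrv = numeric(), transformed = numeric(),
                  z = numeric(), s = numeric()))
  }
  idx <- seq_len(n_packets * 3)
  packet <- rep(seq_len(n_packets), each = 3)
  hrv <- vapply(split(rri$rri[idx], packet), hrv_from_window,
                numeric(1), sd_type = sd_type, apply_sqrt = apply_sqrt)
  transformed <- if (stats$mode == "counterbalance") {
    invert_hrv(hrv, stats$mu_b_raw)
  } else {
    hrv
  }
  z <- standardize(transformed, stats)
  tibble(
    time = rri$time[idx][seq_len(n_packets) * 3],
    hrv = unname(hrv),
    transformed = unname(transformed),
    z = unname(z),
    s = noise_param(z)
  )
}

#' Baseline statistics straight from a baseline RRI stream
#'
#' Convenience wrapper: extracts packet HRVs from a (relaxed) baseline RRI
#' stream with the same 3-beat packetization as [process_stream()], then
#' calls [baseline_stats()] on them.
#'
#' @inheritParams process_stream
#' @inheritParams baseline_stats
#' @export
baseline_from_stream <- function(rri, mode = c("sync", "counterbalance"),
                                 indices = 15:64,
                                 sd_type = c("population", "sample")) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  rri <- as_tibble(rri)
  n_packets <- nrow(rri) %/% 3
  packet <- rep(seq_len(n_packets), each = 3)
  hrvs <- vapply(split(rri$rri[seq_len(n_packets * 3)], packet),
                 hrv_from_window, numeric(1), sd_type = sd_type)
  baseline_stats(unname(hrvs), mode = mode, indices = indices,
                 sd_type = sd_type)
}

#' Read and write RRI streams
#'
#' CSV has columns `time` (s) and `rri` (ms); JSONL has one
#' `{"time": ..., "rri": ...}` object per line.
#'
#' @param path file path; format chosen by extension (`.jsonl` vs `.csv`).
#' @return `read_rri()`: a tibble with columns `time`, `rri`.
#' @export
read_rri <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    rows <- jsonlite::stream_in(file(path), verbose = FALSE)
    return(tibble(time = as.numeric(rows$time), rri = as.numeric(rows$rri)))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(time = as.numeric(raw$time), rri = as.numeric(raw$rri))
}

#' @rdname read_rri
#' @param rri a tibble with columns `time`, `rri`.
#' @export
write_rri <- function(rri, path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(rri), con, verbose = FALSE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(rri), path, row.names = FALSE)
  }
  invisible(path)
}
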