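#' Generate a synthetic multi-week browsing log
#'
#' Emulates the product-visit logs the chunk store is built from: products
#' carry labels drawn with overlap from a shared pool (so attributes fan out
#' across chunks), and visit timestamps cluster around recurring time-period
#' centers, giving the X-means digitization structure to find.
#'
#' @param n_products number of distinct product images.
#' @param n_labels size of the shared label pool.
#' @param labels_per_product labels drawn (without replacement) per product;
#'   must not exceed `n_labels`.
#' @param visits_range integer range `c(lo, hi)` of visit counts per product.
#' @param period_centers absolute timestamps (seconds) of the visit-period
#'   centers; defaults to three weekly evening sessions starting at a fixed
#'   epoch.
#' @param visit_jitter_sd SD in seconds of visit times around their period
#'   center (default 1800, half an hour).
#' @param seed integer seed; generation is reproducible.
#' @return A record tibble (`image_id`, `labels`, `visit_times`) accepted by
#'   [build_store()].
#' @export
gen_browsing_log <- function(n_products = 30, n_labels = 12,
                             labels_per_product = 3,
                             visits_range = c(2, 12),
                             period_centers = 1.6e9 + c(0, 7, 14) * 86400,
                             visit_jitter_sd = 1800, seed = 1L) {
  if (n_products < 1 || n_labels < 1 || labels_per_product < 1) {
    abort("All counts must be >= 1.")
  }
  if (labels_per_product > n_labels) {
    abort("`labels_per_product` cannot exceed `n_labels`.")
  }
  if (length(visits_range) != 2 || visits_range[1] < 1 ||
      visits_range[2] < visits_range[1]) {
    abort("`visits_range` must be c(lo, hi) with 1 <= lo <= hi.")
  }
  pool <- sprintf("label_%02d", seq_len(n_labels))
  withr::with_seed(as.integer(seed), {
    tibble(
      image_id = sprintf("img_%03d", seq_len(n_products)),
      labels = purrr::map(seq_len(n_products),
                          ~ sort(sample(pool, labels_per_product))),
      visit_times = purrr::map(seq_len(n_products), function(i) {
        n_visits <- sample(seq(visits_range[1], visits_range[2]), 1)
        centers <- sample(period_centers, n_visits, replace = TRUE)
        sort(centers + rnorm(n_visits, 0, visit_jitter_sd))
      })
    )
  })
}

#' Generate a synthetic R-R interval stream
#'
#' Emulates the heart-rate monitor's beat-to-beat output under distinct
#' autonomic regimes. RRIs are `mean_rri` plus a slow sinusoid (respiratory
#' sinus arrhythmia, present only when relaxed) plus Gaussian jitter; times
#' accumulate beat by beat. The relaxed regime (parasympathetic dominance)
#' has large RRI fluctuation, hence high windowed HRV; the stressed regime
#' has small fluctuation and low HRV. `"induction_then_recovery"`
#' concatenates a stressed first half and a relaxed second half.
#'
#' @param kind `"relaxed"`, `"stressed"`, or `"induction_then_recovery"`.
#' @param duration stream length in seconds (default 300).
#' @param seed integer seed.
#' @param mean_rri mean RRI in ms; defaults 800 (relaxed) / 700 (stressed).
#' @param rri_jitter_sd Gaussian jitter SD in ms; defaults 30 (relaxed) /
#'   5 (stressed).
#' @param rsa_amplitude sinusoid amplitude in ms; defaults 20 (relaxed) /
#'   0 (stressed).
#' @param rsa_period sinusoid period in seconds (default 10, a slow
#'   breathing cycle).
#' @return A tibble with columns `time` (seconds, strictly increasing) and
#'   `rri` (ms, > 0).
#' @export
gen_rri_stream <- function(kind = c("relaxed", "stressed",
                                    "induction_then_recovery"),
                           duration = 300, seed = 1L,
                           mean_rri = NULL, rri_jitter_sd = NULL,
                           rsa_amplitude = NULL, rsa_period = 10) {
  kind <- match.arg(kind)
  if (kind == "induction_then_recovery") {
    first <- gen_rri_stream("stressed", duration / 2, seed = seed,
                            mean_rri = mean_rri, rri_jitter_sd = rri_jitter_sd,
                            rsa_amplitude = rsa_amplitude,
                            rsa_period = rsa_period)
    second <- gen_rri_stream("relaxed", duration / 2, seed = seed + 1L,
                             mean_rri = mean_rri, rri_jitter_sd = rri_jitter_sd,
                             rsa_amplitude = rsa_amplitude,
                             rsa_period = rsa_period)
    second$time <- second$time + max(first$time)
    return(bind_rows(first, second))
  }
  mean_rri <- mean_rri %||% if (kind == "relaxed") 800 else 700
  rri_jitter_sd <- rri_jitter_sd %||% if (kind == "relaxed") 30 else 5
  rsa_amplitude <- rsa_amplitude %||% if (kind == "relaxed") 20 else 0
  if (mean_rri <= 0 || rri_jitter_sd < 0) {
    abort("`mean_rri` must be > 0 and `rri_jitter_sd` >= 0.")
  }
  n_max <- ceiling(duration * 1000 / max(mean_rri - 4 * rri_jitter_sd, 200)) + 8
  withr::with_seed(as.integer(seed), {
    jitter <- rnorm(n_max, 0, rri_jitter_sd)
    t <- 0
    times <- numeric(n_max)
    rris <- numeric(n_max)
    n <- 0
    for (i in seq_len(n_max)) {
      rri <- mean_rri + rsa_amplitude * sin(2 * pi * t / rsa_period) + jitter[i]
      rri <- max(rri, 200)  # physiological floor
      t <- t + rri / 1000
      if (t > duration) break
      n <- n + 1
      times[n] <- t
      rris[n] <- rri
    }
    tibble(time = times[seq_len(n)], rri = rris[seq_len(n)])
  })
}
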