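#' Behavioral indices of a presentation log
#'
#' `count_switches()` counts consecutive tick pairs showing different images;
#' `unique_images()` counts distinct images shown; `summarize_session()`
#' returns both as a one-row tibble together with the session's mode and
#' seed. Because the model tends to re-present the same image (recency and
#' frequency effects), these two indices separate repetitive from diverse
#' sessions.
#'
#' @param log a `presentation_log` (or any data frame with an `image_id`
#'   column in presentation order).
#' @return `count_switches()`, `unique_images()`: an integer.
#' @export
#' @examples
#' ids <- tibble::tibble(image_id = c("a", "a", "b", "a"))
#' count_switches(ids)  # 2
#' unique_images(ids)   # 2
count_switches <- function(log) {
  ids <- log[["image_id"]]
  if (length(ids) == 0) abort("The presentation log is empty.")
  sum(head(ids, -1) != tail(ids, -1))
}

#' @rdname count_switches
#' @export
unique_images <- function(log) {
  ids <- log[["image_id"]]
  if (length(ids) == 0) abort("The presentation log is empty.")
  n_distinct(ids)
}

#' @rdname count_switches
#' @export
summarize_session <- function(log) {
  cfg <- attr(log, "config")
  tibble(
    total_switches = count_switches(log),
    unique_images = unique_images(log),
    mode = if (is.null(cfg)) NA_character_ else cfg$mode,
    seed = if (is.null(cfg)) NA_integer_ else cfg$seed
  )
}

# cache of combn index matrices keyed by "n1/N" (exact test enumeration)
.combn_cache <- new.env(parent = emptyenv())

combn_indices <- function(N, n1) {
  key <- paste0(n1, "/", N)
  if (is.null(.combn_cache[[key]])) .combn_cache[[key]] <- combn(N, n1)
  .combn_cache[[key]]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample location test on rank sums with midranks for ties. The
#' statistic is the sum of pooled ranks of `x`. For `n1 + n2 <= 12` (the
#' scale of a 12-participant study) the p-value is exact, by full
#' enumeration of all `choose(n1 + n2, n1)` group labelings of the pooled
#' sample; above that a normal approximation with tie correction (and
#' continuity correction) is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` (`x` shifted below
#'   `y`) or `"greater"`.
#' @param exact force exact enumeration (`TRUE`) or the normal approximation
#'   (`FALSE`); default `NULL` chooses exact iff `n1 + n2 <= 12`.
#' @param correct continuity correction in the normal approximation
#'   (default `TRUE`).
#' @return A `rank_sum_test` object with fields `statistic` (rank sum of
#'   `x`), `p_value`, `method`, `alternative`, `n1`, `n2`, `exact`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # p = 0.05
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact = NULL, correct = TRUE) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  use_exact <- exact %||% (N <= 12)

  if (use_exact) {
    combs <- combn_indices(N, n1)
    Wperm <- colSums(matrix(r[combs], nrow = n1))
    tol <- 1e-8
    p <- switch(alternative,
      greater   = mean(Wperm >= W - tol),
      less      = mean(Wperm <= W + tol),
      two.sided = mean(abs(Wperm - EW) >= abs(W - EW) - tol)
    )
    method <- "Exact Wilcoxon rank-sum test (full enumeration, midranks)"
  } else {
    ties <- table(r)
    varW <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (varW <= 0) abort("All observations tied: rank-sum variance is zero.")
    cc <- if (correct) 0.5 else 0
    p <- switch(alternative,
      greater   = pnorm((W - EW - cc) / sqrt(varW), lower.tail = FALSE),
      less      = pnorm((W - EW + cc) / sqrt(varW)),
      two.sided = {
        z <- (abs(W - EW) - cc) / sqrt(varW)
        min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
      }
    )
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  structure(
    list(statistic = W, p_value = p, method = method,
         alternative = alternative, n1 = n1, n2 = n2, exact = use_exact),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("W = %g, n1 = %d, n2 = %d, alternative = %s, p-value = %.4g\n",
              x$statistic, x$n1, x$n2, x$alternative, x$p_value))
  invisible(x)
}

#' Tidiers for rank-sum tests
#' @param x a `rank_sum_test`.
#' @param ... unused.
#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         alternative = x$alternative)
}

#' @rdname tidy.rank_sum_test
#' @method glance rank_sum_test
#' @export
glance.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n1 = x$n1, n2 = x$n2,
         exact = x$exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 pairs.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Spearman correlation is undefined for a constant vector.")
  }
  cor(rank(x), rank(y))
}

# asymptotic relative efficiency of the WMW test vs the t test, by assumed
# parent distribution; "min" is the conservative distribution-free bound
wmw_are <- c(min = 0.864, normal = 3 / pi, logistic = pi^2 / 9, laplace = 1.5)

#' Post-hoc power of a two-sample test
#'
#' Power to detect a standardized mean difference `d` at level `alpha` with
#' group sizes `n1`, `n2`, from the noncentral-t distribution. For
#' `method = "wmw_are"` (the Wilcoxon-Mann-Whitney test) both sample sizes
#' are first multiplied by the test's asymptotic relative efficiency versus
#' the t test — by default the conservative distribution-free minimum 0.864,
#' with the normal-parent value `3/pi`, logistic `pi^2/9` and Laplace `1.5`
#' selectable — before the noncentrality parameter and degrees of freedom
#' are formed. `method = "t_test"` is the plain two-sample t power.
#'
#' @param d standardized effect size (Cohen's d), >= 0.
#' @param n1,n2 group sizes, each >= 2.
#' @param alpha significance level in (0, 1).
#' @param method `"wmw_are"` (default) or `"t_test"`.
#' @param parent assumed parent distribution for the ARE correction.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return Power in `[0, 1]`; equals `alpha` at `d = 0` (two-sided).
#' @export
#' @examples
#' posthoc_power(d = 0.8, n1 = 6, n2 = 6, alpha = 0.10)  # about 0.32
posthoc_power <- function(d, n1, n2, alpha = 0.10,
                          method = c("wmw_are", "t_test"),
                          parent = c("min", "normal", "logistic", "laplace"),
                          alternative = c("two.sided", "one.sided")) {
  method <- match.arg(method)
  parent <- match.arg(parent)
  alternative <- match.arg(alternative)
  if (n1 < 2 || n2 < 2) abort("Both group sizes must be >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (d < 0) abort("`d` must be >= 0.")
  are <- if (method == "wmw_are") wmw_are[[parent]] else 1
  m1 <- n1 * are
  m2 <- n2 * are
  df <- m1 + m2 - 2
  ncp <- d * sqrt(m1 * m2 / (m1 + m2))
  if (alternative == "two.sided") {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Compare sync and counterbalance session cohorts
#'
#' The study-style group comparison on simulated cohorts: per-index medians,
#' two-sided Wilcoxon rank-sum p-values at the stated level (no
#' multiple-testing correction is applied, matching the uncorrected
#' alpha = 0.10 analysis convention — interpret the per-index p-values
#' accordingly), and the Spearman correlation matrix between indices over
#' all sessions pooled.
#'
#' @param summaries_sync,summaries_coun data frames of per-session summaries
#'   (see [summarize_session()]), each with >= 2 rows and the index columns
#'   `total_switches` and `unique_images`.
#' @param alpha significance level recorded in the report (default 0.10).
#' @return A `cohort_report` with fields `medians` (tibble index x arm),
#'   `tests` (tibble of per-index Wilcoxon results), `spearman` (matrix),
#'   `alpha`, `n_sync`, `n_coun`.
#' @export
compare_cohorts <- function(summaries_sync, summaries_coun, alpha = 0.10) {
  indices <- c("total_switches", "unique_images")
  sync <- as_tibble(summaries_sync)
  coun <- as_tibble(summaries_coun)
  if (nrow(sync) < 2 || nrow(coun) < 2) {
    abort("Each arm needs at least 2 session summaries.")
  }
  stopifnot(all(indices %in% names(sync)), all(indices %in% names(coun)))

  medians <- tibble(
    index = indices,
    sync_median = vapply(indices, function(i) median(sync[[i]]), numeric(1),
                         USE.NAMES = FALSE),
    counterbalance_median = vapply(indices, function(i) median(coun[[i]]),
                                   numeric(1), USE.NAMES = FALSE)
  )
  tests <- purrr::map_dfr(indices, function(i) {
    tst <- wilcoxon_rank_sum(sync[[i]], coun[[i]], alternative = "two.sided")
    tibble(index = i, statistic = tst$statistic, p_value = tst$p_value,
           significant = tst$p_value < alpha)
  })
  pooled <- bind_rows(sync[indices], coun[indices])
  rho <- matrix(NA_real_, 2, 2, dimnames = list(indices, indices))
  for (a in indices) for (b in indices) {
    rho[a, b] <- tryCatch(spearman_rho(pooled[[a]], pooled[[b]]),
                          error = function(e) NA_real_)
  }
  structure(
    list(medians = medians, tests = tests, spearman = rho, alpha = alpha,
         n_sync = nrow(sync), n_coun = nrow(coun)),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> sync n=%d vs counterbalance n=%d (alpha = %.2f)\n",
              x$n_sync, x$n_coun, x$alpha))
  cat("\nMedians:\n")
  print(as.data.frame(x$medians), row.names = FALSE)
  cat("\nWilcoxon rank-sum (two-sided):\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  cat("\nSpearman correlations (pooled sessions):\n")
  print(round(x$spearman, 3))
  invisible(x)
}

#' Tidiers for cohort reports
#' @param x a `cohort_report`.
#' @param ... unused.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  dplyr::left_join(x$medians, x$tests, by = "index")
}

#' @rdname tidy.cohort_report
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble(n_sync = x$n_sync, n_coun = x$n_coun, alpha = x$alpha,
         min_p_value = min(x$tests$p_value))
}

#' Serialize a cohort report to JSON and back
#'
#' @param report a `cohort_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  payload <- list(
    medians = report$medians,
    tests = report$tests,
    spearman = list(indices = rownames(report$spearman),
                    values = unname(report$spearman)),
    alpha = report$alpha, n_sync = report$n_sync, n_coun = report$n_coun
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path)
  rho <- as.matrix(raw$spearman$values)
  dimnames(rho) <- list(raw$spearman$indices, raw$spearman$indices)
  structure(
    list(medians = as_tibble(raw$medians), tests = as_tibble(raw$tests),
         spearman = rho, alpha = raw$alpha, n_sync = raw$n_sync,
         n_coun = raw$n_coun),
    class = "cohort_report"
  )
}
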