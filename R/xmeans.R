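#' BIC score of a one-dimensional clustering
#'
#' Schwarz criterion for a hard assignment of 1-D points to `k` clusters under
#' the identical-variance spherical-Gaussian model used by X-means model
#' selection: maximum-likelihood cluster means, a single pooled variance with
#' divisor `n - k`, and mixture weights `n_c / n`. Larger is better.
#'
#' @param x numeric vector of points.
#' @param labels integer (or factor) cluster assignment, one per point.
#' @return A single number: `loglik - p/2 * log(n)` with
#'   `p = 2k` free parameters (`k` means, `k - 1` weights, one shared
#'   variance). `-Inf` when the pooled variance is zero but `k < n`
#'   distinct points remain unexplained; `+Inf` never.
#' @export
#' @examples
#' x <- c(rnorm(20), rnorm(20, 10))
#' xmeans_bic(x, rep(1:2, each = 20)) > xmeans_bic(x, rep(1, 40))
xmeans_bic <- function(x, labels) {
  stopifnot(is.numeric(x), length(x) == length(labels))
  labels <- as.integer(as.factor(labels))
  n <- length(x)
  k <- max(labels)
  centers <- tapply(x, labels, mean)
  rss <- sum((x - centers[labels])^2)
  if (n <= k) return(-Inf)
  sigma2 <- rss / (n - k)
  if (sigma2 <= 0) {
    # zero-variance clustering: degenerate but a perfect fit; score it with a
    # variance floor tied to data scale so identical points never justify splits
    sigma2 <- max(abs(x), 1) * .Machine$double.eps
  }
  n_c <- tabulate(labels, nbins = k)
  loglik <- sum(n_c * log(n_c / n)) -
    n / 2 * log(2 * pi) - n / 2 * log(sigma2) - (n - k) / 2
  p <- 2 * k
  loglik - p / 2 * log(n)
}

# optimal 2-means split of a 1-D vector by exhaustive threshold search (the
# 1-D problem is solved exactly by a cut in sorted order, so Lloyd iteration
# is unnecessary); NULL when all points coincide
split_two <- function(x) {
  if (length(unique(x)) < 2) return(NULL)
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1)
  sse <- (cs2[i] - cs[i]^2 / i) +
    ((cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i))
  sse[xs[i] == xs[i + 1]] <- Inf  # never cut inside a tie group
  cut <- which.min(sse)
  child <- integer(n)
  child[o] <- ifelse(seq_len(n) <= cut, 1L, 2L)
  child
}

#' Digitize timestamps into periods by X-means clustering
#'
#' One-dimensional X-means: start from a single cluster and recursively test
#' 2-means splits, accepting a split when it improves the BIC of the
#' clustering restricted to the parent cluster ([xmeans_bic()]). Splitting
#' stops when no cluster's split improves its BIC or `k_max` clusters are
#' reached. Used to digitize browsing-visit timestamps into time-period
#' attributes.
#'
#' @param timestamps numeric vector of times in seconds (need not be sorted).
#' @param k_max maximum number of clusters (default 8).
#' @param seed integer seed; clustering is deterministic given the seed.
#' @return Integer vector of cluster labels, one per timestamp, relabelled
#'   `1..k` in increasing order of cluster center (label 1 is earliest).
#' @export
#' @examples
#' xmeans_periods(c(1, 2, 3, 1000, 1001, 1002), k_max = 8, seed = 1)
xmeans_periods <- function(timestamps, k_max = 8, seed = 1L) {
  if (!is.numeric(timestamps) || length(timestamps) == 0) {
    abort("`timestamps` must be a non-empty numeric vector.")
  }
  if (!is.numeric(k_max) || length(k_max) != 1 || k_max < 1) {
    abort("`k_max` must be a single integer >= 1.")
  }
  labels <- withr::with_seed(as.integer(seed), {
    clusters <- list(seq_along(timestamps))
    queue <- 1L
    while (length(queue) > 0 && length(clusters) < k_max) {
      ci <- queue[[1]]
      queue <- queue[-1]
      idx <- clusters[[ci]]
      xs <- timestamps[idx]
      child <- split_two(xs)
      if (is.null(child)) next
      bic_parent <- xmeans_bic(xs, rep(1L, length(xs)))
      bic_split <- xmeans_bic(xs, child)
      if (bic_split > bic_parent) {
        clusters[[ci]] <- idx[child == 1]
        clusters[[length(clusters) + 1]] <- idx[child == 2]
        queue <- c(queue, ci, length(clusters))
      }
    }
    out <- integer(length(timestamps))
    for (i in seq_along(clusters)) out[clusters[[i]]] <- i
    out
  })
  # relabel by ascending center so period 1 is the earliest
  centers <- tapply(timestamps, labels, mean)
  rank_of <- rank(centers, ties.method = "first")
  as.integer(rank_of[labels])
}
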