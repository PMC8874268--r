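#' Declarative-memory parameters
#'
#' Bundle of ACT-R subsymbolic parameters used by the retrieval equations.
#' The decay rate defaults to 0.05 and the per-chunk base-level offset to 0,
#' the settings under which recency/frequency effects dominate and looping
#' retrieval can emerge; the canonical ACT-R decay 0.5 is available by
#' argument.
#'
#' @param decay base-level decay rate `d` (> 0), default 0.05.
#' @param noise_s_default noise scale `s` used when no physiological signal
#'   is available (>= 0), default 0.5 (the value a baseline-level z-score of
#'   0 maps to).
#' @param mas maximum associative strength for spreading activation,
#'   default 2.
#' @param source_weight total source-activation weight `W` shared across
#'   context symbols, default 1.
#' @param time_floor smallest elapsed time in seconds used in the base-level
#'   sum (> 0), default 0.05; prevents a just-presented chunk from having
#'   infinite activation.
#' @param noise_dist `"gaussian"` (mean 0, variance `(pi/3) s^2`) or
#'   `"logistic"` (the canonical ACT-R logistic with scale `s`, variance
#'   `(pi^2/3) s^2`).
#' @return A `memory_params` list.
#' @export
memory_params <- function(decay = 0.05, noise_s_default = 0.5, mas = 2,
                          source_weight = 1, time_floor = 0.05,
                          noise_dist = c("gaussian", "logistic")) {
  noise_dist <- match.arg(noise_dist)
  if (decay <= 0) abort("`decay` must be > 0.")
  if (time_floor <= 0) abort("`time_floor` must be > 0.")
  if (noise_s_default < 0) abort("`noise_s_default` must be >= 0.")
  structure(
    list(decay = decay, noise_s_default = noise_s_default, mas = mas,
         source_weight = source_weight, time_floor = time_floor,
         noise_dist = noise_dist),
    class = "memory_params"
  )
}

#' Base-level activation of one chunk
#'
#' `B = ln(sum_j (now - t_j)^(-d)) + offset`, summing power-law decayed
#' traces over the chunk's occurrence history. Elapsed times are floored at
#' `params$time_floor`, so `now` may equal (or even precede) an occurrence
#' without producing a singularity.
#'
#' @param occurrences numeric vector of occurrence timestamps (seconds),
#'   non-empty.
#' @param now current time in seconds.
#' @param params a [memory_params()] bundle.
#' @param offset per-chunk offset (beta), default 0.
#' @return The base-level activation (a single number).
#' @export
#' @examples
#' base_level(0, now = 1)                       # single trace 1 s old: 0
#' base_level(c(-10, -100), now = 0)            # ~0.5222 at d = 0.05
base_level <- function(occurrences, now, params = memory_params(), offset = 0) {
  if (length(occurrences) == 0) {
    abort("A chunk with no occurrence history is unretrievable.")
  }
  elapsed <- pmax(now - occurrences, params$time_floor)
  log(sum(elapsed^(-params$decay))) + offset
}

#' Spreading activation from a retrieval context
#'
#' The ACT-R fan equation: every context symbol `j` that the chunk bears
#' contributes `(W / |context|) * max(mas - ln fan_j, 0)`, where `fan_j` is
#' the number of chunks in the store bearing `j`. Context symbols absent
#' from the chunk (or unknown to the store) contribute 0; an empty context
#' gives 0 exactly. Association strengths are floored at zero: sharing an
#' attribute with the context can only help a chunk, never penalize it,
#' which keeps the chunk whose own attributes form the context at maximal
#' spreading (the property that lets zero-noise retrieval settle into a
#' loop rather than a two-chunk oscillation).
#'
#' @param attributes character vector of the chunk's attribute symbols.
#' @param context character vector of source symbols.
#' @inheritParams base_level
#' @param store a `chunk_store` (source of the fan table).
#' @return Spreading activation (a single number).
#' @export
spreading <- function(attributes, context, store, params = memory_params()) {
  if (length(context) == 0) return(0)
  shared <- intersect(context, attributes)
  if (length(shared) == 0) return(0)
  fan <- attribute_fan(store, shared)
  keep <- fan >= 1
  if (!any(keep)) return(0)
  # association strengths are facilitative only: mas - ln(fan) is floored at
  # 0, so bearing a very common attribute never penalizes a chunk relative to
  # chunks that lack it (that regime produces spurious two-chunk oscillation
  # instead of the looping dynamics the zero-noise model is meant to show)
  strengths <- pmax(params$mas - log(fan[keep]), 0)
  sum((params$source_weight / length(context)) * strengths)
}

#' Draw activation noise
#'
#' Transient retrieval noise with scale parameter `s`: Gaussian with mean 0
#' and variance `(pi/3) s^2`, or the canonical ACT-R logistic with scale `s`
#' (variance `(pi^2/3) s^2`). `s = 0` returns exact zeros without consuming
#' random numbers.
#'
#' @param s noise scale, >= 0.
#' @param n number of draws.
#' @inheritParams base_level
#' @return Numeric vector of length `n`.
#' @export
sample_noise <- function(s, n = 1, params = memory_params()) {
  if (length(s) != 1 || !is.finite(s) || s < 0) {
    abort("`s` must be a single finite number >= 0.")
  }
  if (s == 0) return(rep(0, n))
  switch(params$noise_dist,
    gaussian = rnorm(n, mean = 0, sd = sqrt(pi / 3) * s),
    logistic = rlogis(n, location = 0, scale = s)
  )
}

#' Activation profile of every chunk in a store
#'
#' Computes, for each chunk, the base-level, spreading and noise components
#' and their total at time `now` under noise scale `s`. This is the
#' enumeration that [retrieve()] takes the argmax of.
#'
#' @inheritParams spreading
#' @param now current time (seconds).
#' @param s noise scale in force.
#' @return A tibble with one row per chunk: `image_id`, `base_level`,
#'   `spreading`, `noise`, `total` (exactly the sum of the three parts).
#' @export
activation_profile <- function(store, context = character(), s = 0, now,
                               params = memory_params()) {
  stopifnot(inherits(store, "chunk_store"))
  ch <- store$chunks
  if (nrow(ch) == 0) abort("The chunk store is empty.")
  b <- purrr::map2_dbl(ch$occurrences, ch$offset,
                       ~ base_level(.x, now, params, offset = .y))
  sp <- purrr::map_dbl(ch$attributes, ~ spreading(.x, context, store, params))
  eps <- sample_noise(s, n = nrow(ch), params = params)
  tibble(image_id = ch$image_id, base_level = b, spreading = sp,
         noise = eps, total = b + sp + eps)
}

#' Retrieve the most active chunk
#'
#' Computes the activation of every chunk (base-level + spreading + noise)
#' and returns the maximum. There is no retrieval threshold: retrieval always
#' succeeds. Ties are broken toward the lexicographically smallest
#' `image_id` (chunks are stored sorted by id).
#'
#' @inheritParams activation_profile
#' @return A one-row tibble (a retrieval event): `time`, `image_id`,
#'   `base_level`, `spreading`, `noise`, `total`, `s_in_force`.
#' @export
retrieve <- function(store, context = character(), s = 0, now,
                     params = memory_params()) {
  prof <- activation_profile(store, context, s, now, params)
  winner <- which.max(prof$total)  # first max: smallest id wins ties
  tibble(
    time = now,
    image_id = prof$image_id[winner],
    base_level = prof$base_level[winner],
    spreading = prof$spreading[winner],
    noise = prof$noise[winner],
    total = prof$total[winner],
    s_in_force = s
  )
}

#' Reinforce a chunk with a new occurrence
#'
#' Appends `now` to the chunk's occurrence history (presentation counts as a
#' rehearsal), raising its subsequent base-level activation. The fan table is
#' unchanged.
#'
#' @inheritParams spreading
#' @param image_id id of the chunk to reinforce.
#' @param now occurrence timestamp (seconds).
#' @return The updated `chunk_store`.
#' @export
reinforce <- function(store, image_id, now) {
  stopifnot(inherits(store, "chunk_store"))
  i <- match(image_id, store$chunks$image_id)
  if (is.na(i)) abort(paste0("Unknown chunk id: ", image_id))
  store$chunks$occurrences[[i]] <- c(store$chunks$occurrences[[i]], now)
  store
}
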