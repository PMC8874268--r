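#' Session configuration
#'
#' Settings for one closed-loop browsing session: a 15-minute task with the
#' presented image refreshed every 5 seconds by default.
#'
#' @param duration session length in seconds (default 900).
#' @param tick refresh interval in seconds (default 5); the session runs
#'   `floor(duration / tick)` ticks.
#' @param mode `"sync"` or `"counterbalance"`; recorded for bookkeeping (the
#'   mode acts through the `baseline_stats` used to produce the `s` stream).
#' @param seed integer seed; sessions are bit-identical given config + seed.
#' @param context_policy `"chain"` (the retrieved chunk's attributes become
#'   the next retrieval's spreading sources, the default associative-chain
#'   behavior) or `"empty"` (spreading disabled, for ablation).
#' @return A `session_config` list.
#' @export
session_config <- function(duration = 900, tick = 5,
                           mode = c("sync", "counterbalance"), seed = 1L,
                           context_policy = c("chain", "empty")) {
  mode <- match.arg(mode)
  context_policy <- match.arg(context_policy)
  if (duration <= 0 || tick <= 0) abort("`duration` and `tick` must be > 0.")
  if (floor(duration / tick) < 1) abort("`duration` must cover at least one tick.")
  structure(
    list(duration = duration, tick = tick, mode = mode,
         seed = as.integer(seed), context_policy = context_policy),
    class = "session_config"
  )
}

#' Run one closed-loop presentation session
#'
#' Simulates the 5-second refresh loop: at each tick the engine looks up the
#' noise scale `s` from the most recent HRV packet, retrieves the most active
#' chunk under that noise, logs the presentation, reinforces the presented
#' chunk (a presentation is a rehearsal), and — under the `"chain"` context
#' policy — seeds the next retrieval's spreading activation with the
#' presented chunk's attributes.
#'
#' Two clocks are involved. Store occurrences live on an absolute (unix-like)
#' clock; the session clock starts one second after the store's latest
#' occurrence, so the logged browsing history is strictly in the past.
#' `hrv_samples$time` is interpreted as seconds since session start
#' (session-relative, matching how [process_stream()] output of a
#' task-time RRI stream is indexed): the `s` in force at session-relative
#' time `tau` is that of the latest sample with `time <= tau`, sample-and-
#' hold, or `params$noise_s_default` before the first sample (or when
#' `hrv_samples` is `NULL`).
#'
#' @param store a `chunk_store`; it is copied, the caller's store is not
#'   modified.
#' @param hrv_samples output of [process_stream()] (columns `time`, `s`), or
#'   `NULL` for a fixed noise scale.
#' @param config a [session_config()].
#' @param params a [memory_params()] bundle.
#' @return A `presentation_log`: a tibble with one row per tick (`tick`,
#'   `time` absolute seconds, `session_time`, `image_id`, `base_level`,
#'   `spreading`, `noise`, `total`, `s_in_force`) carrying the config as an
#'   attribute, plus attribute `final_store` (the reinforced store).
#' @export
run_session <- function(store, hrv_samples = NULL, config = session_config(),
                        params = memory_params()) {
  stopifnot(inherits(store, "chunk_store"), inherits(config, "session_config"))
  if (nrow(store$chunks) == 0) abort("The chunk store is empty.")
  if (!is.null(hrv_samples)) {
    stopifnot(all(c("time", "s") %in% names(hrv_samples)))
    hrv_samples <- dplyr::arrange(as_tibble(hrv_samples), .data$time)
  }
  n_ticks <- floor(config$duration / config$tick)
  t0 <- max(unlist(store$chunks$occurrences)) + 1

  events <- withr::with_seed(config$seed, {
    context <- character()
    out <- vector("list", n_ticks)
    for (k in seq_len(n_ticks)) {
      tau <- (k - 1) * config$tick
      now <- t0 + tau
      s_now <- params$noise_s_default
      if (!is.null(hrv_samples) && nrow(hrv_samples) > 0) {
        ready <- hrv_samples$time <= tau
        if (any(ready)) s_now <- hrv_samples$s[max(which(ready))]
      }
      ev <- retrieve(store, context, s = s_now, now = now, params = params)
      store <- reinforce(store, ev$image_id, now)
      if (config$context_policy == "chain") {
        i <- match(ev$image_id, store$chunks$image_id)
        context <- store$chunks$attributes[[i]]
      }
      out[[k]] <- mutate(ev, tick = k, session_time = tau)
    }
    bind_rows(out)
  })

  log <- events %>%
    select("tick", "time", "session_time", "image_id", "base_level",
           "spreading", "noise", "total", "s_in_force")
  log <- new_tibble(log, config = config, final_store = store,
                    class = "presentation_log")
  log
}

#' @export
print.presentation_log <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<presentation_log> %d ticks, tick=%gs, mode=%s, seed=%d\n",
              nrow(x), cfg$tick, cfg$mode, cfg$seed))
  NextMethod()
}

#' Read and write presentation logs
#'
#' JSONL: the first line is an object with field `config`, then one object
#' per tick with fields `tick`, `time`, `session_time`, `image_id`,
#' `base_level`, `spreading`, `noise`, `total`, `s_in_force`.
#'
#' @param log a `presentation_log`.
#' @param path file path (`.jsonl`).
#' @return `read_presentation_log()` returns a `presentation_log` (without
#'   the final store); `write_presentation_log()` returns `path` invisibly.
#' @export
write_presentation_log <- function(log, path) {
  cfg <- attr(log, "config")
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(config = unclass(cfg)), auto_unbox = TRUE,
                              digits = NA), con)
  jsonlite::stream_out(as.data.frame(log), con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_presentation_log
#' @export
read_presentation_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[[1]])
  rows <- jsonlite::stream_in(textConnection(lines[-1]), verbose = FALSE)
  cfg <- do.call(session_config, header$config[
    c("duration", "tick", "mode", "seed", "context_policy")])
  new_tibble(as_tibble(rows), config = cfg, final_store = NULL,
             class = "presentation_log")
}
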