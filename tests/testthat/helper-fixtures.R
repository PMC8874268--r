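# small record sets and stores used across test files

make_records <- function(n = 3, base = 1000) {
  tibble::tibble(
    image_id = sprintf("img_%02d", seq_len(n)),
    labels = purrr::map(seq_len(n), ~ c("shoe", sprintf("tag_%d", .x))),
    visit_times = purrr::map(seq_len(n), ~ base + .x * 10 + c(0, 5, 20))
  )
}

# two chunks sharing "shoe"; ids chosen so "a" < "b" for tie-break checks
two_chunk_store <- function(visits_a = c(-10, -100), visits_b = -1,
                            now0 = 0) {
  build_store(tibble::tibble(
    image_id = c("a", "b"),
    labels = list("shoe", "shoe"),
    visit_times = list(now0 + visits_a, now0 + visits_b)
  ), seed = 1)
}

# per-session switch counts for a cohort of seeds under one mode
cohort_switches <- function(seeds, store_seed, mode, baseline, stream_seed_off = 100) {
  vapply(seeds, function(k) {
    store <- build_store(gen_browsing_log(seed = store_seed), seed = store_seed)
    stressed <- gen_rri_stream("stressed", duration = 900, seed = k + stream_seed_off)
    sam <- process_stream(stressed, baseline)
    log <- run_session(store, sam, session_config(mode = mode, seed = k))
    count_switches(log)
  }, numeric(1))
}
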