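test_that("base-level activation matches direct arithmetic", {
  p <- memory_params()
  # single trace exactly 1 s old: ln(1^-d) = 0 for any d
  expect_equal(base_level(0, now = 1, params = p), 0)
  expect_equal(base_level(0, now = 1, params = memory_params(decay = 0.5)), 0)
  # traces 10 s and 100 s old at d = 0.05
  expect_equal(base_level(c(-10, -100), now = 0, params = p),
               log(10^-0.05 + 100^-0.05), tolerance = 1e-12)
  expect_equal(round(base_level(c(-10, -100), now = 0, params = p), 4), 0.5221)
  # offset shifts additively
  expect_equal(base_level(c(-10, -100), now = 0, params = p, offset = 1.5),
               log(10^-0.05 + 100^-0.05) + 1.5)
  expect_error(base_level(numeric(0), now = 0), "unretrievable")
})

test_that("appending an occurrence strictly increases base-level activation", {
  p <- memory_params()
  occ <- c(-500, -100, -20)
  for (extra in c(-400, -1, 0)) {
    expect_gt(base_level(c(occ, extra), now = 0, params = p),
              base_level(occ, now = 0, params = p))
  }
})

test_that("the elapsed-time floor prevents singularities at now = t_j", {
  p <- memory_params(time_floor = 0.05)
  b <- base_level(10, now = 10, params = p)
  expect_true(is.finite(b))
  expect_equal(b, log(0.05^-0.05))
})

test_that("spreading follows the fan equation with hand-computed values", {
  store <- two_chunk_store()
  p <- memory_params()  # mas = 2, W = 1
  a_attrs <- store$chunks$attributes[[1]]
  # fan("shoe") = 2: contribution 2 - ln 2
  expect_equal(spreading(a_attrs, "shoe", store, p), 2 - log(2))
  expect_equal(round(spreading(a_attrs, "shoe", store, p), 4), 1.3069)
  # empty context and disjoint context contribute nothing
  expect_equal(spreading(a_attrs, character(0), store, p), 0)
  expect_equal(spreading(a_attrs, "hat", store, p), 0)
  # W is split across context symbols: unknown symbol halves the share
  expect_equal(spreading(a_attrs, c("shoe", "unknown"), store, p),
               (2 - log(2)) / 2)
})

test_that("association strengths never go negative at high fan", {
  recs <- tibble::tibble(
    image_id = sprintf("c%02d", 1:10),
    labels = purrr::map(1:10, ~"common"),
    visit_times = purrr::map(1:10, ~ as.numeric(.x))
  )
  store <- build_store(recs, seed = 1)
  p <- memory_params()  # mas = 2 < ln(10)
  sp <- spreading(store$chunks$attributes[[1]], "common", store, p)
  expect_equal(sp, 0)  # floored, not 2 - ln 10 < 0
})

test_that("noise is zero at s = 0 and has variance (pi/3) s^2", {
  expect_identical(sample_noise(0, n = 5), rep(0, 5))
  expect_error(sample_noise(-1), "s")
  set.seed(101)
  draws <- sample_noise(1, n = 1e5)
  expect_equal(var(draws), pi / 3, tolerance = 0.03)
  expect_lt(abs(mean(draws)), 0.02)
  # scale enters as s^2 in the variance
  set.seed(102)
  expect_equal(var(sample_noise(2, n = 1e5)), 4 * pi / 3, tolerance = 0.03)
})

test_that("the logistic noise variant has canonical variance (pi^2/3) s^2", {
  p <- memory_params(noise_dist = "logistic")
  set.seed(103)
  draws <- sample_noise(1, n = 1e5, params = p)
  expect_equal(var(draws), pi^2 / 3, tolerance = 0.03)
})

test_that("retrieval returns the activation argmax with exact breakdown", {
  store <- two_chunk_store(visits_a = c(-10, -100), visits_b = -1)
  p <- memory_params()
  # s = 0, empty context: B_a ~ 0.5222 beats B_b = 0
  ev <- retrieve(store, character(0), s = 0, now = 0, params = p)
  expect_equal(ev$image_id, "a")
  expect_equal(ev$total, ev$base_level + ev$spreading + ev$noise)
  expect_equal(ev$noise, 0)
  # single-chunk store returns its chunk under any s
  single <- build_store(tibble::tibble(image_id = "solo", labels = list("x"),
                                       visit_times = list(-5)), seed = 1)
  set.seed(1)
  expect_equal(retrieve(single, s = 4, now = 0)$image_id, "solo")
  expect_error(retrieve(structure(list(chunks = tibble::tibble()),
                                  class = "chunk_store"), now = 0), "empty")
})

test_that("ties at s = 0 break toward the lexicographically smallest id", {
  store <- two_chunk_store(visits_a = -7, visits_b = -7)
  ev <- retrieve(store, character(0), s = 0, now = 0)
  expect_equal(ev$image_id, "a")
})

test_that("s = 0 retrieval matches brute-force enumeration and ignores the seed", {
  p <- memory_params()
  for (n in 2:5) {
    store <- build_store(make_records(n, base = -200), seed = n)
    ctx <- c("shoe", "tag_1")
    prof <- activation_profile(store, ctx, s = 0, now = 0, params = p)
    manual <- vapply(seq_len(n), function(i) {
      base_level(store$chunks$occurrences[[i]], 0, p) +
        spreading(store$chunks$attributes[[i]], ctx, store, p)
    }, numeric(1))
    expect_equal(prof$total, manual)
    set.seed(1); pick1 <- retrieve(store, ctx, s = 0, now = 0, params = p)
    set.seed(999); pick2 <- retrieve(store, ctx, s = 0, now = 0, params = p)
    expect_identical(pick1, pick2)
    expect_equal(pick1$image_id, store$chunks$image_id[which.max(manual)])
  }
})

test_that("reinforce counts and monotonicity", {
  store <- two_chunk_store(visits_a = c(-30, -20, -10))
  p <- memory_params()
  expect_equal(lengths(store$chunks$occurrences)[1], 3L)
  b_before <- base_level(store$chunks$occurrences[[1]], now = 1, params = p)
  store2 <- reinforce(store, "a", now = 0)
  expect_equal(lengths(store2$chunks$occurrences)[1], 4L)
  b_after <- base_level(store2$chunks$occurrences[[1]], now = 1, params = p)
  expect_gt(b_after, b_before)
  # k reinforcements at distinct times grow n by k
  s <- store
  for (t in 1:5) s <- reinforce(s, "b", now = t)
  expect_equal(lengths(s$chunks$occurrences)[2],
               lengths(store$chunks$occurrences)[2] + 5L)
  expect_error(reinforce(store, "nope", 0), "nope")
})

test_that("zero-noise self-reinforcing retrieval locks onto one chunk", {
  store <- build_store(make_records(5, base = -1000), seed = 3)
  p <- memory_params()
  ids <- character(40)
  for (k in seq_len(40)) {
    ev <- retrieve(store, character(0), s = 0, now = k * 5, params = p)
    store <- reinforce(store, ev$image_id, k * 5)
    ids[k] <- ev$image_id
  }
  expect_equal(length(unique(tail(ids, 30))), 1)
})

test_that("retrieval shares flatten monotonically as s grows", {
  store <- two_chunk_store(visits_a = c(-10, -100), visits_b = -1)
  p <- memory_params()
  gap <- vapply(c(0.5, 1, 2, 4), function(s) {
    set.seed(500 + s * 10)
    picks <- vapply(seq_len(1e4), function(i) {
      retrieve(store, character(0), s = s, now = 0, params = p)$image_id
    }, character(1))
    share <- mean(picks == "a")
    expect_gt(min(share, 1 - share), 0)  # both chunks retrieved at s >= 0.5
    abs(2 * share - 1)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})
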