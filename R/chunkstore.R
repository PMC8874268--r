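#' Build a declarative-memory chunk store from browsing records
#'
#' Converts per-image browsing records into an ACT-R-style declarative memory:
#' one chunk per image, whose symbolic attributes are the image's labels plus
#' a `"period_k"` symbol for the time-of-visit cluster found by
#' [xmeans_periods()] on the pooled visit timestamps. The store also carries
#' the fan table (how many chunks bear each attribute) used by spreading
#' activation.
#'
#' A record whose visits fall in several time clusters receives the period of
#' its modal cluster; ties are broken toward the earlier (lower-numbered)
#' period.
#'
#' @param records a data frame with columns `image_id` (character, unique),
#'   `labels` (list-column of character vectors, may be empty), and
#'   `visit_times` (list-column of numeric timestamps in seconds, non-empty).
#'   See [gen_browsing_log()] and [read_browsing_log()].
#' @param k_max maximum number of time-period clusters (default 8).
#' @param seed integer seed for the clustering step.
#' @return A `chunk_store` object: a list with
#'   \describe{
#'     \item{chunks}{tibble with columns `image_id`, `attributes`
#'       (list-column of symbols), `occurrences` (list-column of sorted
#'       timestamps), `offset` (per-chunk base-level offset, 0 by default).}
#'     \item{fan}{tibble with columns `attribute`, `fan` (number of chunks
#'       bearing the attribute).}
#'   }
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   image_id = c("a", "b"),
#'   labels = list(c("shoe", "red"), "shoe"),
#'   visit_times = list(c(100, 200), 150)
#' )
#' store <- build_store(recs, seed = 1)
#' glance(store)
build_store <- function(records, k_max = 8, seed = 1L) {
  records <- as_tibble(records)
  required <- c("image_id", "labels", "visit_times")
  if (!all(required %in% names(records)) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame with columns image_id, labels, visit_times.")
  }
  dup <- records$image_id[duplicated(records$image_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate image_id in records: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(lengths(records$visit_times) == 0)) {
    abort("Every record must have at least one visit time.")
  }

  all_times <- unlist(records$visit_times, use.names = FALSE)
  period <- xmeans_periods(all_times, k_max = k_max, seed = seed)
  period_of <- split(period, rep(seq_len(nrow(records)), lengths(records$visit_times)))

  modal_period <- vapply(period_of, function(p) {
    tab <- tabulate(p)
    which.max(tab)  # ties toward the earlier period
  }, integer(1))

  chunks <- tibble(
    image_id = as.character(records$image_id),
    attributes = purrr::map2(
      records$labels, modal_period,
      ~ sort(unique(c(as.character(.x), paste0("period_", .y))))
    ),
    occurrences = purrr::map(records$visit_times, ~ sort(as.numeric(.x))),
    offset = 0
  ) %>% arrange(.data$image_id)

  new_chunk_store(chunks)
}

new_chunk_store <- function(chunks) {
  structure(list(chunks = chunks, fan = compute_fan(chunks)), class = "chunk_store")
}

compute_fan <- function(chunks) {
  tibble(attribute = unlist(chunks$attributes, use.names = FALSE)) %>%
    count(.data$attribute, name = "fan") %>%
    arrange(.data$attribute)
}

#' @export
print.chunk_store <- function(x, ...) {
  cat("<chunk_store>", nrow(x$chunks), "chunks,",
      nrow(x$fan), "attributes,",
      sum(lengths(x$chunks$occurrences)), "occurrences\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn build_store number of chunks bearing a given attribute (0 when absent).
#' @param store a `chunk_store`.
#' @param attribute attribute symbol(s).
#' @export
attribute_fan <- function(store, attribute) {
  stopifnot(inherits(store, "chunk_store"))
  idx <- match(attribute, store$fan$attribute)
  out <- store$fan$fan[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Tidiers for chunk stores
#'
#' `tidy()` returns one row per chunk with occurrence counts and collapsed
#' attributes; `glance()` returns one-row store totals.
#'
#' @param x a `chunk_store`.
#' @param ... unused.
#' @method tidy chunk_store
#' @export
tidy.chunk_store <- function(x, ...) {
  tibble(
    image_id = x$chunks$image_id,
    n_occurrences = lengths(x$chunks$occurrences),
    first_visit = vapply(x$chunks$occurrences, min, numeric(1)),
    last_visit = vapply(x$chunks$occurrences, max, numeric(1)),
    attributes = vapply(x$chunks$attributes, paste, character(1), collapse = ";")
  )
}

#' @rdname tidy.chunk_store
#' @method glance chunk_store
#' @export
glance.chunk_store <- function(x, ...) {
  tibble(
    n_chunks = nrow(x$chunks),
    n_attributes = nrow(x$fan),
    total_occurrences = sum(lengths(x$chunks$occurrences)),
    n_periods = sum(startsWith(x$fan$attribute, "period_"))
  )
}

#' Read and write browsing-history logs
#'
#' The CSV layout has one row per visit with columns `image_id`,
#' `label_list` (semicolon-separated labels) and `visit_time` (seconds);
#' the JSON layout is an array of records with fields `image_id`, `labels`
#' and `visit_times`. Both readers return the record tibble accepted by
#' [build_store()].
#'
#' @param path file path; format chosen by extension (`.csv` vs `.json`).
#' @return `read_browsing_log()`: a tibble with columns `image_id`, `labels`
#'   (list), `visit_times` (list).
#' @export
read_browsing_log <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    return(tibble(
      image_id = as.character(recs$image_id),
      labels = purrr::map(recs$labels, as.character),
      visit_times = purrr::map(recs$visit_times, as.numeric)
    ))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "label_list", "visit_time") %in% names(raw)))
  raw %>%
    as_tibble() %>%
    group_by(.data$image_id) %>%
    summarise(
      labels = list(sort(unique(unlist(strsplit(.data$label_list[.data$label_list != ""], ";", fixed = TRUE))))),
      visit_times = list(sort(as.numeric(.data$visit_time))),
      .groups = "drop"
    ) %>%
    mutate(
      image_id = as.character(.data$image_id),
      labels = purrr::map(.data$labels, ~ if (is.null(.x)) character(0) else .x)
    )
}

#' @rdname read_browsing_log
#' @param records a record tibble (see [build_store()]).
#' @export
write_browsing_log <- function(records, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      purrr::pmap(records, function(image_id, labels, visit_times, ...) {
        list(image_id = image_id, labels = as.list(as.character(labels)),
             visit_times = as.numeric(visit_times))
      }),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    rows <- tidyr::unnest(
      records %>% mutate(label_list = purrr::map_chr(.data$labels, paste, collapse = ";")),
      "visit_times"
    )
    utils::write.csv(
      data.frame(image_id = rows$image_id, label_list = rows$label_list,
                 visit_time = rows$visit_times),
      path, row.names = FALSE
    )
  }
  invisible(path)
}

#' Serialize a chunk store to JSON and back
#'
#' @param store a `chunk_store`.
#' @param path file path.
#' @return `read_store()` returns a `chunk_store`; `write_store()` returns
#'   `path` invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "chunk_store"))
  payload <- purrr::pmap(store$chunks, function(image_id, attributes, occurrences, offset) {
    list(image_id = image_id, attributes = as.list(attributes),
         occurrences = as.numeric(occurrences), offset = offset)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  chunks <- tibble(
    image_id = as.character(raw$image_id),
    attributes = purrr::map(raw$attributes, as.character),
    occurrences = purrr::map(raw$occurrences, as.numeric),
    offset = as.numeric(raw$offset)
  ) %>% arrange(.data$image_id)
  new_chunk_store(chunks)
}
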