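#' Configuration for candidate enhancer module detection
#'
#' @param window_length Sliding-window length in nucleotides (default 200,
#'   the "approximately 200-nucleotide interval" scale).
#' @param clusters_per_region Maximum number of modules reported per region
#'   (default 3).
#' @param min_distinct_tfs Minimum number of distinct transcription factor
#'   classes a window must contain to qualify (default 2).
#' @param trim_to_span If `TRUE` (default) report each module as the minimal
#'   interval covering its member hits rather than the full search window.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(window_length = 200, clusters_per_region = 3,
                           min_distinct_tfs = 2, trim_to_span = TRUE) {
  stopifnot(
    window_length >= 1, clusters_per_region >= 1, min_distinct_tfs >= 1,
    is.logical(trim_to_span)
  )
  structure(
    list(
      window_length = as.integer(window_length),
      clusters_per_region = as.integer(clusters_per_region),
      min_distinct_tfs = as.integer(min_distinct_tfs),
      trim_to_span = isTRUE(trim_to_span)
    ),
    class = "cluster_config"
  )
}

overlaps_any <- function(start, end, intervals) {
  if (length(intervals) == 0) {
    return(rep(FALSE, length(start)))
  }
  out <- rep(FALSE, length(start))
  for (iv in intervals) {
    out <- out | (start <= iv[2] & end >= iv[1])
  }
  out
}

#' Best window of binding sites in one region
#'
#' Finds the window of the given length containing the greatest number of
#' (collapsed) binding sites among windows spanning at least
#' `min_distinct_tfs` distinct factor classes. A hit is inside a window iff
#' its full span is contained; hits overlapping an excluded interval are not
#' available. Equal-count ties break to the leftmost (most distal) window.
#'
#' @param hits Collapsed hit tibble from one region.
#' @param window_length Window length in nt.
#' @param excluded List of `c(start, end)` intervals already claimed by
#'   higher-ranked modules.
#' @param min_distinct_tfs Qualification threshold on distinct classes.
#' @return `NULL` when no window qualifies, otherwise a list with `interval`
#'   (`c(start, end)` of the search window) and `hits` (the member rows).
#' @export
best_window <- function(hits, window_length = 200, excluded = list(),
                        min_distinct_tfs = 2) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    return(NULL)
  }
  hits <- hits[!overlaps_any(hits$start, hits$end, excluded), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(NULL)
  }
  w <- as.integer(window_length)
  # the objective only changes where a hit enters or leaves the window,
  # so those offsets (clipped to >= 1) are the only candidates
  candidates <- sort(unique(pmax(
    1L, c(1L, hits$end - w + 1L, hits$start + 1L)
  )))
  best <- NULL
  for (s in candidates) {
    inside <- hits$start >= s & hits$end <= s + w - 1L
    n <- sum(inside)
    if (n == 0) next
    if (length(unique(hits$tf_class[inside])) < min_distinct_tfs) next
    if (is.null(best) || n > best$n) {
      best <- list(n = n, s = s, inside = inside)
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  list(
    interval = c(best$s, best$s + w - 1L),
    hits = hits[best$inside, , drop = FALSE]
  )
}

find_modules_one <- function(hits, config) {
  region_id <- hits$region_id[1]
  excluded <- list()
  rows <- list()
  for (rank in seq_len(config$clusters_per_region)) {
    win <- best_window(hits, config$window_length, excluded,
      config$min_distinct_tfs
    )
    if (is.null(win)) break
    members <- win$hits
    interval <- if (config$trim_to_span) {
      c(min(members$start), max(members$end))
    } else {
      win$interval
    }
    rows[[rank]] <- tibble::tibble(
      region_id = region_id,
      rank = rank,
      start = as.integer(interval[1]),
      end = as.integer(interval[2]),
      n_sites = nrow(members),
      n_distinct_tfs = length(unique(members$tf_class)),
      tf_roster = paste(sort(unique(members$tf_class)), collapse = ","),
      member_hits = list(members)
    )
    excluded <- c(excluded, list(win$interval))
  }
  if (length(rows) == 0) {
    return(empty_modules())
  }
  dplyr::bind_rows(rows)
}

#' Detect candidate enhancer modules
#'
#' Greedy top-k selection per region: the qualifying window with the most
#' collapsed binding sites is taken first, its search window is excluded,
#' and the process repeats until `clusters_per_region` modules are found or
#' no window qualifies. Reported intervals of one region never overlap.
#'
#' @param hits Collapsed hit tibble (one or more regions; modules are found
#'   per region).
#' @param config A [cluster_config()].
#' @return A tibble with one row per module: `region_id`, `rank`, `start`,
#'   `end`, `n_sites`, `n_distinct_tfs`, `tf_roster` and a `member_hits`
#'   list-column.
#' @export
find_modules <- function(hits, config = cluster_config()) {
  stopifnot(is.data.frame(hits), inherits(config, "cluster_config"))
  if (nrow(hits) == 0) {
    return(empty_modules())
  }
  hits |>
    dplyr::group_split(.data$region_id) |>
    purrr::map(find_modules_one, config = config) |>
    dplyr::bind_rows()
}

empty_modules <- function() {
  tibble::tibble(
    region_id = character(), rank = integer(), start = integer(),
    end = integer(), n_sites = integer(), n_distinct_tfs = integer(),
    tf_roster = character(), member_hits = list()
  )
}

#' Summarize detected modules across a study
#'
#' @param modules A module tibble from [find_modules()].
#' @param region_ids Optional character vector of all analyzed regions, so
#'   regions with zero modules still appear with count 0.
#' @return A `module_summary` object: `total_modules`, `n_regions`, and a
#'   `per_region` tibble (module count, total sites, distinct-TF union).
#' @export
summarize_modules <- function(modules, region_ids = NULL) {
  stopifnot(is.data.frame(modules))
  if (is.null(region_ids)) {
    region_ids <- unique(modules$region_id)
  }
  per_region <- tibble::tibble(region_id = region_ids) |>
    dplyr::left_join(
      modules |>
        dplyr::group_by(.data$region_id) |>
        dplyr::summarise(
          n_modules = dplyr::n(),
          n_sites = sum(.data$n_sites),
          distinct_tfs = length(unique(unlist(
            strsplit(.data$tf_roster, ",", fixed = TRUE)
          ))),
          .groups = "drop"
        ),
      by = "region_id"
    ) |>
    tidyr::replace_na(list(n_modules = 0L, n_sites = 0L, distinct_tfs = 0L))
  structure(
    list(
      total_modules = nrow(modules),
      n_regions = length(region_ids),
      per_region = per_region
    ),
    class = "module_summary"
  )
}

#' @export
print.module_summary <- function(x, ...) {
  cat(sprintf(
    "%d candidate enhancer modules across %d upstream regions\n",
    x$total_modules, x$n_regions
  ))
  print(x$per_region)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-region module counts
#'
#' @param x A `module_summary`.
#' @param ... Unused.
#' @return The per-region tibble.
#' @method tidy module_summary
#' @export
tidy.module_summary <- function(x, ...) {
  x$per_region
}

#' One-row study-level summary
#'
#' @param x A `module_summary`.
#' @param ... Unused.
#' @method glance module_summary
#' @export
glance.module_summary <- function(x, ...) {
  tibble::tibble(
    total_modules = x$total_modules,
    n_regions = x$n_regions,
    mean_modules_per_region = if (x$n_regions > 0) {
      x$total_modules / x$n_regions
    } else {
      NA_real_
    }
  )
}

#' Write modules as BED and as a readable TSV
#'
#' BED uses the 0-based half-open convention (`bed_start = start - 1`,
#' `bed_end = end`), `name = region_id.rank`, score = member site count, and
#' a trailing comma-separated factor roster column.
#'
#' @param modules A module tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modules_bed <- function(modules, path) {
  bed <- tibble::tibble(
    chrom = modules$region_id,
    chromStart = modules$start - 1L,
    chromEnd = modules$end,
    name = paste0(modules$region_id, ".", modules$rank),
    score = modules$n_sites,
    strand = ".",
    roster = modules$tf_roster
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_modules_bed
#' @export
write_modules_tsv <- function(modules, path) {
  readr::write_tsv(
    modules[, c("region_id", "rank", "start", "end", "n_sites",
                "n_distinct_tfs", "tf_roster")],
    path
  )
  invisible(path)
}

#' @rdname write_modules_bed
#' @export
read_modules_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      region_id = readr::col_character(),
      rank = readr::col_integer(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      n_sites = readr::col_integer(),
      n_distinct_tfs = readr::col_integer(),
      tf_roster = readr::col_character()
    ),
    progress = FALSE
  )
}
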