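HIT_COLUMNS <- c(
  "region_id", "tf_class", "start", "end", "strand",
  "matched_seq", "dissimilarity_percent", "pattern"
)

empty_hits <- function() {
  tibble::tibble(
    region_id = character(), tf_class = character(),
    start = integer(), end = integer(), strand = character(),
    matched_seq = character(), dissimilarity_percent = double(),
    pattern = character()
  )
}

# Mismatch counts of one pattern against every window of a character vector.
# Returns an integer vector of length n - L + 1 (empty if the sequence is
# shorter than the pattern). A base outside the pattern's IUPAC class at a
# position counts 1; N in the sequence belongs to no class and never matches.
pattern_mismatch_counts <- function(chars, pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(pc)
  n <- length(chars)
  if (n < L) {
    return(integer(0))
  }
  counts <- integer(n - L + 1)
  for (j in seq_len(L)) {
    counts <- counts + !(chars[j:(n - L + j)] %in% IUPAC_CODES[[pc[j]]])
  }
  counts
}

scan_one_pattern <- function(chars, tf_class, pattern, threshold, region_id) {
  L <- nchar(pattern)
  rc <- reverse_complement(pattern)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else rc
    counts <- pattern_mismatch_counts(chars, pat)
    # integer comparison: k mismatches allowed iff 100k <= threshold * L
    ok <- which(counts * 100 <= threshold * L + 1e-9)
    if (length(ok) > 0) {
      rows[[strand]] <- tibble::tibble(
        region_id = region_id,
        tf_class = tf_class,
        start = as.integer(ok),
        end = as.integer(ok + L - 1),
        strand = strand,
        matched_seq = vapply(
          ok, function(s) paste0(chars[s:(s + L - 1)], collapse = ""),
          character(1)
        ),
        dissimilarity_percent = 100 * counts[ok] / L,
        pattern = pattern
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Scan one upstream region for catalog binding sites
#'
#' Every window of every pattern length is tested on both strands; windows at
#' or below the catalog's dissimilarity threshold are reported as hits with
#' 1-based inclusive coordinates on the forward strand (position 1 is the
#' most distal base of the upstream window). `N` bases never match any
#' pattern position. A reverse-strand match of the same pattern and class
#' over the identical span (a palindrome) is reported once, on `+`.
#'
#' @param sequence A nucleotide string over A/C/G/T/N (case-insensitive).
#' @param catalog A [pigment_catalog()]-style motif catalog.
#' @param region_id Identifier recorded in the hit table.
#' @return A tibble of hits with columns `region_id`, `tf_class`, `start`,
#'   `end`, `strand`, `matched_seq`, `dissimilarity_percent`, `pattern`,
#'   sorted by (start, end, tf_class).
#' @examples
#' scan_region("AAAATGACGTCAAAAA", pigment_catalog(), region_id = "demo")
#' @export
scan_region <- function(sequence, catalog = pigment_catalog(),
                        region_id = "region") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid base '%s' at position %d in region '%s'",
      chars[bad[1]], bad[1], region_id
    ), call. = FALSE)
  }
  threshold <- catalog_threshold(catalog)
  hits <- purrr::pmap(
    list(catalog$tf_class, catalog$pattern),
    function(tf_class, pattern) {
      scan_one_pattern(chars, tf_class, pattern, threshold, region_id)
    }
  )
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    return(empty_hits())
  }
  # palindromic / two-orientation duplicates: one record per
  # (class, pattern, span), forward strand preferred
  hits <- hits |>
    dplyr::arrange(
      .data$start, .data$end, .data$tf_class, .data$pattern,
      .data$dissimilarity_percent, .data$strand
    ) |>
    dplyr::distinct(
      .data$tf_class, .data$pattern, .data$start, .data$end,
      .keep_all = TRUE
    )
  hits[, HIT_COLUMNS]
}

#' Scan a table of upstream regions
#'
#' Data-frame-first wrapper around [scan_region()]: one row per region in,
#' one row per hit out.
#'
#' @param regions A data frame with columns `region_id` and `sequence`
#'   (as returned by [read_regions()] or [generate_study()]).
#' @param catalog A motif catalog.
#' @return A tibble of hits across all regions.
#' @export
scan_regions <- function(regions, catalog = pigment_catalog()) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "sequence") %in% names(regions)))
  purrr::map2(
    regions$region_id, regions$sequence,
    function(id, seq) scan_region(seq, catalog, region_id = id)
  ) |>
    dplyr::bind_rows()
}

#' Collapse matrix-level matches into one site class per factor
#'
#' Matrix libraries represent each version of a factor's binding site as a
#' separate entry, so one genomic site typically produces several
#' overlapping hits of the same class. Overlapping hits (>= 1 shared base)
#' of the same class are collapsed to a single representative: lowest
#' dissimilarity, then leftmost, then longest. Hits of different classes are
#' never merged, even at the identical span — overlap between factors is
#' biology, not redundancy.
#'
#' @param hits A hit tibble from one region.
#' @return The collapsed hit tibble, sorted by (start, end, tf_class).
#' @export
collapse_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    return(empty_hits())
  }
  if (dplyr::n_distinct(hits$region_id) > 1) {
    stop("`collapse_hits()` expects hits from a single region; got ",
      dplyr::n_distinct(hits$region_id), " region ids",
      call. = FALSE
    )
  }
  hits |>
    dplyr::group_by(.data$tf_class) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(
      cluster = cumsum(
        .data$start > dplyr::lag(cummax(.data$end), default = -1L) + 0L
      )
    ) |>
    dplyr::group_by(.data$tf_class, .data$cluster) |>
    dplyr::arrange(
      .data$dissimilarity_percent, .data$start, -(.data$end - .data$start),
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$start, .data$end, .data$tf_class)
}

#' Write / read the binding-site hit table TSV
#'
#' Lossless round-trip of all hit fields. The reader validates every row
#' (coordinates, strand, span/pattern length agreement) and reports the
#' offending line; extra trailing columns in externally produced tables are
#' ignored.
#'
#' @param hits A hit tibble.
#' @param path File path.
#' @return `read_hit_table()` returns the hit tibble; `write_hit_table()`
#'   returns `path` invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  readr::write_tsv(hits[, HIT_COLUMNS], path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(HIT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("hit table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- raw[, HIT_COLUMNS]
  hits <- tibble::tibble(
    region_id = raw$region_id,
    tf_class = raw$tf_class,
    start = suppressWarnings(as.integer(raw$start)),
    end = suppressWarnings(as.integer(raw$end)),
    strand = raw$strand,
    matched_seq = raw$matched_seq,
    dissimilarity_percent = suppressWarnings(as.double(raw$dissimilarity_percent)),
    pattern = raw$pattern
  )
  bad_row <- function(cond) {
    line <- which(cond)[1] + 1L # header is line 1
    stop(sprintf("malformed hit table row at line %d of %s", line, path),
      call. = FALSE
    )
  }
  if (anyNA(hits$start) || anyNA(hits$end)) {
    bad_row(is.na(hits$start) | is.na(hits$end))
  }
  if (any(hits$start < 1 | hits$end < hits$start)) {
    bad_row(hits$start < 1 | hits$end < hits$start)
  }
  if (any(!hits$strand %in% c("+", "-"))) {
    bad_row(!hits$strand %in% c("+", "-"))
  }
  if (anyNA(hits$dissimilarity_percent) ||
      any(hits$dissimilarity_percent < 0 | hits$dissimilarity_percent > 100)) {
    bad_row(is.na(hits$dissimilarity_percent) |
              hits$dissimilarity_percent < 0 | hits$dissimilarity_percent > 100)
  }
  if (any(hits$end - hits$start + 1L != nchar(hits$pattern))) {
    bad_row(hits$end - hits$start + 1L != nchar(hits$pattern))
  }
  hits
}

#' Read / write upstream regions as FASTA
#'
#' @param path FASTA file path; record ids are taken as region ids.
#' @return `read_regions()` returns a tibble with `region_id`, `sequence`,
#'   `length`.
#' @export
read_regions <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    region_id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set)),
    length = Biostrings::width(set)
  )
}

#' @rdname read_regions
#' @param regions Tibble with `region_id` and `sequence`.
#' @export
write_regions <- function(regions, path) {
  stopifnot(all(c("region_id", "sequence") %in% names(regions)))
  set <- Biostrings::DNAStringSet(regions$sequence)
  names(set) <- regions$region_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
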