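#' The six pigmentation transcription factor classes
#'
#' CREB, FOXD3, LEF1, MITF, POU3F2 and USF1 — the melanocyte network factors
#' whose binding sites are scanned for in upstream regions.
#'
#' @return Character vector of the six class names.
#' @export
tf_classes <- function() {
  c("CREB", "FOXD3", "LEF1", "MITF", "POU3F2", "USF1")
}

#' Display color for each transcription factor class
#'
#' The fixed color scheme used throughout the module visualization: CREB is
#' green, FOXD3 magenta, LEF1 orange, MITF blue, POU3F2 red and USF1 purple.
#'
#' @return Named character vector mapping class to color name.
#' @export
tf_colors <- function() {
  c(
    CREB = "green", FOXD3 = "magenta", LEF1 = "orange",
    MITF = "blue", POU3F2 = "red", USF1 = "purple"
  )
}

#' Color of one transcription factor class
#'
#' @param tf A transcription factor class name.
#' @return The color name for that class.
#' @examples
#' color_of("MITF")
#' @export
color_of <- function(tf) {
  cols <- tf_colors()
  if (!is.character(tf) || length(tf) != 1 || !tf %in% names(cols)) {
    stop(sprintf("unknown transcription factor class '%s'", as.character(tf)[1]),
      call. = FALSE
    )
  }
  unname(cols[[tf]])
}

new_motif_catalog <- function(motifs, max_dissimilarity) {
  stopifnot(is.numeric(max_dissimilarity), max_dissimilarity >= 0,
            max_dissimilarity <= 100)
  motifs <- tibble::as_tibble(motifs)
  motifs$pattern <- unname(vapply(motifs$pattern, parse_iupac, character(1)))
  structure(motifs,
    class = c("motif_catalog", class(motifs)),
    max_dissimilarity = max_dissimilarity
  )
}

#' Maximum dissimilarity threshold of a catalog
#'
#' @param catalog A motif catalog tibble.
#' @return The percent threshold (default 15) below or at which a window
#'   counts as a binding site.
#' @export
catalog_threshold <- function(catalog) {
  thr <- attr(catalog, "max_dissimilarity")
  if (is.null(thr)) 15 else thr
}

#' The compiled pigmentation motif catalog
#'
#' Literature-compiled consensus binding sequences for the six pigmentation
#' transcription factors, one row per (class, pattern). MITF carries the
#' E-box/M-box family plus eleven individually reported sites; USF1 shares
#' the E-box cores; CREB, POU3F2 and LEF1 carry their reported promoter
#' sites. No binding sequence is reported for FOXD3 in the compiled table,
#' so it carries a generic forkhead-core placeholder (`RTAAAYA`) flagged
#' `is_paper_sourced = FALSE`; replace it via `foxd3_pattern`.
#'
#' @param max_dissimilarity Percent dissimilarity threshold; default 15.
#' @param include_sox10 Also include the SOX10 patterns compiled from the
#'   same literature. SOX10 is not part of the scanned six-factor set, so
#'   they are off by default.
#' @param foxd3_pattern IUPAC pattern to use for FOXD3 instead of the
#'   placeholder, or `NULL` to keep it.
#' @return A `motif_catalog` tibble with columns `tf_class`, `pattern`,
#'   `source_label`, `is_paper_sourced` and a `max_dissimilarity` attribute.
#' @examples
#' cat6 <- pigment_catalog()
#' table(cat6$tf_class)
#' @export
pigment_catalog <- function(max_dissimilarity = 15, include_sox10 = FALSE,
                            foxd3_pattern = NULL) {
  path <- system.file("extdata", "motif_catalog.tsv", package = "enhancerscan",
    mustWork = TRUE
  )
  motifs <- read_catalog_tsv(path)
  if (!include_sox10) {
    motifs <- motifs[motifs$tf_class %in% tf_classes(), , drop = FALSE]
  }
  if (!is.null(foxd3_pattern)) {
    foxd3_pattern <- parse_iupac(foxd3_pattern)
    motifs$pattern[motifs$tf_class == "FOXD3"] <- foxd3_pattern
    motifs$source_label[motifs$tf_class == "FOXD3"] <- "user-supplied FOXD3 pattern"
    motifs$is_paper_sourced[motifs$tf_class == "FOXD3"] <- FALSE
  }
  new_motif_catalog(motifs, max_dissimilarity)
}

read_catalog_tsv <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      tf_class = readr::col_character(),
      pattern = readr::col_character(),
      source_label = readr::col_character(),
      is_paper_sourced = readr::col_logical()
    ),
    progress = FALSE
  )
}

#' Read / write a motif catalog TSV
#'
#' The on-disk form is a four-column TSV (`tf_class`, `pattern`,
#' `source_label`, `is_paper_sourced`); patterns are validated on read.
#'
#' @param path File path.
#' @param max_dissimilarity Threshold to attach on read.
#' @return `read_catalog()` returns a `motif_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path, max_dissimilarity = 15) {
  new_motif_catalog(read_catalog_tsv(path), max_dissimilarity)
}

#' @rdname read_catalog
#' @param catalog A motif catalog.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(
    tibble::as_tibble(catalog)[, c("tf_class", "pattern", "source_label",
                                   "is_paper_sourced")],
    path
  )
  invisible(path)
}
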