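# IUPAC nucleotide alphabet: each code names the set of concrete bases it stands for.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Validate and normalize an IUPAC consensus pattern
#'
#' Consensus binding sequences are expressed in the single-letter IUPAC
#' degenerate nucleotide alphabet (e.g. `N` = any base, `W` = A or T). The
#' pattern is upper-cased and every character checked against the alphabet.
#'
#' @param pattern A single non-empty string.
#' @return The normalized (upper-case) pattern string.
#' @examples
#' parse_iupac("caNNtg")
#' @export
parse_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern) ||
      nchar(pattern) == 0) {
    stop("`pattern` must be a single non-empty string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid IUPAC code '%s' at position %d in pattern '%s'",
      chars[bad[1]], bad[1], pattern
    ), call. = FALSE)
  }
  pattern
}

#' Number of concrete sequences matching an IUPAC pattern
#'
#' @param pattern An IUPAC pattern string.
#' @return The product of per-position degeneracy counts.
#' @export
iupac_cardinality <- function(pattern) {
  pattern <- parse_iupac(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  prod(vapply(chars, function(ch) length(IUPAC_CODES[[ch]]), numeric(1)))
}

#' Expand an IUPAC pattern into every matching concrete sequence
#'
#' @param pattern An IUPAC pattern string.
#' @param cap Refuse to expand patterns with more than this many concrete
#'   sequences (guards against runaway degeneracy).
#' @return Character vector of A/C/G/T sequences, in lexicographic position
#'   order of the degenerate choices.
#' @examples
#' expand_iupac("CANNTG")
#' @export
expand_iupac <- function(pattern, cap = 65536) {
  pattern <- parse_iupac(pattern)
  card <- iupac_cardinality(pattern)
  if (card > cap) {
    stop(sprintf(
      "expansion of '%s' has cardinality %.0f, exceeding cap %.0f",
      pattern, card, cap
    ), call. = FALSE)
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- lapply(chars, function(ch) IUPAC_CODES[[ch]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste0, collapse = "")
}

#' Percent dissimilarity of a concrete window against an IUPAC pattern
#'
#' The score is the percentage of positions at which the window base does not
#' belong to the pattern's IUPAC class at that position: a license-free
#' analogue of a matrix dissimilarity rate. 0 means the window is a perfect
#' instance of the consensus.
#'
#' @param pattern An IUPAC pattern (the reference).
#' @param window A concrete nucleotide string of the same length.
#' @return Percent in \[0, 100\].
#' @examples
#' dissimilarity("CANNTG", "CATGTG") # 0
#' dissimilarity("CANNTG", "CATGTA") # 100/6
#' @export
dissimilarity <- function(pattern, window) {
  pattern <- parse_iupac(pattern)
  if (!is.character(window) || length(window) != 1 || is.na(window)) {
    stop("`window` must be a single string", call. = FALSE)
  }
  window <- toupper(window)
  if (nchar(window) != nchar(pattern)) {
    stop(sprintf(
      "window length %d does not match pattern length %d",
      nchar(window), nchar(pattern)
    ), call. = FALSE)
  }
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  mism <- sum(vapply(
    seq_along(pc),
    function(i) !(wc[i] %in% IUPAC_CODES[[pc[i]]]),
    logical(1)
  ))
  100 * mism / length(pc)
}

#' Reverse complement of a nucleotide string
#'
#' Supports the full IUPAC alphabet so degenerate patterns can be scanned on
#' the reverse strand.
#'
#' @param seq A nucleotide string (IUPAC alphabet).
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("ATGCAAAT") # "ATTTGCAT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    stop("`seq` must be a single string", call. = FALSE)
  }
  chars <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop(sprintf("invalid base '%s' in sequence", chars[bad[1]]), call. = FALSE)
  }
  paste0(IUPAC_COMPLEMENT[chars], collapse = "")
}
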