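# Independent oracles used to cross-check the scanner and the greedy window
# selection. They deliberately take the naive route: expand every pattern to
# its concrete sequences and compare substrings by Hamming distance, and
# enumerate every window offset exhaustively.

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all hits of one catalog over a sequence, by brute force expansion:
# a window is a hit iff its Hamming distance to the NEAREST concrete
# expansion is within the threshold (equivalently, counting positions whose
# base falls outside the pattern's IUPAC class)
naive_scan_oracle <- function(sequence, catalog) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  threshold <- catalog_threshold(catalog)
  rows <- list()
  for (r in seq_len(nrow(catalog))) {
    pattern <- catalog$pattern[r]
    L <- nchar(pattern)
    if (n < L) next
    fwd <- expand_iupac(pattern)
    rev <- vapply(fwd, reverse_complement, character(1))
    for (s in seq_len(n - L + 1)) {
      win <- substr(sequence, s, s + L - 1)
      d_fwd <- min(vapply(fwd, hamming, numeric(1), b = win))
      d_rev <- min(vapply(rev, hamming, numeric(1), b = win))
      for (strand in c("+", "-")) {
        d <- if (strand == "+") d_fwd else d_rev
        if (100 * d <= threshold * L + 1e-9) {
          rows[[length(rows) + 1]] <- data.frame(
            tf_class = catalog$tf_class[r], pattern = pattern,
            start = s, end = s + L - 1, strand = strand,
            dissimilarity_percent = 100 * d / L,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      tf_class = character(), pattern = character(), start = integer(),
      end = integer(), strand = character(),
      dissimilarity_percent = double()
    ))
  }
  # mirror the scanner's palindromic-span rule: one record per
  # (class, pattern, span), forward preferred
  out <- out[order(out$start, out$end, out$tf_class, out$pattern, out$strand), ]
  out[!duplicated(out[, c("tf_class", "pattern", "start", "end")]), ]
}

# maximum member count over every window offset, restricted to windows with
# >= min_tfs distinct classes; returns the count and the leftmost offset
brute_best_window <- function(hits, window_length, min_tfs = 2) {
  if (nrow(hits) == 0) {
    return(NULL)
  }
  best <- NULL
  for (s in seq_len(max(hits$end))) {
    inside <- hits$start >= s & hits$end <= s + window_length - 1
    if (!any(inside)) next
    if (length(unique(hits$tf_class[inside])) < min_tfs) next
    n <- sum(inside)
    if (is.null(best) || n > best$n) best <- list(n = n, s = s)
  }
  best
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

make_hits <- function(starts, classes, len = 8, region_id = "r1") {
  tibble::tibble(
    region_id = region_id,
    tf_class = classes,
    start = as.integer(starts),
    end = as.integer(starts + len - 1),
    strand = "+",
    matched_seq = strrep("A", len),
    dissimilarity_percent = 0,
    pattern = strrep("N", len)
  )
}
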