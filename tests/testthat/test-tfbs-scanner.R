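test_that("scan_region locates a planted CREB site once despite palindromy", {
  hits <- scan_region("AAAATGACGTCAAAAA", pigment_catalog(), "demo")
  creb <- hits[hits$tf_class == "CREB", ]
  expect_equal(nrow(creb), 1)
  expect_equal(creb$start, 5L)
  expect_equal(creb$end, 12L)
  expect_equal(creb$strand, "+")
  expect_equal(creb$dissimilarity_percent, 0)
  expect_equal(creb$matched_seq, "TGACGTCA")
})

test_that("scan_region handles degenerate inputs", {
  expect_error(scan_region("", pigment_catalog()), "non-empty")
  expect_error(scan_region("ACGTQ", pigment_catalog()), "invalid base")
  # shorter than every pattern: empty result, not an error
  expect_equal(nrow(scan_region("ACGT", pigment_catalog())), 0)
  # poly-A matches nothing in the catalog
  expect_equal(nrow(scan_region(strrep("A", 1500), pigment_catalog())), 0)
  # N never matches: the E-box instance is destroyed by a single N
  expect_true(nrow(scan_region("CCCCATGTGCCC", pigment_catalog())) > 0)
  expect_equal(nrow(scan_region("CCCCATGTNCCC", pigment_catalog())), 0)
})

test_that("a planted POU3F2 octamer is reported exactly at its offset", {
  seq <- paste0(strrep("C", 40), "ATGCAAAT", strrep("C", 40))
  hits <- scan_region(seq, pigment_catalog(), "r")
  pou <- hits[hits$tf_class == "POU3F2" & hits$dissimilarity_percent == 0, ]
  expect_equal(pou$start, 41L)
  expect_equal(pou$end, 48L)
})

test_that("scanner agrees with the naive expand-and-match oracle", {
  cat6 <- pigment_catalog()
  set.seed(101)
  sequences <- c(
    replicate(8, random_dna(sample(30:200, 1))),
    paste0(strrep("A", 20), "CATGTG", strrep("G", 20), "TGACGTCA", strrep("T", 20)),
    strrep("CATG", 30) # overlapping E-box tiling
  )
  for (seq in sequences) {
    got <- scan_region(seq, cat6, "r")
    want <- naive_scan_oracle(seq, cat6)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$tf_class, want$tf_class)
    expect_equal(got$pattern, want$pattern)
    expect_equal(got$dissimilarity_percent, want$dissimilarity_percent)
  }
})

test_that("prepending background shifts hits by exactly the prefix length", {
  cat6 <- pigment_catalog()
  set.seed(33)
  for (i in 1:5) {
    seq <- random_dna(300)
    k <- sample(5:50, 1)
    prefix <- random_dna(k)
    base <- scan_region(seq, cat6, "r")
    shifted <- scan_region(paste0(prefix, seq), cat6, "r")
    # every window that lies past the junction comes from the original
    # sequence, so those hits are the originals shifted by k
    past <- shifted[shifted$start > k, ]
    expect_equal(past$start, base$start + k)
    expect_equal(past$end, base$end + k)
    expect_equal(past$tf_class, base$tf_class)
    expect_equal(past$pattern, base$pattern)
  }
})

test_that("collapse merges same-class overlaps but never cross-class ones", {
  # one E-box: MITF is hit through several patterns, USF1 through CATGTG;
  # collapse keeps one MITF and one USF1
  hits <- scan_region("CCCCATGTGCCC", pigment_catalog(), "r")
  expect_gt(sum(hits$tf_class == "MITF"), 1)
  collapsed <- collapse_hits(hits)
  expect_equal(sum(collapsed$tf_class == "MITF"), 1)
  expect_equal(sum(collapsed$tf_class == "USF1"), 1)
  expect_equal(collapsed$dissimilarity_percent[collapsed$tf_class == "MITF"], 0)

  expect_equal(nrow(collapse_hits(hits[0, ])), 0)
  mixed <- rbind(hits, transform(hits, region_id = "other"))
  expect_error(collapse_hits(mixed), "single region")
})

test_that("collapse is idempotent and picks the best representative", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    hits <- make_hits(
      starts = sample(1:300, n, replace = TRUE),
      classes = sample(tf_classes(), n, replace = TRUE),
      len = sample(6:11, 1)
    )
    hits$dissimilarity_percent <- sample(c(0, 9.1, 12.5), n, replace = TRUE)
    once <- collapse_hits(hits)
    twice <- collapse_hits(once)
    expect_equal(twice, once)
    # survivors of one class never overlap
    for (cl in unique(once$tf_class)) {
      h <- once[once$tf_class == cl, ]
      if (nrow(h) > 1) {
        h <- h[order(h$start), ]
        expect_true(all(h$start[-1] > h$end[-nrow(h)]))
      }
    }
  }
})

test_that("hit tables round-trip and the reader validates rows", {
  hits <- scan_region(paste0(strrep("A", 30), "CACGTG", strrep("A", 30)),
    pigment_catalog(), "r1"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  back <- read_hit_table(path)
  expect_equal(back, hits)

  # extra trailing columns are tolerated
  lines <- readLines(path)
  writeLines(paste0(lines, c("\tnote", rep("\textra", length(lines) - 1))), path)
  expect_equal(read_hit_table(path)$start, hits$start)

  # end < start is rejected with the line number
  bad <- hits
  bad$end[1] <- bad$start[1] - 5L
  write_hit_table(bad, path)
  expect_error(read_hit_table(path), "line 2")
})

test_that("regions round-trip through FASTA", {
  regions <- tibble::tibble(
    region_id = c("TYR", "DCT"),
    sequence = c(random_dna(120), random_dna(80))
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_regions(regions, path)
  back <- read_regions(path)
  expect_equal(back$region_id, regions$region_id)
  expect_equal(back$sequence, regions$sequence)
  expect_equal(back$length, nchar(regions$sequence))
})
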