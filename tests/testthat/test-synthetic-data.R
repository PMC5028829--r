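tiny_spec <- function(seed = 1) {
  plant_spec(
    region_id = "toy", region_length = 900,
    windows = tibble::tibble(window = 1:2, start = c(101L, 511L),
                             end = c(300L, 710L)),
    sites = tibble::tibble(
      window = c(1L, 1L, 2L, 2L),
      tf_class = c("CREB", "POU3F2", "LEF1", "USF1"),
      pattern = c("TGACGTCA", "ATGCAAAT", "CTTTGAT", "CACGTG"),
      offset = c(5L, 120L, 10L, 150L)
    ),
    seed = seed
  )
}

test_that("plant_spec enforces its structural invariants", {
  expect_s3_class(tiny_spec(), "plant_spec")
  # windows too close together
  expect_error(
    plant_spec("x", 900,
      windows = tibble::tibble(window = 1:2, start = c(101L, 350L),
                               end = c(300L, 549L)),
      sites = tibble::tibble(window = c(1L, 1L, 2L, 2L),
                             tf_class = c("CREB", "USF1", "LEF1", "USF1"),
                             pattern = c("TGACGTCA", "CACGTG", "CTTTGAT", "CACGTG"),
                             offset = c(1L, 50L, 1L, 50L))
    ),
    "separated"
  )
  # single-class window
  expect_error(
    plant_spec("x", 500,
      windows = tibble::tibble(window = 1L, start = 101L, end = 300L),
      sites = tibble::tibble(window = c(1L, 1L), tf_class = c("MITF", "MITF"),
                             pattern = c("CATGTG", "CACGTG"),
                             offset = c(1L, 50L))
    ),
    "distinct"
  )
  # site overflowing its window
  expect_error(
    plant_spec("x", 500,
      windows = tibble::tibble(window = 1L, start = 101L, end = 300L),
      sites = tibble::tibble(window = c(1L, 1L), tf_class = c("MITF", "CREB"),
                             pattern = c("CATGTG", "TGACGTCA"),
                             offset = c(198L, 50L))
    ),
    "overflows"
  )
  # bad background frequencies
  expect_error(
    plant_spec("x", 500,
      background_freqs = c(A = 0.5, C = 0.5, G = 0.2, T = 0.2),
      windows = tibble::tibble(window = 1L, start = 101L, end = 300L),
      sites = tibble::tibble(window = c(1L, 1L), tf_class = c("MITF", "CREB"),
                             pattern = c("CATGTG", "TGACGTCA"),
                             offset = c(1L, 50L))
    )
  )
})

test_that("generate_region plants exactly the specified sites, reproducibly", {
  gen1 <- generate_region(tiny_spec(seed = 4))
  gen2 <- generate_region(tiny_spec(seed = 4))
  expect_identical(gen1$region$sequence, gen2$region$sequence)
  expect_equal(nrow(gen1$truth), 4)
  expect_equal(nchar(gen1$region$sequence), 900)

  # each planted site sits verbatim in the sequence at its coordinates
  for (i in seq_len(nrow(gen1$truth))) {
    t <- gen1$truth[i, ]
    expect_equal(substr(gen1$region$sequence, t$start, t$end), t$matched_seq)
    expect_equal(dissimilarity(t$pattern, t$matched_seq), 0)
  }
  gen3 <- generate_region(tiny_spec(seed = 5))
  expect_false(identical(gen1$region$sequence, gen3$region$sequence))
})

test_that("the scanner recovers planted truth and nothing outside it", {
  for (seed in c(2, 3)) {
    spec <- tiny_spec(seed)
    gen <- generate_region(spec)
    hits <- scan_region(gen$region$sequence, pigment_catalog(),
      region_id = "toy"
    )
    # every planted site is found at its exact span and class
    found <- merge(
      gen$truth[, c("tf_class", "start", "end")],
      hits[, c("tf_class", "start", "end")]
    )
    expect_equal(nrow(unique(found)), nrow(gen$truth))
    # no hit falls outside the planted windows (this spec has no decoys)
    win_ok <- rep(FALSE, nrow(hits))
    for (w in seq_len(nrow(spec$windows))) {
      win_ok <- win_ok | (hits$start <= spec$windows$end[w] &
                            hits$end >= spec$windows$start[w])
    }
    expect_true(all(win_ok))
  }
})

test_that("generate_study builds the default nine-gene design", {
  study <- generate_study(seed = 11)
  expect_equal(nrow(study$regions), 9)
  expect_setequal(
    study$regions$region_id,
    c("AIM1", "DCT", "MC1R", "MITF", "MLANA", "OA1", "PMEL", "RAB27A", "TYR")
  )
  expect_true(all(study$regions$length == 1500))
  expect_equal(nrow(study$windows), 27)
  # each planted window carries >= 2 distinct factors
  per_win <- tapply(
    study$truth$tf_class,
    paste(study$truth$region_id, study$truth$window),
    function(x) length(unique(x))
  )
  expect_true(all(per_win >= 2))
  # determinism across calls, divergence across seeds
  study2 <- generate_study(seed = 11)
  expect_identical(study$regions$sequence, study2$regions$sequence)
  expect_identical(study$protein_families$sequence,
                   study2$protein_families$sequence)
  study3 <- generate_study(seed = 12)
  expect_false(identical(study$regions$sequence, study3$regions$sequence))
  # empty study is allowed
  empty <- generate_study(n_regions = 0, seed = 1)
  expect_equal(nrow(empty$regions), 0)
})

test_that("mutate_protein honors the substitution rate at its extremes", {
  set.seed(8)
  s <- paste0(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                     100, replace = TRUE), collapse = "")
  expect_equal(mutate_protein(s, 0, seed = 1), s)
  m <- mutate_protein(s, 1, seed = 1)
  expect_true(all(strsplit(m, "")[[1]] != strsplit(s, "")[[1]]))
  expect_equal(nchar(mutate_protein(s, 0.5, seed = 2)), 100)
  # reproducible under a fixed seed
  expect_equal(mutate_protein(s, 0.3, seed = 9), mutate_protein(s, 0.3, seed = 9))
})

test_that("identity of mutated families recovers the substitution rate", {
  set.seed(1234)
  p <- 0.1
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  devs <- replicate(20, {
    ref <- paste0(sample(aa, 300, replace = TRUE), collapse = "")
    mut <- mutate_protein(ref, p)
    align_identity(ref, mut)$identity_percent - 100 * (1 - p)
  })
  sd3 <- 3 * 100 * sqrt(p * (1 - p) / 300)
  expect_lt(mean(abs(devs)), sd3)
})

test_that("write_study emits the full on-disk bundle", {
  study <- generate_study(n_regions = 2, seed = 21)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "regions.fasta")))
  expect_true(file.exists(file.path(dir, "proteins.fasta")))
  expect_true(file.exists(file.path(dir, "truth_hits.tsv")))
  expect_true(file.exists(file.path(dir, "study_manifest.yaml")))
  regions <- read_regions(file.path(dir, "regions.fasta"))
  expect_equal(regions$sequence, study$regions$sequence)
  manifest <- yaml::read_yaml(file.path(dir, "study_manifest.yaml"))
  expect_equal(manifest$n_regions, 2)
  expect_equal(manifest$seed, 21)
  truth <- read_hit_table(file.path(dir, "truth_hits.tsv"))
  expect_equal(nrow(truth), nrow(study$truth))
})
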