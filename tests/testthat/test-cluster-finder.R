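test_that("best_window matches brute-force enumeration on a hand case", {
  hits <- make_hits(
    starts = c(10, 50, 60, 900),
    classes = c("LEF1", "POU3F2", "USF1", "FOXD3")
  )
  win <- best_window(hits, window_length = 200)
  expect_equal(nrow(win$hits), 3)
  expect_setequal(win$hits$start, c(10, 50, 60))
  oracle <- brute_best_window(hits, 200)
  expect_equal(nrow(win$hits), oracle$n)
  expect_equal(win$interval[1], oracle$s)
})

test_that("windows of a single factor class never qualify", {
  hits <- make_hits(starts = c(10, 40, 70), classes = rep("MITF", 3))
  expect_null(best_window(hits, 200))
  expect_null(best_window(hits[0, ], 200))
  expect_equal(nrow(find_modules(hits)), 0)
})

test_that("greedy rank-1 count equals exhaustive enumeration", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(3:30, 1)
    hits <- make_hits(
      starts = sample(1:1300, n),
      classes = sample(tf_classes(), n, replace = TRUE),
      len = sample(6:11, 1)
    )
    win <- best_window(hits, 200)
    oracle <- brute_best_window(hits, 200)
    if (is.null(oracle)) {
      expect_null(win)
    } else {
      expect_equal(nrow(win$hits), oracle$n)
      expect_equal(win$interval[1], oracle$s)
    }
  }
})

test_that("adding a hit never decreases the rank-1 member count", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    hits <- make_hits(
      starts = sample(1:1200, n),
      classes = sample(tf_classes(), n, replace = TRUE)
    )
    base <- best_window(hits, 200)
    extra <- make_hits(sample(1:1200, 1), sample(tf_classes(), 1))
    grown <- best_window(rbind(hits, extra), 200)
    n0 <- if (is.null(base)) 0 else nrow(base$hits)
    n1 <- if (is.null(grown)) 0 else nrow(grown$hits)
    expect_gte(n1, n0)
  }
})

test_that("find_modules recovers three separated planted clusters in rank order", {
  # three clusters of 2, 3 and 4 distinct-factor sites
  hits <- rbind(
    make_hits(c(100, 150), c("MITF", "USF1")),
    make_hits(c(500, 540, 590), c("LEF1", "FOXD3", "POU3F2")),
    make_hits(c(1000, 1040, 1090, 1130), c("CREB", "MITF", "LEF1", "USF1"))
  )
  mods <- find_modules(hits)
  expect_equal(nrow(mods), 3)
  expect_equal(mods$rank, 1:3)
  expect_equal(mods$n_sites[mods$rank == 1], 4) # biggest cluster first
  expect_equal(mods$start[mods$rank == 1], 1000)
  expect_equal(mods$n_sites, c(4, 3, 2))
  # trimmed intervals cover exactly the member spans
  expect_equal(mods$end[mods$rank == 1], 1130 + 7)
  # single qualifying cluster yields a single module
  one <- find_modules(make_hits(c(100, 150), c("MITF", "USF1")))
  expect_equal(nrow(one), 1)
})

test_that("a hit table shaped like the TYR upstream region yields its three clusters", {
  # clusters described for tyrosinase: distal 1-200, mid ~410-640,
  # proximal ~1210-1410
  hits <- rbind(
    make_hits(c(10, 60, 120, 180), c("POU3F2", "USF1", "LEF1", "FOXD3")),
    make_hits(c(430, 480, 540, 600), c("FOXD3", "LEF1", "USF1", "POU3F2")),
    make_hits(c(1215, 1300, 1350, 1395), c("CREB", "MITF", "POU3F2", "USF1"))
  )
  hits$region_id <- "TYR"
  mods <- find_modules(hits)
  expect_equal(nrow(mods), 3)
  planted <- list(c(1, 200), c(410, 640), c(1210, 1410))
  for (iv in planted) {
    overlapping <- sum(mods$start <= iv[2] & mods$end >= iv[1])
    expect_equal(overlapping, 1)
  }
})

test_that("modules of one region never overlap and respect their invariants", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    hits <- make_hits(
      starts = sample(1:1400, n),
      classes = sample(tf_classes(), n, replace = TRUE),
      len = sample(6:11, 1)
    )
    mods <- find_modules(hits)
    if (nrow(mods) > 1) {
      m <- mods[order(mods$start), ]
      expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    }
    for (j in seq_len(nrow(mods))) {
      members <- mods$member_hits[[j]]
      expect_true(all(members$start >= mods$start[j]))
      expect_true(all(members$end <= mods$end[j]))
      expect_equal(nrow(members), mods$n_sites[j])
      expect_gte(mods$n_distinct_tfs[j], 2)
    }
  }
})

test_that("summarize_modules totals and rosters add up", {
  hits <- rbind(
    make_hits(c(100, 150), c("MITF", "USF1")),
    make_hits(c(600, 650, 700), c("LEF1", "FOXD3", "POU3F2"))
  )
  mods <- find_modules(hits)
  s <- summarize_modules(mods, region_ids = c("r1", "r2"))
  expect_equal(s$total_modules, nrow(mods))
  expect_equal(sum(s$per_region$n_modules), s$total_modules)
  expect_equal(s$per_region$n_modules[s$per_region$region_id == "r2"], 0)
  expect_equal(
    s$per_region$distinct_tfs[s$per_region$region_id == "r1"], 5
  )
  empty <- summarize_modules(find_modules(make_hits(10, "MITF")))
  expect_equal(empty$total_modules, 0)
  expect_equal(glance(s)$total_modules, s$total_modules)
  expect_equal(nrow(tidy(s)), 2)
})

test_that("module BED/TSV exports use the expected conventions", {
  hits <- make_hits(c(100, 150, 600, 660), c("MITF", "USF1", "LEF1", "CREB"))
  mods <- find_modules(hits)
  bed_path <- withr::local_tempfile(fileext = ".bed")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_modules_bed(mods, bed_path)
  write_modules_tsv(mods, tsv_path)
  bed <- readr::read_tsv(bed_path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, mods$start - 1)
  expect_equal(bed$X3, mods$end)
  expect_equal(bed$X4, paste0(mods$region_id, ".", mods$rank))
  back <- read_modules_tsv(tsv_path)
  expect_equal(back$start, mods$start)
  expect_equal(back$tf_roster, mods$tf_roster)
})
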