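PAPER_REGION_IDS <- c(
  "AIM1", "DCT", "MC1R", "MITF", "MLANA", "OA1", "PMEL", "RAB27A", "TYR"
)

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, offset) {
  (as.numeric(seed) + offset * 1013) %% (.Machine$integer.max - 1)
}

#' Specification of one synthetic upstream region
#'
#' Describes everything needed to reproduce a region: the background base
#' composition, the planted site-cluster windows (each with at least two
#' distinct factor classes), decoy sites outside the windows, and the seed.
#'
#' @param region_id Region identifier.
#' @param region_length Region length in nt (default 1500).
#' @param background_freqs Named A/C/G/T probabilities summing to 1.
#' @param windows Tibble with `window`, `start`, `end`: the planted cluster
#'   intervals, pairwise separated by more than `min_separation` bases.
#' @param sites Tibble with `window`, `tf_class`, `pattern`, `offset`
#'   (1-based within the window); sites must fit inside their window and
#'   each window must carry at least two distinct classes.
#' @param decoys Tibble with `tf_class`, `pattern`, `position` for isolated
#'   sites planted outside every window.
#' @param seed Integer seed driving all random draws for this region.
#' @param min_separation Required gap between planted windows (defaults to
#'   the 200-nt cluster search window).
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(region_id, region_length = 1500,
                       background_freqs = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       windows, sites, decoys = NULL, seed = 1,
                       min_separation = 200) {
  stopifnot(
    is.character(region_id), length(region_id) == 1,
    region_length >= 1,
    all(sort(names(background_freqs)) == c("A", "C", "G", "T")),
    abs(sum(background_freqs) - 1) < 1e-9,
    is.data.frame(windows), all(c("window", "start", "end") %in% names(windows)),
    is.data.frame(sites),
    all(c("window", "tf_class", "pattern", "offset") %in% names(sites))
  )
  windows <- dplyr::arrange(tibble::as_tibble(windows), .data$start)
  if (any(windows$start < 1 | windows$end > region_length |
            windows$end < windows$start)) {
    stop("planted windows must lie inside the region", call. = FALSE)
  }
  if (nrow(windows) > 1) {
    gaps <- windows$start[-1] - windows$end[-nrow(windows)] - 1L
    if (any(gaps <= min_separation)) {
      stop(sprintf(
        "planted windows must be separated by more than %d bases",
        min_separation
      ), call. = FALSE)
    }
  }
  sites <- tibble::as_tibble(sites)
  sites$pattern <- unname(vapply(sites$pattern, parse_iupac, character(1)))
  per_win <- split(sites, sites$window)
  for (w in names(per_win)) {
    win <- windows[windows$window == as.integer(w), ]
    if (nrow(win) != 1) {
      stop(sprintf("sites reference unknown window %s", w), call. = FALSE)
    }
    s <- per_win[[w]]
    if (length(unique(s$tf_class)) < 2) {
      stop(sprintf("planted window %s must carry >= 2 distinct TF classes", w),
        call. = FALSE
      )
    }
    if (any(win$start + s$offset - 1 + nchar(s$pattern) - 1 > win$end) ||
        any(s$offset < 1)) {
      stop(sprintf("a planted site overflows window %s", w), call. = FALSE)
    }
  }
  if (!is.null(decoys)) {
    decoys <- tibble::as_tibble(decoys)
    stopifnot(all(c("tf_class", "pattern", "position") %in% names(decoys)))
    decoys$pattern <- unname(vapply(decoys$pattern, parse_iupac, character(1)))
    dec_end <- decoys$position + nchar(decoys$pattern) - 1
    if (any(decoys$position < 1 | dec_end > region_length)) {
      stop("a decoy site overflows the region", call. = FALSE)
    }
    inside <- overlaps_any(decoys$position, dec_end,
      purrr::map(seq_len(nrow(windows)),
                 function(i) c(windows$start[i], windows$end[i]))
    )
    if (any(inside)) {
      stop("decoy sites must lie outside every planted window", call. = FALSE)
    }
  } else {
    decoys <- tibble::tibble(
      tf_class = character(), pattern = character(), position = integer()
    )
  }
  structure(
    list(
      region_id = region_id, region_length = as.integer(region_length),
      background_freqs = background_freqs[c("A", "C", "G", "T")],
      windows = windows, sites = sites, decoys = decoys,
      seed = as.integer(seed), min_separation = as.integer(min_separation)
    ),
    class = "plant_spec"
  )
}

#' Generate a synthetic upstream region with planted binding sites
#'
#' Draws a background sequence from the spec's base composition, overwrites
#' the planted and decoy site positions with concrete instances drawn
#' uniformly from each pattern's IUPAC expansion, then rejection-checks the
#' background: any catalog hit outside the planted windows (or, at decoys,
#' of a class other than the decoy's) has its background bases redrawn, for
#' a bounded number of rounds. The result is a region whose only binding
#' sites are the planted ones.
#'
#' @param spec A [plant_spec()].
#' @param catalog The motif catalog the rejection step scans with.
#' @param max_rounds Bound on redraw rounds before giving up.
#' @return A list with `region` (one-row tibble: `region_id`, `sequence`,
#'   `length`) and `truth` (the planted-site hit tibble, coordinate order).
#' @export
generate_region <- function(spec, catalog = pigment_catalog(),
                            max_rounds = 100) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, generate_region_impl(spec, catalog, max_rounds))
}

generate_region_impl <- function(spec, catalog, max_rounds) {
  L <- spec$region_length
  chars <- sample(c("A", "C", "G", "T"), L,
    replace = TRUE, prob = spec$background_freqs
  )

  plant <- function(at, pattern) {
    expansion <- expand_iupac(pattern)
    concrete <- if (length(expansion) == 1) {
      expansion
    } else {
      sample(expansion, 1)
    }
    chars[at:(at + nchar(concrete) - 1)] <<- strsplit(concrete, "")[[1]]
    concrete
  }

  truth <- list()
  for (i in seq_len(nrow(spec$sites))) {
    s <- spec$sites[i, ]
    win <- spec$windows[spec$windows$window == s$window, ]
    at <- win$start + s$offset - 1L
    concrete <- plant(at, s$pattern)
    truth[[length(truth) + 1]] <- tibble::tibble(
      region_id = spec$region_id, tf_class = s$tf_class,
      start = as.integer(at), end = as.integer(at + nchar(s$pattern) - 1L),
      strand = "+", matched_seq = concrete,
      dissimilarity_percent = 0, pattern = s$pattern,
      window = win$window
    )
  }
  decoy_rows <- list()
  for (i in seq_len(nrow(spec$decoys))) {
    d <- spec$decoys[i, ]
    concrete <- plant(d$position, d$pattern)
    decoy_rows[[i]] <- tibble::tibble(
      tf_class = d$tf_class, start = as.integer(d$position),
      end = as.integer(d$position + nchar(d$pattern) - 1L)
    )
  }
  truth <- dplyr::bind_rows(truth) |>
    dplyr::arrange(.data$start, .data$end, .data$tf_class)
  decoy_spans <- dplyr::bind_rows(decoy_rows)

  # positions that must never be redrawn
  fixed <- rep(FALSE, L)
  for (i in seq_len(nrow(truth))) fixed[truth$start[i]:truth$end[i]] <- TRUE
  if (nrow(decoy_spans) > 0) {
    for (i in seq_len(nrow(decoy_spans))) {
      fixed[decoy_spans$start[i]:decoy_spans$end[i]] <- TRUE
    }
  }
  win_ivs <- purrr::map(
    seq_len(nrow(spec$windows)),
    function(i) c(spec$windows$start[i], spec$windows$end[i])
  )

  offending <- function(hits) {
    if (nrow(hits) == 0) {
      return(hits)
    }
    ok <- overlaps_any(hits$start, hits$end, win_ivs)
    if (nrow(decoy_spans) > 0) {
      for (i in seq_len(nrow(decoy_spans))) {
        d <- decoy_spans[i, ]
        ok <- ok | (hits$tf_class == d$tf_class &
                      hits$start <= d$end & hits$end >= d$start)
      }
    }
    hits[!ok, , drop = FALSE]
  }

  for (round in seq_len(max_rounds)) {
    hits <- scan_region(paste0(chars, collapse = ""), catalog,
      region_id = spec$region_id
    )
    bad <- offending(hits)
    if (nrow(bad) == 0) {
      region <- tibble::tibble(
        region_id = spec$region_id,
        sequence = paste0(chars, collapse = ""),
        length = L
      )
      return(list(region = region, truth = truth))
    }
    redraw <- rep(FALSE, L)
    for (i in seq_len(nrow(bad))) redraw[bad$start[i]:bad$end[i]] <- TRUE
    redraw <- redraw & !fixed
    if (!any(redraw)) {
      stop("background rejection cannot remove a spurious hit overlapping ",
        "only planted bases; adjust the spec",
        call. = FALSE
      )
    }
    chars[redraw] <- sample(c("A", "C", "G", "T"), sum(redraw),
      replace = TRUE, prob = spec$background_freqs
    )
  }
  stop(sprintf(
    "rejection sampling did not converge in %d rounds for region '%s'",
    max_rounds, spec$region_id
  ), call. = FALSE)
}

# one concrete planted pattern per class; MITF uses the extended M-box so its
# internal E-box stays inside the planted span
PLANT_PATTERNS <- c(
  CREB = "TGACGTCA", FOXD3 = "RTAAAYA", LEF1 = "CTTTGAT",
  MITF = "AGTCATGTGCT", POU3F2 = "ATGCAAAT", USF1 = "CACGTG"
)

default_plant_spec <- function(region_id, region_length, clusters_per_region,
                               sites_per_cluster_range, seed,
                               window_length = 200) {
  k <- clusters_per_region
  decoy_zone <- 250L
  usable <- region_length - decoy_zone
  if (usable < k * window_length + (k - 1) * (window_length + 2)) {
    stop("region too short to pack the requested clusters", call. = FALSE)
  }
  centers <- decoy_zone + (seq_len(k) - 0.5) * usable / k
  starts <- pmax(decoy_zone + 1L, as.integer(round(centers - window_length / 2)))
  windows <- tibble::tibble(
    window = seq_len(k),
    start = starts,
    end = starts + as.integer(window_length) - 1L
  )
  with_seed(seed, {
    # small jitter keeps placements varied across regions while preserving
    # the > window_length separation guarantee
    jitter <- sample(-8:8, k, replace = TRUE)
    windows$start <- windows$start + jitter
    windows$end <- windows$end + jitter
    sites <- purrr::map(seq_len(k), function(w) {
      n <- sample(seq(sites_per_cluster_range[1], sites_per_cluster_range[2]), 1)
      classes <- sample(tf_classes(), n)
      slot <- as.integer(window_length) %/% n
      # first/last sites anchor near the window edges so the planted cluster
      # spans most of its window; middle sites take interior slots
      offs <- vapply(seq_len(n), function(i) {
        len <- nchar(PLANT_PATTERNS[[classes[i]]])
        if (i == 1) {
          sample.int(15L, 1)
        } else if (i == n) {
          as.integer(window_length) - len - sample.int(15L, 1) + 1L
        } else {
          (i - 1L) * slot + sample.int(slot - len, 1)
        }
      }, integer(1))
      tibble::tibble(
        window = w, tf_class = classes,
        pattern = unname(PLANT_PATTERNS[classes]), offset = offs
      )
    }) |> dplyr::bind_rows()
    decoys <- tibble::tibble(
      tf_class = "POU3F2",
      pattern = PLANT_PATTERNS[["POU3F2"]],
      position = c(30L, 130L)
    )
    plant_spec(region_id,
      region_length = region_length, windows = windows, sites = sites,
      decoys = decoys, seed = derive_seed(seed, 7),
      min_separation = window_length
    )
  })
}

#' Generate a full synthetic study
#'
#' Emulates the study design the analysis assumes: nine 1500-nt upstream
#' regions (named after the nine pigmentation target genes), each carrying
#' three well-separated planted clusters of 2-5 distinct-factor binding
#' sites plus two same-class decoy sites, together with protein ortholog
#' families diverged at fixed per-species substitution rates.
#'
#' @param n_regions Number of upstream regions (default 9).
#' @param clusters_per_region Planted clusters per region (default 3).
#' @param sites_per_cluster_range Inclusive range for the number of
#'   distinct-factor sites per cluster (default `c(2, 5)`).
#' @param region_length Region length in nt (default 1500).
#' @param seed Integer master seed; per-region substreams are derived from
#'   it at fixed offsets.
#' @param catalog Motif catalog used for planting and rejection scanning.
#' @param protein_length Length of the synthetic reference proteins.
#' @param species_rates Named per-species substitution rates for the
#'   protein families.
#' @return A `synthetic_study` list: `regions`, `truth`, `windows`,
#'   `protein_families`, `params`.
#' @examples
#' \donttest{
#' study <- generate_study(n_regions = 2, seed = 1)
#' study$regions
#' }
#' @export
generate_study <- function(n_regions = 9, clusters_per_region = 3,
                           sites_per_cluster_range = c(2, 5),
                           region_length = 1500, seed = 42,
                           catalog = pigment_catalog(),
                           protein_length = 300,
                           species_rates = c(
                             hum = 0.25, mouse = 0.26, dog = 0.25,
                             horse = 0.25, cow = 0.26, chick = 0.20,
                             anole = 0.12, Tham_sirt = 0.06
                           )) {
  stopifnot(n_regions >= 0, clusters_per_region >= 1,
            length(sites_per_cluster_range) == 2,
            sites_per_cluster_range[1] >= 2,
            sites_per_cluster_range[2] >= sites_per_cluster_range[1])
  ids <- if (n_regions <= length(PAPER_REGION_IDS)) {
    PAPER_REGION_IDS[seq_len(n_regions)]
  } else {
    c(PAPER_REGION_IDS,
      paste0("region", seq_len(n_regions - length(PAPER_REGION_IDS))))
  }
  regions <- list()
  truths <- list()
  windows <- list()
  for (i in seq_len(n_regions)) {
    spec <- default_plant_spec(
      ids[i], region_length, clusters_per_region,
      sites_per_cluster_range, seed = derive_seed(seed, i)
    )
    gen <- generate_region(spec, catalog)
    regions[[i]] <- gen$region
    truths[[i]] <- gen$truth
    windows[[i]] <- dplyr::mutate(spec$windows, region_id = ids[i], .before = 1)
  }
  families <- generate_protein_families(
    genes = ids, species_rates = species_rates,
    protein_length = protein_length, seed = derive_seed(seed, 900)
  )
  structure(
    list(
      regions = dplyr::bind_rows(regions) %||% tibble::tibble(
        region_id = character(), sequence = character(), length = integer()
      ),
      truth = dplyr::bind_rows(truths) %||% empty_hits(),
      windows = dplyr::bind_rows(windows),
      protein_families = families,
      params = list(
        n_regions = n_regions, clusters_per_region = clusters_per_region,
        sites_per_cluster_range = sites_per_cluster_range,
        region_length = region_length, seed = seed,
        species_rates = species_rates, protein_length = protein_length
      )
    ),
    class = "synthetic_study"
  )
}

`%||%` <- function(x, y) if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) y else x

#' Mutate a protein sequence at a fixed substitution rate
#'
#' Each position is independently substituted with probability `p` to a
#' uniformly chosen different residue; no indels are introduced.
#'
#' @param seq A protein sequence.
#' @param p Substitution probability in \[0, 1\].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The diverged sequence, same length.
#' @export
mutate_protein <- function(seq, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  seq <- check_protein(seq, "seq")
  run <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < p
    aa20 <- setdiff(AA_ALPHABET, "X")
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(aa20, ch), 1)
    }, character(1))
    paste0(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate synthetic protein ortholog families
#'
#' One random reference protein per gene, plus one ortholog per species
#' produced by [mutate_protein()] at that species' substitution rate.
#'
#' @param genes Character vector of gene symbols.
#' @param species_rates Named numeric vector of per-species substitution
#'   rates.
#' @param protein_length Reference protein length.
#' @param reference_species Name recorded for the reference sequences.
#' @param seed Integer seed.
#' @return Tibble with `gene`, `species`, `sequence`, `substitution_rate`.
#' @export
generate_protein_families <- function(genes, species_rates,
                                      protein_length = 300,
                                      reference_species = "python",
                                      seed = 1) {
  aa20 <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, {
    purrr::map(genes, function(g) {
      ref <- paste0(sample(aa20, protein_length, replace = TRUE),
        collapse = ""
      )
      rows <- purrr::imap(as.list(species_rates), function(p, sp) {
        tibble::tibble(
          gene = g, species = sp,
          sequence = mutate_protein(ref, p),
          substitution_rate = p
        )
      })
      dplyr::bind_rows(
        tibble::tibble(
          gene = g, species = reference_species, sequence = ref,
          substitution_rate = 0
        ),
        dplyr::bind_rows(rows)
      )
    }) |> dplyr::bind_rows()
  })
}

#' Write a synthetic study to disk
#'
#' Emits the region FASTA, protein FASTA, planted-truth hit table TSV and a
#' YAML manifest of the generation parameters.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_regions(study$regions, file.path(dir, "regions.fasta"))
  write_protein_families(
    study$protein_families, file.path(dir, "proteins.fasta")
  )
  write_hit_table(
    study$truth[, HIT_COLUMNS], file.path(dir, "truth_hits.tsv")
  )
  yaml::write_yaml(study$params, file.path(dir, "study_manifest.yaml"))
  invisible(dir)
}
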