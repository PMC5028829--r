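#' Pipeline run configuration
#'
#' Defaults reproduce the study parameters: 1500-nt regions, 15 percent
#' maximum dissimilarity, 200-nt windows, top 3 modules per region with at
#' least two distinct factors.
#'
#' @param regions_fasta Path to an upstream-region FASTA, or `NULL` to
#'   generate a synthetic study.
#' @param n_regions,clusters_planted Synthetic-study shape used when
#'   `regions_fasta` is `NULL`.
#' @param catalog `"paper-default"` for the packaged catalog, or a catalog
#'   TSV path.
#' @param max_dissimilarity Percent dissimilarity threshold.
#' @param window_length,clusters_per_region,min_distinct_tfs,trim_to_span
#'   Cluster detection parameters, see [cluster_config()].
#' @param out_dir Output directory.
#' @param seed Integer seed for the synthetic study.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `run_config` list.
#' @export
run_config <- function(regions_fasta = NULL, n_regions = 9,
                       clusters_planted = 3, catalog = "paper-default",
                       max_dissimilarity = 15, window_length = 200,
                       clusters_per_region = 3, min_distinct_tfs = 2,
                       trim_to_span = TRUE, out_dir = tempfile("escan_run_"),
                       seed = 42, log_level = "info") {
  stopifnot(
    max_dissimilarity >= 0, max_dissimilarity <= 100,
    log_level %in% c("quiet", "info", "debug")
  )
  structure(
    list(
      regions_fasta = regions_fasta, n_regions = n_regions,
      clusters_planted = clusters_planted, catalog = catalog,
      max_dissimilarity = max_dissimilarity,
      window_length = window_length,
      clusters_per_region = clusters_per_region,
      min_distinct_tfs = min_distinct_tfs,
      trim_to_span = trim_to_span,
      out_dir = out_dir, seed = seed, log_level = log_level
    ),
    class = "run_config"
  )
}

log_msg <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]]) {
    message(sprintf(...))
  }
}

resolve_catalog <- function(config) {
  if (identical(config$catalog, "paper-default")) {
    pigment_catalog(max_dissimilarity = config$max_dissimilarity)
  } else {
    read_catalog(config$catalog, max_dissimilarity = config$max_dissimilarity)
  }
}

#' Run the full candidate-enhancer pipeline
#'
#' Orchestrates the stages end-to-end: obtain upstream regions (FASTA or
#' synthetic study), scan for catalog binding sites, collapse matrix-level
#' matches per factor, detect the top-k modules per region, and write the
#' hit table, module BED/TSV, one SVG track per region, a per-region summary
#' TSV and the resolved configuration next to the outputs. A rerun with the
#' same configuration and seed reproduces the outputs bit for bit.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run` report: module summary, tibbles of hits and
#'   modules, output paths.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(n_regions = 2, out_dir = tempfile(),
#'                                log_level = "quiet"))
#' glance(run)
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$regions_fasta) && !file.exists(config$regions_fasta)) {
    stop(sprintf("regions FASTA not found: %s", config$regions_fasta),
      call. = FALSE
    )
  }
  catalog <- resolve_catalog(config)
  study <- NULL
  if (is.null(config$regions_fasta)) {
    log_msg(config, "info", "generating synthetic study (%d regions, seed %d)",
      config$n_regions, config$seed
    )
    study <- generate_study(
      n_regions = config$n_regions,
      clusters_per_region = config$clusters_planted,
      seed = config$seed, catalog = catalog
    )
    regions <- study$regions
  } else {
    regions <- read_regions(config$regions_fasta)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  hits <- scan_regions(regions, catalog)
  log_msg(config, "info", "scanned %d regions: %d raw hits",
    nrow(regions), nrow(hits)
  )
  collapsed <- hits |>
    dplyr::group_split(.data$region_id) |>
    purrr::map(collapse_hits) |>
    dplyr::bind_rows()
  cc <- cluster_config(
    window_length = config$window_length,
    clusters_per_region = config$clusters_per_region,
    min_distinct_tfs = config$min_distinct_tfs,
    trim_to_span = config$trim_to_span
  )
  modules <- find_modules(collapsed, cc)
  summary <- summarize_modules(modules, region_ids = regions$region_id)
  if (config$log_level == "debug") {
    for (i in seq_len(nrow(summary$per_region))) {
      log_msg(config, "debug", "  %s: %d modules",
        summary$per_region$region_id[i], summary$per_region$n_modules[i]
      )
    }
  }
  log_msg(config, "info", "detected %d candidate enhancer modules",
    summary$total_modules
  )

  paths <- list(
    hits = file.path(config$out_dir, "hits.tsv"),
    collapsed = file.path(config$out_dir, "hits_collapsed.tsv"),
    modules_tsv = file.path(config$out_dir, "modules.tsv"),
    modules_bed = file.path(config$out_dir, "modules.bed"),
    summary = file.path(config$out_dir, "summary.tsv"),
    config = file.path(config$out_dir, "run_config.yaml")
  )
  write_hit_table(hits, paths$hits)
  write_hit_table(collapsed, paths$collapsed)
  write_modules_tsv(modules, paths$modules_tsv)
  write_modules_bed(modules, paths$modules_bed)
  readr::write_tsv(summary$per_region, paths$summary)
  yaml::write_yaml(
    config[setdiff(names(config), "out_dir")], paths$config
  )

  svg_paths <- character(0)
  for (rid in regions$region_id) {
    mods <- modules[modules$region_id == rid, , drop = FALSE]
    track <- layout_region(
      mods,
      hits = collapsed[collapsed$region_id == rid, , drop = FALSE],
      region_length = nchar(regions$sequence[regions$region_id == rid][1]),
      region_id = rid
    )
    p <- file.path(config$out_dir, paste0(rid, ".svg"))
    render_svg(track, path = p)
    svg_paths <- c(svg_paths, p)
  }
  paths$svg <- svg_paths

  identity <- NULL
  if (!is.null(study)) {
    identity <- build_identity_matrix(study$protein_families)
    paths$identity <- file.path(config$out_dir, "identity_matrix.tsv")
    readr::write_tsv(identity, paths$identity)
  }

  structure(
    list(
      summary = summary, hits = hits, collapsed = collapsed,
      modules = modules, identity = identity, study = study,
      config = config, paths = paths
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("candidate-enhancer pipeline run\n")
  cat(sprintf("  output: %s\n", x$config$out_dir))
  print(x$summary)
  invisible(x)
}

#' Per-region results of a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @method tidy pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) {
  tidy(x$summary)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  dplyr::mutate(glance(x$summary),
    n_hits = nrow(x$hits), n_collapsed = nrow(x$collapsed),
    seed = x$config$seed
  )
}
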