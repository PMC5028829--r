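AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

check_protein <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) ||
      nchar(seq) == 0) {
    stop(sprintf("`%s` must be a single non-empty protein sequence", arg),
      call. = FALSE
    )
  }
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid residue '%s' at position %d in `%s`", chars[bad[1]], bad[1], arg
    ), call. = FALSE)
  }
  seq
}

#' Percent identity between two protein sequences
#'
#' Pairwise alignment with BLOSUM62 scoring and affine gaps (open 11,
#' extend 1), the common protein-alignment defaults. Identity is matches
#' divided by alignment columns; local mode aligns (and counts) only the
#' best-scoring subsequences, so terminal gap columns never enter the
#' denominator there.
#'
#' @param a,b Protein sequences over the 20 amino acids plus X.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return One-row tibble: `identity_percent`, `aligned_columns`, `matches`,
#'   `gaps`.
#' @examples
#' align_identity("MKVLAA", "MKVLAA")$identity_percent
#' @export
align_identity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- check_protein(a, "a")
  b <- check_protein(b, "b")
  blosum62 <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62,
    gapOpening = 11, gapExtension = 1,
    type = mode
  )
  aligned_columns <- Biostrings::nchar(pa)
  matches <- Biostrings::nmatch(pa)
  gaps <- aligned_columns - matches - Biostrings::nmismatch(pa)
  tibble::tibble(
    identity_percent = 100 * matches / aligned_columns,
    aligned_columns = aligned_columns,
    matches = matches,
    gaps = gaps
  )
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Build the gene-by-species-pair percent identity matrix
#'
#' For every gene family, the reference-species sequence is aligned against
#' each other species' ortholog; absent orthologs become missing (`NA`)
#' cells, not zeros.
#'
#' @param families Tibble with columns `gene`, `species`, `sequence`.
#' @param reference_species Species aligned against all others (must be
#'   present in every family).
#' @param mode Alignment mode, see [align_identity()].
#' @return An `identity_matrix`: a tibble with a `gene` column and one
#'   numeric percent column per `<ref>2<species>` pair.
#' @export
build_identity_matrix <- function(families, reference_species = "python",
                                  mode = "global") {
  stopifnot(
    is.data.frame(families),
    all(c("gene", "species", "sequence") %in% names(families))
  )
  genes <- unique(families$gene)
  others <- setdiff(unique(families$species), reference_species)
  pair_names <- paste0(reference_species, "2", others)
  rows <- purrr::map(genes, function(g) {
    fam <- families[families$gene == g, , drop = FALSE]
    ref <- fam$sequence[fam$species == reference_species]
    if (length(ref) == 0) {
      stop(sprintf(
        "family '%s' lacks the reference species '%s'", g, reference_species
      ), call. = FALSE)
    }
    vals <- vapply(others, function(sp) {
      other <- fam$sequence[fam$species == sp]
      if (length(other) == 0) {
        return(NA_real_)
      }
      align_identity(ref[1], other[1], mode = mode)$identity_percent
    }, numeric(1))
    tibble::as_tibble(as.list(stats::setNames(vals, pair_names))) |>
      dplyr::mutate(gene = g, .before = 1)
  })
  new_identity_matrix(dplyr::bind_rows(rows))
}

new_identity_matrix <- function(tbl) {
  stopifnot(names(tbl)[1] == "gene")
  vals <- as.matrix(tbl[, -1])
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop("identity values must be percentages in [0, 100]", call. = FALSE)
  }
  structure(tbl, class = c("identity_matrix", class(tibble::as_tibble(tbl))))
}

#' The packaged coat-color ortholog identity matrix
#'
#' Percent identity of 23 python coat-color proteins against their human,
#' mouse, dog, horse, cow, chicken, anole and garter-snake orthologs (best
#' reciprocal protein hits). The two garter-snake orthologs that are absent
#' from the public protein repository (RAB38, SLC24A5) are missing cells,
#' not 0% identities.
#'
#' @return An `identity_matrix` tibble (23 genes x 8 species pairs).
#' @export
pigment_identity_matrix <- function() {
  path <- system.file("extdata", "table1_identity.tsv",
    package = "enhancerscan", mustWork = TRUE
  )
  tbl <- readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, na = "NA"
  )
  new_identity_matrix(tbl)
}

#' Domain annotations of the six pigmentation transcription factors
#'
#' Static annotation table of functional domains (DNA-binding and
#' coactivator regions) detected in the python transcription factor
#' proteins, with 1-based residue coordinates.
#'
#' @return Tibble with `gene`, `protein_name`, `start`, `end`, `domain_id`,
#'   `domain_name`.
#' @export
pigment_domains <- function() {
  path <- system.file("extdata", "table3_domains.tsv",
    package = "enhancerscan", mustWork = TRUE
  )
  readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(),
      protein_name = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      domain_id = readr::col_character(),
      domain_name = readr::col_character()
    ),
    progress = FALSE
  )
}

#' Min-max identity range per gene
#'
#' @param matrix An `identity_matrix`.
#' @param gene Optional single gene symbol; default summarizes every gene.
#' @return Tibble with `gene`, `min_identity`, `max_identity` over the
#'   non-missing cells of each row.
#' @examples
#' range_summary(pigment_identity_matrix(), "PAX3")
#' @export
range_summary <- function(matrix, gene = NULL) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "gene")
  tbl <- tibble::as_tibble(matrix)
  if (!is.null(gene)) {
    if (!gene %in% tbl$gene) {
      stop(sprintf("gene '%s' not present in the identity matrix", gene),
        call. = FALSE
      )
    }
    tbl <- tbl[tbl$gene == gene, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(tbl, -"gene",
    names_to = "species_pair", values_to = "identity"
  )
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$identity)),
      min_identity = suppressWarnings(min(.data$identity, na.rm = TRUE)),
      max_identity = suppressWarnings(max(.data$identity, na.rm = TRUE)),
      .groups = "drop"
    )
  if (any(!is.finite(out$min_identity))) {
    stop("all cells missing for gene(s): ",
      paste(out$gene[!is.finite(out$min_identity)], collapse = ", "),
      call. = FALSE
    )
  }
  out <- out[match(unique(tbl$gene), out$gene), ]
  out[, c("gene", "min_identity", "max_identity", "n_missing")]
}

#' Export the identity matrix as a heat-map input table
#'
#' Tab-delimited text in the layout heat-map builders expect: first column
#' holds `"GENE (annotation)"` row labels, remaining columns follow the
#' species-pair order of the matrix, and missing cells are emitted as the
#' literal `NA`.
#'
#' @param matrix An `identity_matrix`.
#' @param annotations Optional tibble with `gene` and `annotation` columns
#'   (pleiotropic-effect strings); genes without an entry, or with an empty
#'   annotation, are labelled by the bare gene symbol.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(matrix, annotations = NULL, path) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "gene")
  tbl <- tibble::as_tibble(matrix)
  ann <- stats::setNames(rep("", nrow(tbl)), tbl$gene)
  if (!is.null(annotations)) {
    stopifnot(all(c("gene", "annotation") %in% names(annotations)))
    known <- intersect(annotations$gene, names(ann))
    ann[known] <- annotations$annotation[match(known, annotations$gene)]
  }
  label <- ifelse(ann == "" | is.na(ann),
    names(ann), sprintf("%s (%s)", names(ann), ann)
  )
  out <- dplyr::mutate(tbl, gene = unname(label))
  names(out)[1] <- "Gene"
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read protein families from FASTA
#'
#' Record ids must be `gene|species`.
#'
#' @param path FASTA file path.
#' @return Tibble with `gene`, `species`, `sequence`.
#' @export
read_protein_families <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("protein record ids must be of the form 'gene|species'",
      call. = FALSE
    )
  }
  tibble::tibble(
    gene = vapply(parts, `[`, character(1), 1),
    species = vapply(parts, `[`, character(1), 2),
    sequence = unname(as.character(set))
  )
}

#' @rdname read_protein_families
#' @param families Tibble with `gene`, `species`, `sequence`.
#' @export
write_protein_families <- function(families, path) {
  set <- Biostrings::AAStringSet(families$sequence)
  names(set) <- paste0(families$gene, "|", families$species)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
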