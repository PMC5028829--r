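#' Lay out the candidate-enhancer track for one region
#'
#' Builds the drawable structure behind the module visualization: module
#' boxes positioned and sized proportionally to their interval within the
#' region, and per-site glyphs packed in site order inside each box. Glyphs
#' carry the factor's display color and an overlap flag set when the site's
#' span intersects a site of a different factor class. By design the track
#' does not encode strand, within-box genomic spacing, per-site length, or
#' nucleotide composition.
#'
#' @param modules Module tibble for one region (from [find_modules()]).
#' @param hits Optional hit tibble used to evaluate cross-factor overlap;
#'   defaults to the pooled member hits of `modules`.
#' @param region_length Region length in nt (default 1500).
#' @param region_id Region identifier; inferred from `modules` when present.
#' @return A `region_track`: list with `region_id`, `region_length`,
#'   `boxes` (rank, start, end, x0, x1 as fractions of the region) and
#'   `glyphs` (rank, order, tf_class, color, overlap, start, end).
#' @export
layout_region <- function(modules, hits = NULL, region_length = 1500,
                          region_id = NULL) {
  stopifnot(is.data.frame(modules))
  if (nrow(modules) > 0 && dplyr::n_distinct(modules$region_id) > 1) {
    stop("`layout_region()` expects modules from a single region",
      call. = FALSE
    )
  }
  if (is.null(region_id)) {
    region_id <- if (nrow(modules) > 0) modules$region_id[1] else "region"
  }
  if (nrow(modules) == 0) {
    return(structure(
      list(
        region_id = region_id, region_length = as.integer(region_length),
        boxes = tibble::tibble(
          rank = integer(), start = integer(), end = integer(),
          x0 = double(), x1 = double()
        ),
        glyphs = tibble::tibble(
          rank = integer(), order = integer(), tf_class = character(),
          color = character(), overlap = logical(),
          start = integer(), end = integer()
        )
      ),
      class = "region_track"
    ))
  }
  if (any(modules$start < 1 | modules$end > region_length)) {
    stop("module interval outside region bounds", call. = FALSE)
  }
  members <- dplyr::bind_rows(
    purrr::map2(modules$member_hits, modules$rank, function(m, r) {
      dplyr::mutate(m, rank = r)
    })
  )
  pool <- if (is.null(hits)) members else hits
  overlap_flag <- vapply(seq_len(nrow(members)), function(i) {
    any(pool$tf_class != members$tf_class[i] &
          pool$start <= members$end[i] & pool$end >= members$start[i])
  }, logical(1))
  glyphs <- members |>
    dplyr::mutate(overlap = overlap_flag) |>
    dplyr::group_by(.data$rank) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(color = unname(tf_colors()[.data$tf_class]))
  structure(
    list(
      region_id = region_id,
      region_length = as.integer(region_length),
      boxes = tibble::tibble(
        rank = modules$rank,
        start = modules$start,
        end = modules$end,
        x0 = (modules$start - 1) / region_length,
        x1 = modules$end / region_length
      ),
      glyphs = glyphs[, c("rank", "order", "tf_class", "color", "overlap",
                          "start", "end")]
    ),
    class = "region_track"
  )
}

#' Tidy the glyph table of a region track
#'
#' @param x A `region_track`.
#' @param ... Unused.
#' @method tidy region_track
#' @export
tidy.region_track <- function(x, ...) {
  x$glyphs
}

#' Render a region track as an SVG document
#'
#' Deterministic byte output: one `<rect class="glyph">` per binding-site
#' glyph, one `<rect class="module">` per module box, equal-width glyphs
#' packed in site order inside each box.
#'
#' @param track A `region_track`.
#' @param path Optional file to write the SVG to.
#' @param width,height Canvas size in pixels.
#' @return The SVG document as a single string (invisibly when `path` is
#'   given).
#' @export
render_svg <- function(track, path = NULL, width = 1000, height = 140) {
  stopifnot(inherits(track, "region_track"))
  margin <- 40
  track_w <- width - 2 * margin
  y0 <- 50
  box_h <- 40
  lines <- c(
    sprintf(
      paste0(
        "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
        "height=\"%d\" viewBox=\"0 0 %d %d\">"
      ),
      width, height, width, height
    ),
    sprintf(
      "<text x=\"%d\" y=\"30\" font-family=\"sans-serif\" font-size=\"16\">%s (%d nt upstream)</text>",
      margin, track$region_id, track$region_length
    ),
    sprintf(
      "<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" stroke=\"black\" stroke-width=\"1\"/>",
      margin, y0 + box_h %/% 2, margin + track_w, y0 + box_h %/% 2
    )
  )
  for (i in seq_len(nrow(track$boxes))) {
    b <- track$boxes[i, ]
    bx <- margin + b$x0 * track_w
    bw <- (b$x1 - b$x0) * track_w
    lines <- c(lines, sprintf(
      "<rect class=\"module\" x=\"%.2f\" y=\"%d\" width=\"%.2f\" height=\"%d\" fill=\"white\" stroke=\"black\" stroke-width=\"1.5\"/>",
      bx, y0, bw, box_h
    ))
    g <- track$glyphs[track$glyphs$rank == b$rank, , drop = FALSE]
    n <- nrow(g)
    if (n == 0) next
    gw <- bw / n
    for (j in seq_len(n)) {
      lines <- c(lines, sprintf(
        "<rect class=\"glyph\" x=\"%.2f\" y=\"%d\" width=\"%.2f\" height=\"%d\" fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
        bx + (j - 1) * gw, y0 + 4, gw, box_h - 8, g$color[j],
        if (g$overlap[j]) "black" else "none",
        if (g$overlap[j]) "2" else "0"
      ))
    }
    lines <- c(lines, sprintf(
      "<text x=\"%.2f\" y=\"%d\" font-family=\"sans-serif\" font-size=\"12\">%d-%d</text>",
      bx, y0 + box_h + 16, b$start, b$end
    ))
  }
  lines <- c(lines, "</svg>")
  svg <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Render a region track as plain text
#'
#' A diff-friendly mirror of the SVG layout: one line per module with its
#' interval and the ordered site roster; sites overlapping a different
#' factor's site are marked with `*`.
#'
#' @param track A `region_track`.
#' @param path Optional file to write to.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
render_text <- function(track, path = NULL) {
  stopifnot(inherits(track, "region_track"))
  out <- sprintf("%s (%d nt upstream)", track$region_id, track$region_length)
  for (i in seq_len(nrow(track$boxes))) {
    b <- track$boxes[i, ]
    g <- track$glyphs[track$glyphs$rank == b$rank, , drop = FALSE]
    roster <- paste0(g$tf_class, ifelse(g$overlap, "*", ""), collapse = " ")
    out <- c(out, sprintf(
      "  module %d [%d-%d]: %s", b$rank, b$start, b$end, roster
    ))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Plot a region track with ggplot2
#'
#' @param object A `region_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_track
#' @export
autoplot.region_track <- function(object, ...) {
  boxes <- object$boxes
  glyphs <- object$glyphs
  if (nrow(boxes) > 0) {
    glyphs <- glyphs |>
      dplyr::left_join(boxes, by = "rank", suffix = c("", ".box")) |>
      dplyr::group_by(.data$rank) |>
      dplyr::mutate(
        gx0 = .data$x0 + (.data$order - 1) * (.data$x1 - .data$x0) / dplyr::n(),
        gx1 = .data$x0 + .data$order * (.data$x1 - .data$x0) / dplyr::n()
      ) |>
      dplyr::ungroup()
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = data.frame(x = 0, xend = 1),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 0.3
    )
  if (nrow(boxes) > 0) {
    p <- p +
      ggplot2::geom_rect(
        data = boxes,
        ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = -0.4, ymax = 0.4),
        fill = NA, color = "black"
      ) +
      ggplot2::geom_rect(
        data = glyphs,
        ggplot2::aes(
          xmin = .data$gx0, xmax = .data$gx1, ymin = -0.32, ymax = 0.32,
          fill = .data$tf_class
        ),
        color = "white", linewidth = 0.2
      ) +
      ggplot2::scale_fill_manual(values = tf_colors(), name = NULL)
  }
  p +
    ggplot2::scale_x_continuous(
      labels = function(x) round(x * object$region_length),
      name = "position (nt, distal to TSS)"
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-1, 1)) +
    ggplot2::ggtitle(object$region_id) +
    ggplot2::theme_minimal()
}
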