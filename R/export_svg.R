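# Deterministic, hand-assembled SVG exports (heat map and list view).
# SVG text is produced directly so that identical in-memory models always
# yield byte-identical files.

#' Linear white-to-red color ramp
#'
#' Interpolates linearly in RGB from white (count 0) to a saturated red,
#' RGB (178, 24, 43), at the domain maximum.
#'
#' @param counts numeric vector of cell counts.
#' @param max_count domain maximum (> 0).
#' @return character vector of `rgb(r,g,b)` strings.
#' @export
color_ramp <- function(counts, max_count) {
  if (max_count <= 0) stop_dz("dz_validation_error", "max_count must be > 0")
  f <- pmin(pmax(counts / max_count, 0), 1)
  hi <- c(178, 24, 43)
  sprintf("rgb(%d,%d,%d)",
          round(255 + f * (hi[1] - 255)),
          round(255 + f * (hi[2] - 255)),
          round(255 + f * (hi[3] - 255)))
}

svg_header <- function(width, height) {
  c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
           "height=\"%d\" viewBox=\"0 0 %d %d\" font-family=\"monospace\">"),
    width, height, width, height))
}

residue_label <- function(name, number) sprintf("%s %d", name, number)

#' Export the frequency matrix as an SVG heat map
#'
#' One rectangle per nonzero cell, filled from the white-to-red
#' [color_ramp()] over `[0, max count]`; axis labels are `NAME number`.
#' Output is a deterministic function of the matrix.
#'
#' @param matrix a non-empty `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(matrix, path) {
  if (nrow(matrix$cells) == 0L) {
    stop_dz("dz_export_error", "cannot export an empty matrix")
  }
  cell <- 18L; label_w <- 80L; label_h <- 70L; pad <- 4L
  nr <- nrow(matrix$rows); nc <- nrow(matrix$cols)
  width <- label_w + nc * cell + pad
  height <- label_h + nr * cell + pad
  maxc <- max(matrix$cells$count)
  out <- svg_header(width, height)
  ri <- match(matrix$cells$row_key, matrix$rows$key)
  ci <- match(matrix$cells$col_key, matrix$cols$key)
  fills <- color_ramp(matrix$cells$count, maxc)
  out <- c(out, sprintf(
    paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" ",
           "fill=\"%s\" stroke=\"#888\"><title>%s x %s: %d/%d",
           "</title></rect>"),
    label_w + (ci - 1L) * cell, label_h + (ri - 1L) * cell, cell, cell,
    fills, matrix$cells$row_key, matrix$cells$col_key,
    matrix$cells$count, matrix$n))
  out <- c(out, sprintf(
    "<text x=\"%d\" y=\"%d\" font-size=\"10\" text-anchor=\"end\">%s</text>",
    label_w - 4L, label_h + (seq_len(nr) - 1L) * cell + 13L,
    residue_label(matrix$rows$name, matrix$rows$number)))
  out <- c(out, sprintf(
    paste0("<text x=\"%d\" y=\"%d\" font-size=\"10\" text-anchor=\"start\" ",
           "transform=\"rotate(-60 %d %d)\">%s</text>"),
    label_w + (seq_len(nc) - 1L) * cell + 9L, label_h - 6L,
    label_w + (seq_len(nc) - 1L) * cell + 9L, label_h - 6L,
    residue_label(matrix$cols$name, matrix$cols$number)))
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

lv_geom <- list(row_h = 16L, col_w = 70L, gap = 60L, pad = 10L,
                panel_gap = 30L, header = 18L)

panel_svg <- function(model, x0, highlight_pairs = character(0),
                      placeholders = character(0), primary_left = NULL,
                      title = "") {
  g <- lv_geom
  # rows: placeholders are injected at their primary-left positions
  left_keys <- model$left$key
  rows <- if (length(placeholders) && !is.null(primary_left)) {
    ord <- primary_left[primary_left %in% c(left_keys, placeholders)]
    c(ord, setdiff(left_keys, ord))
  } else left_keys
  y_of_left <- function(k) g$header + (match(k, rows) - 1L) * g$row_h
  out <- sprintf(
    "<text x=\"%d\" y=\"%d\" font-size=\"11\">%s</text>",
    x0, g$header - 6L, title)
  # left rectangles
  for (i in seq_len(nrow(model$left))) {
    k <- model$left$key[i]
    out <- c(out, sprintf(
      paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" ",
             "fill=\"#d8e6f2\" stroke=\"#555\"/>",
             "<text x=\"%d\" y=\"%d\" font-size=\"9\">%s %s</text>"),
      x0, y_of_left(k), g$col_w, g$row_h - 2L,
      x0 + 3L, y_of_left(k) + 11L, model$left$name[i], k))
  }
  # placeholders (compare mode): white rectangles with labels
  for (k in placeholders) {
    out <- c(out, sprintf(
      paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" ",
             "fill=\"white\" stroke=\"#bbb\"/>",
             "<text x=\"%d\" y=\"%d\" font-size=\"9\" fill=\"#999\">%s",
             "</text>"),
      x0, y_of_left(k), g$col_w, g$row_h - 2L,
      x0 + 3L, y_of_left(k) + 11L, k))
  }
  # right rectangles + connection lines, one per contact pair
  xr <- x0 + g$col_w + g$gap
  for (j in seq_len(nrow(model$right))) {
    r <- model$right[j, ]
    lk <- model$left$key[r$left_index]
    pairkey <- paste(lk, r$key, sep = "\r")
    hit <- pairkey %in% highlight_pairs
    yr <- g$header + (j - 1L) * g$row_h
    out <- c(out, sprintf(
      paste0("<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" ",
             "fill=\"#f2e8d8\" stroke=\"%s\" stroke-width=\"%s\"/>",
             "<text x=\"%d\" y=\"%d\" font-size=\"9\">%s %s</text>"),
      xr, yr, g$col_w, g$row_h - 2L,
      if (hit) "#b2182b" else "#555", if (hit) "2" else "1",
      xr + 3L, yr + 11L, r$name, r$key))
    out <- c(out, sprintf(
      paste0("<line x1=\"%d\" y1=\"%d\" x2=\"%d\" y2=\"%d\" ",
             "stroke=\"%s\"/>"),
      x0 + g$col_w, y_of_left(lk) + g$row_h %/% 2L,
      xr, yr + g$row_h %/% 2L,
      if (hit) "#b2182b" else "#333"))
  }
  list(svg = out,
       n_rows = max(length(rows), nrow(model$right)),
       width = g$col_w * 2L + g$gap)
}

#' Export a comparison model as an SVG list view
#'
#' Panels are laid out left to right in rank order with the primary
#' leftmost. Pairs matching the primary get red-bordered rectangles and
#' red connection lines; in compare mode, primary residues missing from a
#' compared zone appear as white placeholder rectangles (compact mode
#' omits them).
#'
#' @param cmp a `comparison_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_listview_svg <- function(cmp, path) {
  g <- lv_geom
  x0 <- g$pad
  all_pairs <- paste(
    cmp$primary$left$key[cmp$primary$right$left_index],
    cmp$primary$right$key, sep = "\r")
  body <- character(0)
  max_rows <- 0L
  p <- panel_svg(cmp$primary, x0, highlight_pairs = all_pairs,
                 title = paste0("primary: ", cmp$primary$config_id))
  body <- c(body, p$svg)
  max_rows <- max(max_rows, p$n_rows)
  x0 <- x0 + p$width + g$panel_gap
  for (panel in cmp$panels) {
    ps <- panel_svg(panel$model, x0,
                    highlight_pairs = panel$matched_pairs,
                    placeholders = panel$placeholders,
                    primary_left = cmp$primary$left$key,
                    title = panel$model$config_id)
    body <- c(body, ps$svg)
    max_rows <- max(max_rows, ps$n_rows)
    x0 <- x0 + ps$width + g$panel_gap
  }
  width <- x0 + g$pad
  height <- g$header + max_rows * g$row_h + g$pad
  writeLines(c(svg_header(width, height), body, "</svg>"), path)
  invisible(path)
}

#' Export a layout plan (exploded view) as JSON
#'
#' Per configuration a 4x4 row-major homogeneous matrix for the paired
#' unit (reference units stay in place), tube endpoints, and the grid
#' parameters.
#'
#' @param plan a `layout_plan` from [exploded_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_layout_json <- function(plan, path) {
  obj <- list(
    grid = plan$grid,
    configurations = lapply(seq_len(nrow(plan$slots)), function(i) {
      s <- plan$slots[i, ]
      tf <- plan$transforms[[s$config_id]]
      list(config_id = s$config_id,
           paired_matrix = as.vector(t(rigid_to_matrix(tf))),
           reference_matrix = as.vector(t(diag(4))),
           tube = list(
             reference = c(s$tube_ref_x, s$tube_ref_y, s$tube_ref_z),
             paired = c(s$tube_paired_x, s$tube_paired_y, s$tube_paired_z)),
           slot = c(s$slot_x, s$slot_y, s$slot_z),
           bounding_radius = s$radius)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export an open-book result as JSON
#'
#' @param ob an `open_book_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_openbook_json <- function(ob, path) {
  obj <- list(
    reference_matrix = as.vector(t(rigid_to_matrix(ob$transform_ref))),
    paired_matrix = as.vector(t(rigid_to_matrix(ob$transform_paired))),
    normal_ref_before = ob$normal_ref_before,
    normal_paired_before = ob$normal_paired_before,
    normal_ref_after = ob$normal_ref_after,
    normal_paired_after = ob$normal_paired_after,
    view_dir = ob$view_dir, separation_axis = ob$separation_axis,
    gap = ob$gap
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
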