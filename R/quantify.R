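#' Convert a shift map to an elastic-contrast map
#'
#' Elementwise application of [shift_to_contrast()]; grid metadata (pixel
#' size, origin) is preserved.
#'
#' @param map A [shift_map()].
#' @param config An [optical_config()].
#' @return A [contrast_map()].
#' @export
to_contrast_map <- function(map, config = optical_config()) {
  stopifnot(inherits(map, "shift_map"))
  v <- matrix(shift_to_contrast(map$values, config),
              nrow(map$values), ncol(map$values))
  contrast_map(v, pixel_um = map$pixel_um, origin_um = map$origin_um)
}

#' Rectangular region of interest
#'
#' Axis-aligned rectangle in map coordinates (micrometres). Pixel
#' membership is by pixel-centre inclusion in the half-open rectangle
#' `[x, x + width) x [y, y + height)`, which partitions the plane
#' unambiguously when ROIs tile it.
#'
#' @param x_um,y_um Top-left corner.
#' @param width_um,height_um Positive extent.
#' @return A `rect_roi` list.
#' @export
rect_roi <- function(x_um, y_um, width_um, height_um) {
  stopifnot(is.numeric(x_um), is.numeric(y_um),
            width_um > 0, height_um > 0)
  structure(list(x_um = x_um, y_um = y_um, width_um = width_um,
                 height_um = height_um), class = "rect_roi")
}

# logical matrix of pixels whose centres fall inside the ROI
.roi_mask <- function(map, roi) {
  xs <- .map_x(map); ys <- .map_y(map)
  inx <- xs >= roi$x_um & xs < roi$x_um + roi$width_um
  iny <- ys >= roi$y_um & ys < roi$y_um + roi$height_um
  outer(iny, inx, `&`)
}

#' Mean contrast inside a rectangular ROI
#'
#' Arithmetic mean over all pixels whose centres fall inside the ROI.
#'
#' @param map A [contrast_map()].
#' @param roi A [rect_roi()]; must contain at least one pixel centre and
#'   lie within the map bounds.
#' @return Mean elastic contrast (scalar).
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "contrast_map"), inherits(roi, "rect_roi"))
  xs <- .map_x(map); ys <- .map_y(map)
  half <- map$pixel_um / 2
  if (roi$x_um < min(xs) - half || roi$x_um + roi$width_um > max(xs) + half ||
      roi$y_um < min(ys) - half || roi$y_um + roi$height_um > max(ys) + half)
    stop("ROI extends outside the map bounds", call. = FALSE)
  sel <- .roi_mask(map, roi)
  if (!any(sel)) stop("ROI contains no pixel centres", call. = FALSE)
  mean(map$values[sel])
}

#' Mask-based means: chondrocytes versus ECM
#'
#' Quantifies a contrast map through its paired label mask: one mean per
#' individual chondrocyte (by `cell_id`) and a single mean over all
#' ECM-labelled pixels, each with its pixel count. A label class absent
#' from the mask is flagged absent rather than reported as zero.
#'
#' @param map A [contrast_map()].
#' @param mask A [label_mask()] on the same grid.
#' @return List with `cells` (`data.frame`: `cell_id`, `mean`, `n_pixels`;
#'   zero rows when no chondrocytes), `ecm_mean`, `ecm_n`, and logical
#'   flags `has_cells`, `has_ecm`.
#' @export
mask_means <- function(map, mask) {
  stopifnot(inherits(map, "contrast_map"), inherits(mask, "label_mask"))
  if (!all(dim(map$values) == dim(mask$labels)))
    stop("mask shape does not match map shape", call. = FALSE)
  has_ecm <- any(mask$labels == "ecm")
  ecm_mean <- if (has_ecm) mean(map$values[mask$labels == "ecm"]) else NA_real_
  ids <- mask$cell_ids
  if (is.null(ids)) ids <- matrix(0L, nrow(mask$labels), ncol(mask$labels))
  cell_px <- mask$labels == "chondrocyte"
  has_cells <- any(cell_px)
  cells <- if (has_cells) {
    sp <- split(map$values[cell_px], ids[cell_px])
    data.frame(cell_id = as.integer(names(sp)),
               mean = vapply(sp, mean, numeric(1)),
               n_pixels = lengths(sp), row.names = NULL)
  } else {
    data.frame(cell_id = integer(0), mean = numeric(0),
               n_pixels = integer(0))
  }
  list(cells = cells, ecm_mean = ecm_mean,
       ecm_n = sum(mask$labels == "ecm"),
       has_cells = has_cells, has_ecm = has_ecm)
}

#' Line profile container
#'
#' Ordered positions (micrometres, or percent of structure half-width
#' after [normalize_profile()]) with elastic-contrast values.
#'
#' @param positions Strictly increasing numeric positions.
#' @param values Contrast values, same length.
#' @param normalized Logical: positions on the normalized \[-100, 100\]
#'   scale?
#' @return A `line_profile` list.
#' @export
line_profile <- function(positions, values, normalized = FALSE) {
  stopifnot(is.numeric(positions), is.numeric(values),
            length(positions) == length(values), length(positions) >= 1L)
  if (any(diff(positions) <= 0))
    stop("profile positions must be strictly increasing", call. = FALSE)
  structure(list(positions = positions, values = values,
                 normalized = isTRUE(normalized)),
            class = "line_profile")
}

#' Averaged transversal line profiles
#'
#' Emulates the manual line-profile procedure: five consecutive parallel
#' transversal lines of 1 um nominal width, separated by 5 um, are drawn
#' across the structure, sampled, and averaged position-wise into a single
#' profile per map. On grids with pixels of 2 um or more the 1 um line
#' width is sub-pixel, so each line is realized as a single pixel column
#' (or row); the 5 um separation is rounded to the nearest whole-pixel
#' offset and the realized spacing is recorded in the result's
#' `realized_spacing_um` attribute.
#'
#' @param map A [contrast_map()].
#' @param anchor_um Coordinate (um) of the first line along the
#'   longitudinal axis: an x position for `orientation = "vertical"`
#'   lines, a y position for `"horizontal"`.
#' @param orientation `"vertical"` (default; lines run along y, the
#'   transversal axis of a digit lying along x) or `"horizontal"`.
#' @param n_lines Number of parallel lines (default 5).
#' @param spacing_um Nominal line separation (default 5).
#' @return A `line_profile` in micrometres along the transversal axis,
#'   with attribute `realized_spacing_um`.
#' @export
transversal_profiles <- function(map, anchor_um, orientation = c("vertical",
                                                                 "horizontal"),
                                 n_lines = 5L, spacing_um = 5) {
  stopifnot(inherits(map, "contrast_map"), n_lines >= 1L, spacing_um > 0)
  orientation <- match.arg(orientation)
  step_px <- max(1L, as.integer(round(spacing_um / map$pixel_um)))
  realized <- step_px * map$pixel_um
  along <- if (orientation == "vertical") .map_x(map) else .map_y(map)
  first <- which.min(abs(along - anchor_um))
  idx <- first + (seq_len(n_lines) - 1L) * step_px
  if (max(idx) > length(along))
    stop(sprintf(
      "%d lines spaced %g um from anchor %g um exceed the map extent",
      n_lines, realized, anchor_um), call. = FALSE)
  lines <- if (orientation == "vertical")
    map$values[, idx, drop = FALSE]
  else
    t(map$values[idx, , drop = FALSE])
  positions <- if (orientation == "vertical") .map_y(map) else .map_x(map)
  prof <- line_profile(positions, rowMeans(lines), normalized = FALSE)
  attr(prof, "realized_spacing_um") <- realized
  attr(prof, "line_coords_um") <- along[idx]
  prof
}

#' Size-normalize a line profile
#'
#' Normalizes structure size so profiles from differently sized limbs are
#' comparable: the structure edges are the outermost profile positions
#' whose value is at or above `edge_threshold` (default 0.006, the elastic
#' contrast of the surrounding benzocaine medium); the midpoint between
#' the edges maps to 0 and the edges to -100 and +100 percent. Positions
#' are rescaled linearly, values are unchanged, and the output is
#' restricted to \[-100, 100\]. No interpolation or smoothing is applied:
#' isolated sub-threshold dips interior to the structure do not move the
#' edges.
#'
#' @param profile A `line_profile` in micrometres.
#' @param edge_threshold Contrast value defining the structure edge.
#' @return A normalized `line_profile` (positions in percent).
#' @export
normalize_profile <- function(profile, edge_threshold = 0.006) {
  stopifnot(inherits(profile, "line_profile"))
  above <- which(profile$values >= edge_threshold)
  if (length(above) < 2L)
    stop("no structure found: fewer than 2 positions reach the edge threshold",
         call. = FALSE)
  left <- profile$positions[min(above)]
  right <- profile$positions[max(above)]
  centre <- (left + right) / 2
  half <- (right - left) / 2
  pos <- (profile$positions - centre) / half * 100
  keep <- pos >= -100 - 1e-9 & pos <= 100 + 1e-9
  line_profile(pmin(pmax(pos[keep], -100), 100), profile$values[keep],
               normalized = TRUE)
}

#' Digit length ratios normalized to day 0
#'
#' Regeneration progress metric: each digit's length at every time point is
#' divided by its own day-0 length, so intact growth and regrowth after
#' amputation are on a common scale.
#'
#' @param lengths `data.frame` with columns `digit` (identifier, e.g.
#'   animal x amputated/contralateral), `timepoint` (numeric, must include
#'   0 for every digit) and `length_um` (> 0 at day 0).
#' @return The input with a `ratio` column, `length_um / length at day 0`.
#' @export
digit_length_ratio <- function(lengths) {
  stopifnot(is.data.frame(lengths),
            all(c("digit", "timepoint", "length_um") %in% names(lengths)))
  sp <- split(lengths, lengths$digit)
  out <- lapply(sp, function(d) {
    L0 <- d$length_um[d$timepoint == 0]
    if (length(L0) != 1L || !is.finite(L0) || L0 <= 0)
      stop(sprintf("digit '%s': missing or non-positive day-0 length",
                   d$digit[1]), call. = FALSE)
    d$ratio <- d$length_um / L0
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a line profile as CSV
#'
#' Two columns, `position` (um or percent) and `value` (contrast), at full
#' double precision.
#'
#' @param profile A `line_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  df <- data.frame(position = .fmt_num(profile$positions),
                   value = .fmt_num(profile$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
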