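#' @name map-containers
#' @title Grid containers for Brillouin maps and label masks
#'
#' @description
#' A map is a rectangular grid of per-pixel values with square pixels of
#' known physical size. The grid convention, used throughout the package,
#' is: matrix rows index y (downwards), columns index x (rightwards);
#' coordinates refer to pixel centres in micrometres; the origin is the
#' centre of the top-left pixel.
#'
#' * `shift_map()` holds Brillouin frequency shifts in GHz (all finite,
#'   positive).
#' * `contrast_map()` holds the dimensionless elastic contrast (all finite,
#'   > -1).
#' * `label_mask()` holds tissue-region labels over the closed set
#'   medium, epidermis, interstitial, ecm, chondrocyte, joint — optionally
#'   with per-pixel integer `cell_ids` identifying individual chondrocytes
#'   (0 = not a cell).
#'
#' @param values Numeric matrix of pixel values.
#' @param pixel_um Pixel edge length in micrometres, positive.
#' @param origin_um Length-2 numeric, (x, y) of the top-left pixel centre.
#' @param labels Character matrix of tissue labels.
#' @param cell_ids Optional integer matrix, same shape as `labels`,
#'   non-zero exactly on `"chondrocyte"` pixels.
#' @return An object of class `shift_map`, `contrast_map` or `label_mask`.
NULL

#' Closed set of tissue-region labels
#' @export
TISSUE_LABELS <- c("medium", "epidermis", "interstitial", "ecm",
                   "chondrocyte", "joint")

.check_grid <- function(values, pixel_um, origin_um) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L ||
      !is.finite(pixel_um) || pixel_um <= 0)
    stop("`pixel_um` must be a single positive length", call. = FALSE)
  if (!is.numeric(origin_um) || length(origin_um) != 2L ||
      any(!is.finite(origin_um)))
    stop("`origin_um` must be a finite (x, y) pair", call. = FALSE)
  invisible(TRUE)
}

#' @rdname map-containers
#' @export
shift_map <- function(values, pixel_um, origin_um = c(0, 0)) {
  .check_grid(values, pixel_um, origin_um)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("shift values must all be finite and positive", call. = FALSE)
  structure(list(values = values, pixel_um = pixel_um,
                 origin_um = as.numeric(origin_um)),
            class = "shift_map")
}

#' @rdname map-containers
#' @export
contrast_map <- function(values, pixel_um, origin_um = c(0, 0)) {
  .check_grid(values, pixel_um, origin_um)
  if (any(!is.finite(values)) || any(values <= -1))
    stop("contrast values must all be finite and > -1", call. = FALSE)
  structure(list(values = values, pixel_um = pixel_um,
                 origin_um = as.numeric(origin_um)),
            class = "contrast_map")
}

#' @rdname map-containers
#' @export
label_mask <- function(labels, pixel_um, origin_um = c(0, 0),
                       cell_ids = NULL) {
  if (!is.matrix(labels) || !is.character(labels))
    stop("`labels` must be a character matrix", call. = FALSE)
  .check_grid(matrix(0, nrow(labels), ncol(labels)), pixel_um, origin_um)
  bad <- setdiff(unique(as.vector(labels)), TISSUE_LABELS)
  if (length(bad))
    stop("unknown tissue labels: ", toString(bad), call. = FALSE)
  if (!is.null(cell_ids)) {
    if (!is.matrix(cell_ids) || !all(dim(cell_ids) == dim(labels)))
      stop("`cell_ids` must match the shape of `labels`", call. = FALSE)
    storage.mode(cell_ids) <- "integer"
    if (any((cell_ids != 0L) != (labels == "chondrocyte")))
      stop("`cell_ids` must be non-zero exactly on chondrocyte pixels",
           call. = FALSE)
  }
  structure(list(labels = labels, pixel_um = pixel_um,
                 origin_um = as.numeric(origin_um), cell_ids = cell_ids),
            class = "label_mask")
}

#' @export
print.shift_map <- function(x, ...) {
  cat(sprintf("<shift_map> %d x %d px @ %g um, shifts %.4f-%.4f GHz\n",
              nrow(x$values), ncol(x$values), x$pixel_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %d x %d px @ %g um, contrast %.4f-%.4f\n",
              nrow(x$values), ncol(x$values), x$pixel_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = TISSUE_LABELS))
  cat(sprintf("<label_mask> %d x %d px @ %g um\n",
              nrow(x$labels), ncol(x$labels), x$pixel_um))
  print(tab[tab > 0])
  invisible(x)
}

# x/y coordinates (um) of pixel centres, column- and row-wise
.map_x <- function(map) map$origin_um[1] + (seq_len(ncol(map[[1]])) - 1L) * map$pixel_um
.map_y <- function(map) map$origin_um[2] + (seq_len(nrow(map[[1]])) - 1L) * map$pixel_um

# full-precision numeric serialization so write/read round trips are exact
.fmt_num <- function(x) sprintf("%.17g", x)

# long-format lattice -> matrix; errors carry 1-based data row numbers
.lattice_to_matrix <- function(x_um, y_um, what = "lattice") {
  xs <- sort(unique(x_um))
  ys <- sort(unique(y_um))
  if (length(xs) > 1L) {
    dx <- diff(xs)
    if (max(abs(dx - dx[1])) > 1e-9 * max(abs(xs), 1))
      stop(sprintf("%s: x coordinates are not a uniform lattice", what),
           call. = FALSE)
  }
  if (length(ys) > 1L) {
    dy <- diff(ys)
    if (max(abs(dy - dy[1])) > 1e-9 * max(abs(ys), 1))
      stop(sprintf("%s: y coordinates are not a uniform lattice", what),
           call. = FALSE)
  }
  px <- if (length(xs) > 1L) xs[2] - xs[1] else if (length(ys) > 1L) ys[2] - ys[1] else 1
  py <- if (length(ys) > 1L) ys[2] - ys[1] else px
  if (abs(px - py) > 1e-9 * max(px, py))
    stop(sprintf("%s: x pitch (%g) and y pitch (%g) differ; pixels must be square",
                 what, px, py), call. = FALSE)
  ri <- match(y_um, ys)
  ci <- match(x_um, xs)
  idx <- (ci - 1L) * length(ys) + ri
  dup <- which(duplicated(idx))
  if (length(dup))
    stop(sprintf("%s: duplicate coordinates at data row %d", what, dup[1]),
         call. = FALSE)
  if (length(idx) != length(xs) * length(ys))
    stop(sprintf(
      "%s: ragged lattice (%d points, expected %d for a %d x %d grid)",
      what, length(idx), length(xs) * length(ys), length(ys), length(xs)),
      call. = FALSE)
  list(ri = ri, ci = ci, nrow = length(ys), ncol = length(xs),
       pixel_um = px, origin_um = c(xs[1], ys[1]))
}

.read_checked_csv <- function(path, cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df)[seq_along(cols)], cols))
    stop(sprintf("%s: expected header %s, found %s", path,
                 toString(cols), toString(names(df))), call. = FALSE)
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' in column %s at data row %d",
                   path, df[[cl]][bad[1]], cl, bad[1]), call. = FALSE)
    df[[cl]] <- v
  }
  df
}

#' Read / write a Brillouin shift map as CSV
#'
#' The on-disk format is a long-format CSV with mandatory header
#' `x_um,y_um,shift_GHz`, one row per pixel centre, forming a complete
#' rectangular lattice with uniform square pitch. Values are serialized at
#' full double precision, so `write_map_csv()` then [read_map_csv()] is
#' bit-exact.
#'
#' @param path Path of the CSV file.
#' @param map A [shift_map()].
#' @return `read_map_csv()` returns a [shift_map()]; `write_map_csv()`
#'   returns `path` invisibly.
#' @export
read_map_csv <- function(path) {
  df <- .read_checked_csv(path, c("x_um", "y_um", "shift_GHz"),
                          c("x_um", "y_um", "shift_GHz"))
  lat <- .lattice_to_matrix(df$x_um, df$y_um, what = path)
  m <- matrix(NA_real_, lat$nrow, lat$ncol)
  m[cbind(lat$ri, lat$ci)] <- df$shift_GHz
  shift_map(m, pixel_um = lat$pixel_um, origin_um = lat$origin_um)
}

#' @rdname read_map_csv
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "shift_map"))
  xs <- .map_x(map); ys <- .map_y(map)
  df <- data.frame(
    x_um = .fmt_num(rep(xs, each = length(ys))),
    y_um = .fmt_num(rep(ys, times = length(xs))),
    shift_GHz = .fmt_num(as.vector(map$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a tissue label mask as CSV
#'
#' Long-format CSV with header `x_um,y_um,label,cell_id` over the same
#' lattice convention as [read_map_csv()]. `cell_id` is 0 away from
#' chondrocytes.
#'
#' @param path Path of the CSV file.
#' @param mask A [label_mask()].
#' @return `read_mask_csv()` returns a [label_mask()].
#' @export
read_mask_csv <- function(path) {
  df <- .read_checked_csv(path, c("x_um", "y_um", "label", "cell_id"),
                          c("x_um", "y_um", "cell_id"))
  bad <- which(!(df$label %in% TISSUE_LABELS))
  if (length(bad))
    stop(sprintf("%s: unknown label '%s' at data row %d", path,
                 df$label[bad[1]], bad[1]), call. = FALSE)
  lat <- .lattice_to_matrix(df$x_um, df$y_um, what = path)
  lab <- matrix(NA_character_, lat$nrow, lat$ncol)
  lab[cbind(lat$ri, lat$ci)] <- df$label
  ids <- matrix(0L, lat$nrow, lat$ncol)
  ids[cbind(lat$ri, lat$ci)] <- as.integer(df$cell_id)
  label_mask(lab, pixel_um = lat$pixel_um, origin_um = lat$origin_um,
             cell_ids = ids)
}

#' @rdname read_mask_csv
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  xs <- mask$origin_um[1] + (seq_len(ncol(mask$labels)) - 1L) * mask$pixel_um
  ys <- mask$origin_um[2] + (seq_len(nrow(mask$labels)) - 1L) * mask$pixel_um
  ids <- mask$cell_ids
  if (is.null(ids)) ids <- matrix(0L, nrow(mask$labels), ncol(mask$labels))
  df <- data.frame(
    x_um = .fmt_num(rep(xs, each = length(ys))),
    y_um = .fmt_num(rep(ys, times = length(xs))),
    label = as.vector(mask$labels),
    cell_id = as.integer(as.vector(ids)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort tables of per-animal measurements
#'
#' A cohort table is the long-format record consumed by the statistics
#' suite: one row per (animal, condition) with the per-animal averaged
#' elastic contrast (or any scalar outcome). Conditions keep a declared
#' order, which downstream tests use to label post hoc pairs.
#'
#' @param animal_id Character vector of animal identifiers.
#' @param condition Character vector of condition labels.
#' @param value Numeric outcome values.
#' @param condition_levels Ordered set of allowed conditions; defaults to
#'   order of first appearance.
#' @return A `data.frame` of class `cohort_table` with attribute
#'   `condition_levels`.
#' @export
cohort_table <- function(animal_id, condition, value,
                         condition_levels = unique(condition)) {
  stopifnot(length(animal_id) == length(condition),
            length(condition) == length(value), is.numeric(value))
  animal_id <- as.character(animal_id)
  condition <- as.character(condition)
  if (!all(condition %in% condition_levels))
    stop("conditions outside the declared ordered set: ",
         toString(setdiff(condition, condition_levels)), call. = FALSE)
  key <- paste(animal_id, condition, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (animal, condition) pair at row %d: (%s, %s)",
                 dup[1], animal_id[dup[1]], condition[dup[1]]),
         call. = FALSE)
  structure(data.frame(animal_id = animal_id, condition = condition,
                       value = value, stringsAsFactors = FALSE),
            condition_levels = as.character(condition_levels),
            class = c("cohort_table", "data.frame"))
}

#' Read / write a cohort table as CSV
#'
#' Header `animal_id,condition,value`; duplicate (animal, condition) pairs
#' are a format error. Row order is preserved by the round trip.
#'
#' @param path Path of the CSV file.
#' @param cohort A [cohort_table()].
#' @param condition_levels Optional declared condition order for the table
#'   read back; defaults to order of first appearance in the file.
#' @return `read_cohort_csv()` returns a [cohort_table()].
#' @export
read_cohort_csv <- function(path, condition_levels = NULL) {
  df <- .read_checked_csv(path, c("animal_id", "condition", "value"),
                          "value")
  if (is.null(condition_levels)) condition_levels <- unique(df$condition)
  cohort_table(df$animal_id, df$condition, df$value, condition_levels)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- data.frame(animal_id = cohort$animal_id,
                   condition = cohort$condition,
                   value = .fmt_num(cohort$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a contrast map as a heat-map image
#'
#' Writes a PNG raster of the map with a fixed colour ramp; values outside
#' `color_limits` are clamped to the end colours. Rendering is
#' deterministic: identical map and limits give byte-identical files.
#'
#' @param map A [contrast_map()].
#' @param color_limits Length-2 numeric `(low, high)`, `low < high`, both
#'   finite.
#' @param path Output PNG path.
#' @param px_per_pixel Integer magnification (image pixels per map pixel).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, color_limits, path, px_per_pixel = 4L) {
  stopifnot(inherits(map, "contrast_map"))
  if (length(color_limits) != 2L || any(!is.finite(color_limits)) ||
      color_limits[1] >= color_limits[2])
    stop("`color_limits` must be finite with low < high", call. = FALSE)
  v <- map$values
  if (length(v) == 0L) stop("empty map", call. = FALSE)
  v <- pmin(pmax(v, color_limits[1]), color_limits[2])
  pal <- grDevices::hcl.colors(256L, "viridis")
  nr <- nrow(v); nc <- ncol(v)
  grDevices::png(path, width = nc * px_per_pixel, height = nr * px_per_pixel)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  # image() draws row 1 at the bottom; flip so matrix row 1 (y = origin) is top
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(v[nr:1, , drop = FALSE]),
                  zlim = color_limits, col = pal, axes = FALSE,
                  xlab = "", ylab = "", useRaster = TRUE)
  invisible(path)
}
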