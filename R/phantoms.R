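#' Region specification for tissue phantoms
#'
#' A phantom region is a tissue label plus the Gaussian contrast model that
#' fills it: per-pixel contrast ~ Normal(`mean_contrast`, `sd_contrast`).
#' The medium default (0.006) corresponds to the anaesthetic benzocaine
#' solution surrounding the animal, which also serves as the edge-detection
#' threshold for line profiles.
#'
#' @param label One of the tissue labels in [TISSUE_LABELS].
#' @param mean_contrast Mean elastic contrast, > -1.
#' @param sd_contrast Standard deviation of the per-pixel contrast, >= 0.
#' @return A `region_spec` list.
#' @export
region_spec <- function(label, mean_contrast, sd_contrast = 0) {
  if (!label %in% TISSUE_LABELS)
    stop("unknown tissue label: ", label, call. = FALSE)
  stopifnot(is.numeric(mean_contrast), mean_contrast > -1,
            is.numeric(sd_contrast), sd_contrast >= 0)
  structure(list(label = label, mean_contrast = mean_contrast,
                 sd_contrast = sd_contrast), class = "region_spec")
}

.default_regions <- function() {
  list(
    medium = region_spec("medium", 0.006, 0.002),
    epidermis = region_spec("epidermis", 0.040, 0.004),
    interstitial = region_spec("interstitial", 0.030, 0.004),
    ecm = region_spec("ecm", 0.060, 0.004),
    chondrocyte = region_spec("chondrocyte", 0.045, 0.004))
}

#' Phantom specification for a digit map
#'
#' Describes the synthetic digit geometry rendered by
#' [render_digit_phantom()]: a horizontal cartilage (ECM) band through the
#' map centre containing non-overlapping oval chondrocytes, wrapped
#' symmetrically (moving outward in y) by interstitial space, an epidermis
#' layer, and the surrounding medium. All thicknesses are in micrometres
#' and are realized at pixel resolution.
#'
#' @param width_um,height_um Map extent in micrometres; must be multiples
#'   of `pixel_um`.
#' @param pixel_um Pixel size in micrometres.
#' @param regions Named list of [region_spec()]s; any label absent from the
#'   rendered geometry is allowed to be missing.
#' @param cell_count Number of chondrocyte ovals to place.
#' @param cell_radii_um Length-2 (x, y) semi-axes of the cell ovals.
#' @param epidermis_um,interstitial_um,medium_margin_um Layer thicknesses
#'   on each side of the band (y direction).
#' @param joint Optional `list(x_um =, width_um =, mean_contrast =)`
#'   describing a vertical joint strip inside the cartilage band.
#' @param core_label Tissue label of the central band: `"ecm"` (default,
#'   a cartilage band) or `"interstitial"` (homogeneous limb bud with no
#'   distinct cartilage; requires `cell_count = 0`).
#' @param seed Integer seed; all rendering is a pure function of
#'   (spec, seed).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width_um = 148, height_um = 80, pixel_um = 2,
                         regions = .default_regions(),
                         cell_count = 13, cell_radii_um = c(8, 5),
                         epidermis_um = 6, interstitial_um = 6,
                         medium_margin_um = 4, joint = NULL,
                         core_label = "ecm", seed = 1L) {
  stopifnot(width_um > 0, height_um > 0, pixel_um > 0,
            cell_count >= 0, length(cell_radii_um) == 2L,
            all(cell_radii_um > 0), epidermis_um >= 0,
            interstitial_um >= 0, medium_margin_um >= 0)
  if (abs(width_um / pixel_um - round(width_um / pixel_um)) > 1e-9 ||
      abs(height_um / pixel_um - round(height_um / pixel_um)) > 1e-9)
    stop("map extent must be a whole number of pixels", call. = FALSE)
  band_um <- height_um -
    2 * (medium_margin_um + epidermis_um + interstitial_um)
  if (band_um <= 0)
    stop("layer thicknesses leave no room for the cartilage band",
         call. = FALSE)
  if (cell_count > 0 && 2 * cell_radii_um[2] > band_um)
    stop("cell ovals do not fit inside the cartilage band", call. = FALSE)
  stopifnot(core_label %in% c("ecm", "interstitial"))
  if (core_label != "ecm" && cell_count > 0)
    stop("chondrocytes require an ECM core band", call. = FALSE)
  for (r in regions) stopifnot(inherits(r, "region_spec"))
  names(regions) <- vapply(regions, `[[`, "", "label")
  structure(list(width_um = width_um, height_um = height_um,
                 pixel_um = pixel_um, regions = regions,
                 cell_count = cell_count, cell_radii_um = cell_radii_um,
                 epidermis_um = epidermis_um,
                 interstitial_um = interstitial_um,
                 medium_margin_um = medium_margin_um,
                 joint = joint, core_label = core_label,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default mature-digit phantom
#'
#' Mature cartilage: the collagen-rich ECM is stiffer than the embedded
#' chondrocytes (ECM mean 0.060 > chondrocyte mean 0.045), geometry
#' 148 x 80 um at 2 um pixels as in the collagenase experiment.
#'
#' @param seed Integer seed.
#' @return A `phantom_spec`.
#' @export
mature_digit_spec <- function(seed = 1L) phantom_spec(seed = seed)

# deterministic sub-seed derivation (kept within 32-bit integer range)
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + 7919 * as.numeric(index)) %%
               .Machine$integer.max)
}

# place non-overlapping ovals on a jittered lattice along the band centre;
# uses the current RNG stream
.place_cells <- function(spec, band_top_um, band_bot_um) {
  n <- spec$cell_count
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  rx <- spec$cell_radii_um[1]; ry <- spec$cell_radii_um[2]
  y_mid <- (band_top_um + band_bot_um) / 2
  y_play <- max(0, (band_bot_um - band_top_um) / 2 - ry)
  x_lo <- rx; x_hi <- spec$width_um - rx
  band_area <- spec$width_um * (band_bot_um - band_top_um)
  if (x_hi <= x_lo || n * pi * rx * ry > 0.6 * band_area)
    stop(sprintf(
      "cannot place %d non-overlapping cells of radii (%g, %g) in a %g x %g um band",
      n, rx, ry, spec$width_um, band_bot_um - band_top_um), call. = FALSE)
  anchors <- seq(x_lo, x_hi, length.out = n)
  jit <- if (n > 1L) (anchors[2] - anchors[1]) / 2 - rx else x_hi - x_lo
  jit <- max(jit, 0)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      cx <- anchors[i] + stats::runif(1, -jit, jit)
      cy <- y_mid + stats::runif(1, -y_play, y_play)
      ok <- TRUE
      if (length(xs)) {
        # sufficient separation test for equal axis-aligned ellipses
        sep <- (((cx - xs) / (2 * rx))^2 + ((cy - ys) / (2 * ry))^2) > 1
        ok <- all(sep)
      }
      if (ok) { xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(
        "cell placement failed: could not place cell %d of %d without overlap (radii %g x %g um)",
        i, n, rx, ry), call. = FALSE)
  }
  cbind(x = xs, y = ys)
}

# label matrix + cell ids for a spec; pure function of (spec, seed)
.render_labels <- function(spec) {
  px <- spec$pixel_um
  nc <- round(spec$width_um / px)
  nr <- round(spec$height_um / px)
  xc <- (seq_len(nc) - 0.5) * px   # pixel centres relative to map edge
  yc <- (seq_len(nr) - 0.5) * px
  mm <- spec$medium_margin_um; ep <- spec$epidermis_um
  it <- spec$interstitial_um
  band_top <- mm + ep + it
  band_bot <- spec$height_um - band_top
  core <- if (is.null(spec$core_label)) "ecm" else spec$core_label
  ylab <- ifelse(yc < mm | yc >= spec$height_um - mm, "medium",
          ifelse(yc < mm + ep | yc >= spec$height_um - mm - ep, "epidermis",
          ifelse(yc < band_top | yc >= band_bot, "interstitial", core)))
  labels <- matrix(ylab, nr, nc)
  cell_ids <- matrix(0L, nr, nc)
  cells <- withr_local_seed(.sub_seed(spec$seed, 1L),
                            .place_cells(spec, band_top, band_bot))
  if (nrow(cells)) {
    rx <- spec$cell_radii_um[1]; ry <- spec$cell_radii_um[2]
    X <- matrix(xc, nr, nc, byrow = TRUE)
    Y <- matrix(yc, nr, nc)
    for (i in seq_len(nrow(cells))) {
      inside <- ((X - cells[i, 1]) / rx)^2 + ((Y - cells[i, 2]) / ry)^2 <= 1
      inside <- inside & labels == "ecm"
      labels[inside] <- "chondrocyte"
      cell_ids[inside] <- i
    }
  }
  if (!is.null(spec$joint)) {
    j <- spec$joint
    strip <- xc >= j$x_um & xc < j$x_um + j$width_um
    jmask <- matrix(rep(strip, each = nr), nr, nc) & labels == "ecm"
    labels[jmask] <- "joint"
  }
  list(labels = labels, cell_ids = cell_ids, nr = nr, nc = nc)
}

#' Render a digit phantom
#'
#' Renders the phantom described by a [phantom_spec()] into a shift map and
#' its ground-truth label mask. Per-pixel contrast is drawn as
#' region mean + Gaussian noise and converted to a Brillouin frequency
#' shift for storage. Rendering is deterministic for a fixed spec/seed.
#'
#' @param spec A [phantom_spec()].
#' @param config An [optical_config()] used for the contrast-to-shift
#'   conversion.
#' @return List with elements `map` ([shift_map()]) and `mask`
#'   ([label_mask()]).
#' @export
render_digit_phantom <- function(spec, config = optical_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- .render_labels(spec)
  present <- unique(as.vector(lab$labels))
  missing <- setdiff(present, names(spec$regions))
  if (length(missing))
    stop("no region_spec for rendered labels: ", toString(missing),
         call. = FALSE)
  mu <- vapply(spec$regions, `[[`, 0, "mean_contrast")[lab$labels]
  sd <- vapply(spec$regions, `[[`, 0, "sd_contrast")[lab$labels]
  contrast <- withr_local_seed(.sub_seed(spec$seed, 2L),
                               mu + stats::rnorm(length(mu), 0, sd))
  contrast <- matrix(pmax(contrast, -0.999), lab$nr, lab$nc)
  shift <- matrix(contrast_to_shift(contrast, config), lab$nr, lab$nc)
  half <- spec$pixel_um / 2
  list(map = shift_map(shift, spec$pixel_um, origin_um = c(half, half)),
       mask = label_mask(lab$labels, spec$pixel_um,
                         origin_um = c(half, half),
                         cell_ids = lab$cell_ids))
}

#' Expected whole-map mean contrast of a phantom
#'
#' Area-weighted average of the region mean contrasts, using the exact
#' pixel counts of the rendered label geometry (noise-free expectation).
#'
#' @param spec A [phantom_spec()].
#' @return Expected mean elastic contrast of the rendered map.
#' @export
expected_map_mean <- function(spec) {
  lab <- .render_labels(spec)
  mu <- vapply(spec$regions, `[[`, 0, "mean_contrast")
  counts <- table(factor(as.vector(lab$labels), levels = names(mu)))
  sum(mu * as.numeric(counts)) / sum(counts)
}

.set_region_mean <- function(spec, label, mean_contrast) {
  r <- spec$regions[[label]]
  spec$regions[[label]] <- region_spec(label, mean_contrast,
                                       r$sd_contrast)
  spec
}

#' Collagenase digestion series
#'
#' Derives one phantom spec per digestion time from a mature-digit base
#' spec, emulating progressive enzymatic degradation of the collagen-rich
#' ECM: the ECM mean contrast decreases strictly with incubation time; at
#' the final time point the chondrocytes round up and stiffen (equal oval
#' axes, increased mean) while cell density drops.
#'
#' @param base A mature-digit [phantom_spec()] (ECM mean > chondrocyte
#'   mean).
#' @param times_min Sorted subset of `c(0, 30, 45)` minutes.
#' @param ecm_means,chond_means,cell_counts Optional per-time overrides;
#'   non-monotone overrides are accepted with a warning.
#' @return Named list of `phantom_spec`s, one per time point.
#' @export
collagenase_series <- function(base = mature_digit_spec(),
                               times_min = c(0, 30, 45),
                               ecm_means = NULL, chond_means = NULL,
                               cell_counts = NULL) {
  stopifnot(inherits(base, "phantom_spec"),
            all(times_min %in% c(0, 30, 45)), !is.unsorted(times_min),
            !anyDuplicated(times_min))
  defaults <- list(
    ecm = c(`0` = base$regions$ecm$mean_contrast, `30` = 0.050,
            `45` = 0.040),
    chond = c(`0` = base$regions$chondrocyte$mean_contrast, `30` = 0.045,
              `45` = 0.050),
    cells = c(`0` = base$cell_count, `30` = base$cell_count, `45` = 10))
  key <- as.character(times_min)
  ecm <- unname(if (is.null(ecm_means)) defaults$ecm[key] else ecm_means)
  chd <- unname(if (is.null(chond_means)) defaults$chond[key]
                else chond_means)
  ncell <- unname(if (is.null(cell_counts)) defaults$cells[key]
                  else cell_counts)
  if (length(times_min) > 1L) {
    if (any(diff(ecm) >= 0))
      warning("ECM means are not strictly decreasing over time",
              call. = FALSE)
    if (chd[length(chd)] < chd[1] && 45 %in% times_min)
      warning("chondrocyte mean at 45 min is not above its 0 min value",
              call. = FALSE)
  }
  out <- lapply(seq_along(times_min), function(i) {
    s <- base
    s <- .set_region_mean(s, "ecm", ecm[i])
    s <- .set_region_mean(s, "chondrocyte", chd[i])
    s$cell_count <- ncell[i]
    if (times_min[i] == 45) {
      # cells round up: equalize oval axes at preserved area
      s$cell_radii_um <- rep(sqrt(prod(base$cell_radii_um)), 2L)
    }
    s$seed <- .sub_seed(base$seed, 100L + i)
    s
  })
  names(out) <- paste0(times_min, "min")
  out
}

#' Digit development series
#'
#' Phantom specs for developmental stages 45-53 at 5 um pixels. The limb
#' bud at stage 45 is semi-homogeneous (no distinct cartilage region, a
#' thin epidermis only); from stage 47 a condensing cartilage core appears
#' whose mean contrast increases strictly with stage. In developing digits
#' the chondrocytes are stiffer than their immature surrounding ECM
#' (the reverse of the mature digit). Epidermis thickness is
#' non-decreasing across stages, and stage 53 carries a joint strip with
#' locally elevated contrast.
#'
#' @param stages Sorted subset of `c(45, 47, 49, 51, 53)`.
#' @param seed Integer seed for the series.
#' @return Named list of `phantom_spec`s.
#' @export
development_series <- function(stages = c(45, 47, 49, 51, 53), seed = 1L) {
  allowed <- c(45, 47, 49, 51, 53)
  if (!all(stages %in% allowed))
    stop("unknown developmental stage(s): ",
         toString(setdiff(stages, allowed)), call. = FALSE)
  stopifnot(!is.unsorted(stages), !anyDuplicated(stages))
  # per-stage targets: cartilage core mean (strictly increasing),
  # epidermis thickness (non-decreasing, in 5 um pixels)
  cart_mean <- c(`45` = 0.012, `47` = 0.024, `49` = 0.032, `51` = 0.040,
                 `53` = 0.048)
  epi_um <- c(`45` = 5, `47` = 5, `49` = 10, `51` = 10, `53` = 15)
  out <- lapply(seq_along(stages), function(i) {
    st <- as.character(stages[i])
    cm <- cart_mean[[st]]
    if (stages[i] == 45) {
      # homogeneous limb bud: interstitial tissue fills the core
      regions <- list(
        medium = region_spec("medium", 0.006, 0.002),
        epidermis = region_spec("epidermis", 0.020, 0.004),
        interstitial = region_spec("interstitial", cm, 0.004))
      phantom_spec(width_um = 150, height_um = 100, pixel_um = 5,
                   regions = regions, cell_count = 0,
                   epidermis_um = epi_um[[st]], interstitial_um = 0,
                   medium_margin_um = 10, core_label = "interstitial",
                   seed = .sub_seed(seed, 200L + i))
    } else {
      # condensing cartilage: chondrocytes stiffer than immature ECM
      regions <- list(
        medium = region_spec("medium", 0.006, 0.002),
        epidermis = region_spec("epidermis", cm * 0.8, 0.004),
        interstitial = region_spec("interstitial", 0.015, 0.004),
        ecm = region_spec("ecm", cm - 0.004, 0.004),
        chondrocyte = region_spec("chondrocyte", cm + 0.006, 0.004))
      joint <- if (stages[i] == 53)
        list(x_um = 20, width_um = 25,
             mean_contrast = cm + 0.008) else NULL
      sp <- phantom_spec(width_um = 150, height_um = 100, pixel_um = 5,
                         regions = regions, cell_count = 5,
                         cell_radii_um = c(10, 8),
                         epidermis_um = epi_um[[st]], interstitial_um = 10,
                         medium_margin_um = 10, joint = joint,
                         seed = .sub_seed(seed, 200L + i))
      if (!is.null(joint))
        sp$regions$joint <- region_spec("joint", joint$mean_contrast,
                                        0.004)
      sp
    }
  })
  names(out) <- paste0("st", stages)
  out
}

#' Digit regeneration series
#'
#' Phantom specs for 0, 15 and 30 days post-amputation (dpa) on the
#' 200 x 80 um, 2.5 um-pixel regeneration geometry, plus a per-animal digit
#' length model. At 0 dpa the digit is mature (ECM > chondrocytes); at
#' 15 dpa condensation has just begun: contrast is strongly reduced and ECM
#' and chondrocytes are indistinguishable (equal means); at 30 dpa the
#' mechanical properties are partially re-established
#' (0 dpa > 30 dpa > 15 dpa in cartilage mean). The length model returns
#' per-digit lengths normalized to day 0, with the amputated digit ratio
#' increasing over dpa but still below the contralateral ratio at 30 dpa.
#'
#' @param dpas Sorted subset of `c(0, 15, 30)`.
#' @param seed Integer seed.
#' @return List with `specs` (named list of `phantom_spec`s) and
#'   `length_model`, a function `(n_animals, seed)` returning a
#'   `data.frame` of per-animal digit lengths and day-0-normalized ratios.
#' @export
regeneration_series <- function(dpas = c(0, 15, 30), seed = 1L) {
  stopifnot(all(dpas %in% c(0, 15, 30)), !is.unsorted(dpas),
            !anyDuplicated(dpas))
  ecm <- c(`0` = 0.060, `15` = 0.030, `30` = 0.050)
  chd <- c(`0` = 0.045, `15` = 0.030, `30` = 0.042)
  specs <- lapply(seq_along(dpas), function(i) {
    key <- as.character(dpas[i])
    s <- phantom_spec(width_um = 200, height_um = 80, pixel_um = 2.5,
                      cell_count = 16, cell_radii_um = c(8, 5),
                      seed = .sub_seed(seed, 300L + i))
    s <- .set_region_mean(s, "ecm", ecm[[key]])
    s <- .set_region_mean(s, "chondrocyte", chd[[key]])
    s
  })
  names(specs) <- paste0(dpas, "dpa")
  # growth of the uninjured digit and regrowth of the amputated one,
  # as day-0-normalized ratios
  contral_ratio <- c(`0` = 1, `15` = 1.06, `30` = 1.12)
  amput_ratio <- c(`0` = 1, `15` = 0.40, `30` = 0.72)
  length_model <- function(n_animals = 4L, seed = 1L) {
    withr_local_seed(.sub_seed(seed, 400L), {
      rows <- list()
      for (a in seq_len(n_animals)) {
        L0 <- stats::rnorm(2, 500, 25)  # amputated, contralateral (um)
        for (d in dpas) {
          key <- as.character(d)
          noise <- if (d == 0) c(0, 0) else stats::rnorm(2, 0, 0.02)
          ra <- amput_ratio[[key]] + noise[1]
          rc <- contral_ratio[[key]] + noise[2]
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = sprintf("A%d", a),
            dpa = d,
            digit = c("amputated", "contralateral"),
            length_um = c(L0[1] * ra, L0[2] * rc),
            ratio = c(ra, rc), stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }
  list(specs = specs, length_model = length_model)
}

#' Cohort specification
#'
#' Repeated-measures cohort model: animal `a` under condition `c` yields
#' `value = condition_effect[c] + animal_effect[a] + residual`, with
#' animal effects ~ Normal(0, `animal_sd`) and residuals ~ Normal(0,
#' `residual_sd`). Defaults reproduce the collagenase design: 5 animals,
#' 3 conditions with strictly decreasing effects, and noise small enough
#' that within-animal orderings are preserved with probability > 0.999.
#'
#' @param n_animals Number of animals, >= 2.
#' @param conditions Ordered character vector of >= 2 condition labels.
#' @param condition_effects Numeric mean contrast per condition.
#' @param animal_sd,residual_sd Random-effect standard deviations, >= 0.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_animals = 5L,
                        conditions = c("0min", "30min", "45min"),
                        condition_effects = c(0.0535, 0.0480, 0.0400),
                        animal_sd = 0.002, residual_sd = 0.001,
                        seed = 1L) {
  stopifnot(n_animals >= 2, length(conditions) >= 2,
            length(condition_effects) == length(conditions),
            animal_sd >= 0, residual_sd >= 0)
  structure(list(n_animals = as.integer(n_animals),
                 conditions = as.character(conditions),
                 condition_effects = condition_effects,
                 animal_sd = animal_sd, residual_sd = residual_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a cohort table from a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort_table()] in long format, one row per
#'   (animal, condition).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_local_seed(.sub_seed(spec$seed, 500L), {
    k <- length(spec$conditions)
    animal_eff <- stats::rnorm(spec$n_animals, 0, spec$animal_sd)
    rows <- expand.grid(condition = spec$conditions,
                        animal = seq_len(spec$n_animals),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    value <- spec$condition_effects[match(rows$condition,
                                          spec$conditions)] +
      animal_eff[rows$animal] +
      stats::rnorm(nrow(rows), 0, spec$residual_sd)
    cohort_table(sprintf("A%d", rows$animal), rows$condition, value,
                 condition_levels = spec$conditions)
  })
}
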