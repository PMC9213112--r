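#' Default configuration for a phantom experiment
#'
#' Returns the parameter tree driving [run_experiment()]: cohort sizes fixed
#' to the original designs (5 animals for collagenase, 5/5/5/4/4 across
#' developmental stages 45-53, 4 for regeneration), quantification ROIs
#' (100 x 100 um for development, 25 x 25 um in the phalanx centre for
#' regeneration), per-animal random-effect spread, and rendering options.
#' Any element may be overridden via the `config` argument of
#' [run_experiment()] or a JSON config file.
#'
#' @param experiment One of `"collagenase"`, `"development"`,
#'   `"regeneration"`.
#' @return Named list of parameters.
#' @export
default_config <- function(experiment = c("collagenase", "development",
                                          "regeneration")) {
  experiment <- match.arg(experiment)
  common <- list(experiment = experiment, animal_sd = 0.002,
                 noise_scale = 1, render_png = TRUE,
                 color_limits = c(0, 0.08))
  switch(experiment,
    collagenase = c(common, list(
      n_animals = 5L, times_min = c(0, 30, 45))),
    development = c(common, list(
      stages = c(45, 47, 49, 51, 53),
      n_animals_per_stage = c(5L, 5L, 5L, 4L, 4L),
      roi = list(x_um = 25, y_um = 0, width_um = 100, height_um = 100),
      profile_anchor_um = 65)),
    regeneration = c(common, list(
      n_animals = 4L, dpas = c(0, 15, 30),
      roi = list(x_um = 87.5, y_um = 27.5, width_um = 25,
                 height_um = 25))))
}

#' Read an experiment configuration from a JSON file
#'
#' The file holds overrides merged onto [default_config()]; it must name
#' the experiment in an `experiment` key.
#'
#' @param path JSON file path.
#' @return Configuration list.
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$experiment))
    stop("config file must set `experiment`", call. = FALSE)
  utils::modifyList(default_config(cfg$experiment), cfg)
}

# shift every tissue region mean by a per-animal random effect and scale
# per-pixel noise (noise_scale = 0 gives deterministic expectation maps)
.offset_spec <- function(spec, offset, noise_scale = 1) {
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    mu <- if (nm == "medium") r$mean_contrast  # the bath does not vary
          else r$mean_contrast + offset
    spec$regions[[nm]] <- region_spec(nm, mu,
                                      r$sd_contrast * noise_scale)
  }
  spec
}

.log_line <- function(bundle, ...) {
  bundle$log <- c(bundle$log, sprintf(...))
  bundle
}

#' Run a phantom experiment end to end
#'
#' Generates phantom maps for every animal and condition, quantifies them,
#' runs the matching statistical analysis, and (optionally) writes the
#' report bundle to disk via [write_report()]. Everything is a pure
#' function of `(config, seed)`: rerunning with the same arguments
#' reproduces the report byte for byte.
#'
#' * `collagenase`: 5 animals x 0/30/45 min digestion; whole-map contrast
#'   mean per animal; Friedman + Dunn + Kendall's W.
#' * `development`: stages 45-53, >= 4 animals each; 100 x 100 um ROI
#'   means; averaged size-normalized transversal profiles (one per animal,
#'   plus a median-selected representative per stage); Kruskal-Wallis +
#'   Dunn + eta-squared.
#' * `regeneration`: 4 animals x 0/15/30 dpa; 25 x 25 um cartilage ROI
#'   means; Friedman + Dunn + W; digit-length ratios with Mann-Whitney
#'   (amputated vs contralateral) at 15 and 30 dpa.
#'
#' @param experiment Experiment name, see [default_config()].
#' @param seed Integer seed for all randomness.
#' @param outdir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @param config Optional list of overrides onto [default_config()].
#' @return The report bundle (invisibly if written): a list with `cohort`,
#'   `tests`, `maps`, `masks`, and experiment-specific extras.
#' @export
run_experiment <- function(experiment, seed = 1L, outdir = NULL,
                           config = list()) {
  cfg <- utils::modifyList(default_config(experiment), config)
  bundle <- switch(cfg$experiment,
                   collagenase = run_collagenase(cfg, seed),
                   development = run_development(cfg, seed),
                   regeneration = run_regeneration(cfg, seed))
  if (!is.null(outdir)) {
    write_report(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' @rdname run_experiment
#' @param cfg Full configuration list (see [default_config()]).
#' @export
run_collagenase <- function(cfg = default_config("collagenase"),
                            seed = 1L) {
  bundle <- list(experiment = "collagenase", seed = seed, config = cfg,
                 maps = list(), masks = list(), log = character())
  bundle <- .log_line(bundle, "stage=start experiment=collagenase seed=%d",
                      seed)
  offsets <- withr_local_seed(.sub_seed(seed, 1L),
                              stats::rnorm(cfg$n_animals, 0,
                                           cfg$animal_sd))
  rows <- list()
  for (a in seq_len(cfg$n_animals)) {
    base <- mature_digit_spec(seed = .sub_seed(seed, 10L + a))
    series <- collagenase_series(base, times_min = cfg$times_min)
    for (i in seq_along(series)) {
      spec <- .offset_spec(series[[i]], offsets[a], cfg$noise_scale)
      ph <- render_digit_phantom(spec)
      cm <- to_contrast_map(ph$map)
      key <- sprintf("A%d_%s", a, names(series)[i])
      bundle$maps[[key]] <- ph$map
      bundle$masks[[key]] <- ph$mask
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%d", a), condition = names(series)[i],
        value = mean(cm$values), stringsAsFactors = FALSE)
      bundle <- .log_line(bundle,
        "stage=generate animal=A%d condition=%s grid=%dx%d pixel_um=%g",
        a, names(series)[i], nrow(ph$map$values), ncol(ph$map$values),
        spec$pixel_um)
    }
  }
  df <- do.call(rbind, rows)
  bundle$cohort <- cohort_table(df$animal_id, df$condition, df$value,
                                condition_levels = names(series))
  wide <- cohort_to_matrix(bundle$cohort)
  bundle$tests <- list(friedman = friedman_rank_test(wide))
  bundle <- .log_line(bundle,
    "stage=test test=friedman chi2=%.6f p=%.6g W=%.4f",
    bundle$tests$friedman$statistic, bundle$tests$friedman$p_value,
    bundle$tests$friedman$effect_size$value)
  bundle
}

#' @rdname run_experiment
#' @export
run_development <- function(cfg = default_config("development"),
                            seed = 1L) {
  bundle <- list(experiment = "development", seed = seed, config = cfg,
                 maps = list(), masks = list(), profiles = list(),
                 log = character())
  bundle <- .log_line(bundle, "stage=start experiment=development seed=%d",
                      seed)
  roi <- do.call(rect_roi, cfg$roi)
  groups <- list()
  representative <- list()
  for (s in seq_along(cfg$stages)) {
    stage <- cfg$stages[s]
    n_a <- cfg$n_animals_per_stage[s]
    offsets <- withr_local_seed(.sub_seed(seed, 20L + s),
                                stats::rnorm(n_a, 0, cfg$animal_sd))
    vals <- numeric(n_a)
    prof_means <- numeric(n_a)
    for (a in seq_len(n_a)) {
      spec <- development_series(stage,
                                 seed = .sub_seed(seed, 1000L * s + a))[[1]]
      spec <- .offset_spec(spec, offsets[a], cfg$noise_scale)
      ph <- render_digit_phantom(spec)
      cm <- to_contrast_map(ph$map)
      key <- sprintf("st%d_A%d", stage, a)
      bundle$maps[[key]] <- ph$map
      bundle$masks[[key]] <- ph$mask
      vals[a] <- roi_mean(cm, roi)
      prof <- transversal_profiles(cm, anchor_um = cfg$profile_anchor_um)
      nprof <- normalize_profile(prof)
      bundle$profiles[[key]] <- nprof
      prof_means[a] <- mean(prof$values)
      bundle <- .log_line(bundle,
        "stage=generate stage_id=%d animal=A%d roi_mean=%.6f spacing_um=%g",
        stage, a, vals[a], attr(prof, "realized_spacing_um"))
    }
    groups[[sprintf("st%d", stage)]] <- vals
    # representative animal: median whole-profile mean
    rep_a <- order(prof_means)[ceiling(n_a / 2)]
    representative[[sprintf("st%d", stage)]] <- sprintf("st%d_A%d",
                                                        stage, rep_a)
    bundle <- .log_line(bundle,
      "stage=profiles stage_id=%d representative=A%d", stage, rep_a)
  }
  df <- data.frame(
    animal_id = unlist(lapply(names(groups), function(g)
      sprintf("%s_A%d", g, seq_along(groups[[g]])))),
    condition = rep(names(groups), lengths(groups)),
    value = unlist(groups, use.names = FALSE), stringsAsFactors = FALSE)
  bundle$cohort <- cohort_table(df$animal_id, df$condition, df$value,
                                condition_levels = names(groups))
  bundle$representative <- representative
  bundle$tests <- list(kruskal_wallis = kruskal_wallis_test(groups))
  bundle <- .log_line(bundle,
    "stage=test test=kruskal_wallis H=%.6f p=%.6g eta2=%.4f",
    bundle$tests$kruskal_wallis$statistic,
    bundle$tests$kruskal_wallis$p_value,
    bundle$tests$kruskal_wallis$effect_size$value)
  bundle
}

#' @rdname run_experiment
#' @export
run_regeneration <- function(cfg = default_config("regeneration"),
                             seed = 1L) {
  bundle <- list(experiment = "regeneration", seed = seed, config = cfg,
                 maps = list(), masks = list(), log = character())
  bundle <- .log_line(bundle,
                      "stage=start experiment=regeneration seed=%d", seed)
  roi <- do.call(rect_roi, cfg$roi)
  offsets <- withr_local_seed(.sub_seed(seed, 30L),
                              stats::rnorm(cfg$n_animals, 0,
                                           cfg$animal_sd))
  rows <- list()
  for (a in seq_len(cfg$n_animals)) {
    series <- regeneration_series(cfg$dpas,
                                  seed = .sub_seed(seed, 40L + a))
    for (i in seq_along(series$specs)) {
      spec <- .offset_spec(series$specs[[i]], offsets[a], cfg$noise_scale)
      ph <- render_digit_phantom(spec)
      cm <- to_contrast_map(ph$map)
      key <- sprintf("A%d_%s", a, names(series$specs)[i])
      bundle$maps[[key]] <- ph$map
      bundle$masks[[key]] <- ph$mask
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%d", a),
        condition = names(series$specs)[i],
        value = roi_mean(cm, roi), stringsAsFactors = FALSE)
      bundle <- .log_line(bundle,
        "stage=generate animal=A%d condition=%s roi_mean=%.6f",
        a, names(series$specs)[i],
        rows[[length(rows)]]$value)
    }
  }
  df <- do.call(rbind, rows)
  bundle$cohort <- cohort_table(df$animal_id, df$condition, df$value,
                                condition_levels = names(series$specs))
  wide <- cohort_to_matrix(bundle$cohort)
  bundle$tests <- list(friedman = friedman_rank_test(wide))
  # digit-length ratios: amputated vs contralateral at each post-op dpa
  lengths <- regeneration_series(cfg$dpas, seed = seed)$length_model(
    cfg$n_animals, seed = seed)
  bundle$lengths <- lengths
  for (d in setdiff(cfg$dpas, 0)) {
    amp <- lengths$ratio[lengths$dpa == d & lengths$digit == "amputated"]
    con <- lengths$ratio[lengths$dpa == d &
                           lengths$digit == "contralateral"]
    bundle$tests[[sprintf("mann_whitney_%ddpa", d)]] <-
      mann_whitney_exact(amp, con)
  }
  bundle <- .log_line(bundle,
    "stage=test test=friedman chi2=%.6f p=%.6g W=%.4f",
    bundle$tests$friedman$statistic, bundle$tests$friedman$p_value,
    bundle$tests$friedman$effect_size$value)
  bundle
}

#' Reshape a cohort table to a repeated-measures matrix
#'
#' Subjects in rows, conditions in the table's declared order in columns;
#' errors if the design is incomplete.
#'
#' @param cohort A [cohort_table()].
#' @return Numeric matrix, subjects x conditions.
#' @export
cohort_to_matrix <- function(cohort) {
  lv <- attr(cohort, "condition_levels")
  animals <- unique(cohort$animal_id)
  m <- matrix(NA_real_, length(animals), length(lv),
              dimnames = list(animals, lv))
  m[cbind(match(cohort$animal_id, animals),
          match(cohort$condition, lv))] <- cohort$value
  if (any(is.na(m)))
    stop("cohort is not a complete repeated-measures design", call. = FALSE)
  m
}

#' Write a report bundle to disk
#'
#' Deterministic layout under `outdir`: `maps/` (shift-map CSVs, paired
#' label-mask CSVs and heat-map PNGs), `cohorts/` (cohort CSV),
#' `profiles/` (normalized profile CSVs, when present), `stats/` (one JSON
#' per test) and `log.txt` (structured lines with seed and realized
#' parameters; no timestamps, so identical bundles give identical trees).
#'
#' @param bundle A bundle from [run_experiment()].
#' @param outdir Output directory, created if missing.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  for (d in file.path(outdir, c("", "maps", "cohorts", "stats")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (key in names(bundle$maps)) {
    write_map_csv(bundle$maps[[key]],
                  file.path(outdir, "maps", paste0(key, ".csv")))
    write_mask_csv(bundle$masks[[key]],
                   file.path(outdir, "maps", paste0(key, "_mask.csv")))
    if (isTRUE(bundle$config$render_png))
      render_heatmap(to_contrast_map(bundle$maps[[key]]),
                     bundle$config$color_limits,
                     file.path(outdir, "maps", paste0(key, ".png")))
  }
  write_cohort_csv(bundle$cohort,
                   file.path(outdir, "cohorts",
                             paste0(bundle$experiment, ".csv")))
  if (!is.null(bundle$profiles)) {
    dir.create(file.path(outdir, "profiles"), showWarnings = FALSE)
    for (key in names(bundle$profiles))
      write_profile_csv(bundle$profiles[[key]],
                        file.path(outdir, "profiles",
                                  paste0(key, ".csv")))
  }
  if (!is.null(bundle$lengths)) {
    df <- bundle$lengths
    df$length_um <- .fmt_num(df$length_um)
    df$ratio <- .fmt_num(df$ratio)
    utils::write.csv(df, file.path(outdir, "cohorts", "digit_lengths.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (nm in names(bundle$tests))
    write_test_json(bundle$tests[[nm]],
                    file.path(outdir, "stats", paste0(nm, ".json")))
  writeLines(c(sprintf("experiment=%s seed=%d brillquant_version=%s",
                       bundle$experiment, bundle$seed,
                       as.character(utils::packageVersion("brillquant"))),
               bundle$log),
             file.path(outdir, "log.txt"))
  invisible(outdir)
}
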