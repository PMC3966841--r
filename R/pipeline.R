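# End-to-end orchestration: JSON config, staged execution with derived
# seeds, provenance sidecars, and a stats report.

STAGES <- c("simulate_erg", "fit_decay", "plan_window",
            "simulate_oct", "segment", "enface")

# Required per-stage config fields (no sensible default exists for these).
STAGE_REQUIRED <- list(
  simulate_erg = character(0),
  fit_decay = character(0),
  plan_window = c("inject_age", "assess_delay"),
  simulate_oct = c("n_eyes_young", "n_eyes_old"),
  segment = character(0),
  enface = c("n_eyes")
)

#' Validate a pipeline configuration
#'
#' @param config list (parsed JSON) or path to a JSON config file.
#' @return the validated config (with `config_hash` attribute).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), "no such config file: ", config)
    hash <- unname(tools::md5sum(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    hash <- unname(tools::md5sum(tmp))
  }
  for (f in c("seed", "output_dir", "stages")) {
    check_that(!is.null(config[[f]]), "config missing required field '", f, "'")
  }
  check_that(all(config$stages %in% STAGES),
             "unknown stage(s): ",
             paste(setdiff(config$stages, STAGES), collapse = ", "),
             " (known: ", paste(STAGES, collapse = ", "), ")")
  for (st in config$stages) {
    for (f in STAGE_REQUIRED[[st]]) {
      check_that(!is.null(config[[st]][[f]]),
                 "config missing required field '", st, ".", f, "'")
    }
  }
  attr(config, "config_hash") <- hash
  config
}

write_provenance <- function(path, config_hash, seed) {
  jsonlite::write_json(
    list(config_hash = config_hash, seed = seed,
         package = "retnathist",
         version = as.character(utils::packageVersion("retnathist"))),
    paste0(path, ".prov.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (simulate ERG cohort, fit the
#' decay, plan the treatment window, simulate OCT cohorts, segment and
#' summarise thickness, en-face rosette detection), writing all artifacts
#' plus provenance sidecars (config hash + seed) under `output_dir`.
#' Re-running with the same config and seed reproduces identical outputs.
#'
#' @param config list or path to JSON config; see `inst/extdata/demo_config.json`.
#' @return the stats report (list), invisibly also written as
#'   `stats_report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  hash <- attr(cfg, "config_hash")
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, config_hash = hash)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(obj)) write_table(obj, path)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    write_provenance(path, hash, cfg$seed)
    path
  }
  erg <- NULL; fit <- NULL
  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[si]
    seed_st <- derive_seed(cfg$seed, si)
    sc <- cfg[[st]]
    if (is.null(sc)) sc <- list()
    message("[retnathist] stage ", st, " (seed ", seed_st, ")")
    if (st == "simulate_erg") {
      p <- erg_cohort_params(
        slope_log = sc$slope_log %||% (log10(22) - log10(139)) / 52,
        intercept_log = sc$intercept_log,
        scatter_sd = sc$scatter_sd %||% 0.2,
        noise_floor = sc$noise_floor %||% 5,
        ages = sc$ages %||% seq(31, 83, by = 4),
        n_per_age = sc$n_per_age %||% 7L,
        stimulus = sc$stimulus %||% "UV",
        seed = seed_st)
      erg <- gen_erg_cohort(p)
      emit(erg, "erg_cohort.csv")
    } else if (st == "fit_decay") {
      if (is.null(erg)) {
        check_that(!is.null(sc$input), "fit_decay: no simulated cohort and ",
                   "no 'input' CSV configured")
        erg <- read_table(sc$input, c("animal_id", "age_days", "stimulus",
                                      "amplitude_uV"))
      }
      fit <- fit_decay(erg, floor_policy = sc$floor_policy %||% "drop",
                       noise_floor = sc$noise_floor %||% 5)
      report$decay_fit <- fit[c("slope", "intercept", "residual_sd",
                                "pi95_halfwidth", "n", "stimulus")]
      report$percent_per_day <- percent_per_day(fit)
      emit(report$decay_fit, "decay_fit.json")
    } else if (st == "plan_window") {
      check_that(!is.null(fit), "plan_window requires a preceding fit_decay")
      win <- plan_window(fit, inject_age = sc$inject_age,
                         assess_delay = sc$assess_delay,
                         asym_log = sc$asym_log %||% 0.3,
                         noise_floor = sc$noise_floor %||% 5)
      report$treatment_window <- unclass(win)
      emit(unclass(win), "treatment_window.json")
    } else if (st == "simulate_oct") {
      report$oct <- pipeline_oct_cohorts(sc, seed_st, out_dir, hash, cfg$seed)
    } else if (st == "segment") {
      check_that(!is.null(report$oct), "segment requires simulate_oct")
      report$thickness <- pipeline_segment(report$oct, sc)
      emit(report$thickness, "thickness_stats.json")
    } else if (st == "enface") {
      report$enface <- pipeline_enface(sc, seed_st)
      emit(report$enface$sector_table, "sector_stats.csv")
    }
  }
  report_path <- file.path(out_dir, "stats_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  write_provenance(report_path, hash, cfg$seed)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hemifield rosette densities (per mm^2) from per-hemifield counts measured
# in the standard 1.5 mm field with the 0.09 mm ONH disk removed.
hemifield_densities <- function(sup_count, inf_count) {
  hemi_area <- pi * (0.75^2 - 0.09^2) / 2
  c(superior = sup_count / hemi_area, inferior = inf_count / hemi_area)
}

# Simulate young/old line-scan cohorts and write volumes.
pipeline_oct_cohorts <- function(sc, seed, out_dir, hash, master_seed) {
  mk <- function(n_eyes, mean_onl, sd_between, sd_within, total_mean,
                 total_sd_between, total_sd_within, densities, label, seed0) {
    vols <- vector("list", n_eyes)
    for (e in seq_len(n_eyes)) {
      se <- derive_seed(seed0, e)
      draws <- with_seed(se, stats::rnorm(2))
      total_draw <- max(total_mean + total_sd_between * draws[2],
                        mean_onl + 80)  # keep band geometry valid
      p <- oct_phantom_params(
        scan_mode = "linescan",
        n_bscans = sc$n_repeats %||% 2L, n_repeats = sc$n_repeats %||% 2L,
        n_lrps_per_bscan = sc$n_lrps %||% 240L,
        axial_px = sc$axial_px %||% 256L,
        field_diameter = sc$field_diameter %||% 2.4,
        onl_thickness_mean = mean_onl + sd_between * draws[1],
        onl_thickness_sd = sd_within,
        total_thickness_mean = total_draw,
        total_thickness_sd = total_sd_within,
        rosette_density_by_sector = densities,
        noise_sd = sc$noise_sd %||% 0.02,
        seed = derive_seed(se, 7))
      vols[[e]] <- gen_oct_volume(p)
      if (isTRUE(sc$write_volumes)) {
        path <- file.path(out_dir, sprintf("%s_eye%02d.tif", label, e))
        write_volume(vols[[e]]$volume, path)
        write_provenance(path, hash, master_seed)
      }
    }
    vols
  }
  # pooled profile SD split evenly between- vs within-eye (see vignette)
  young_sd <- (sc$young_sd %||% 7.6) / sqrt(2)
  old_sd <- (sc$old_sd %||% 7.0) / sqrt(2)
  total_sd <- (sc$total_sd %||% 13) / sqrt(2)
  # old-cohort total: pooled 34.4 um SD placed mostly between eyes, with a
  # fixed 10 um within-eye component (see vignette)
  old_total_between <- sqrt(max((sc$total_sd_old %||% 34.4)^2 - 10^2, 0))
  list(
    young = mk(sc$n_eyes_young, sc$young_mean %||% 66.4, young_sd, young_sd,
               sc$total_mean %||% 197.4, total_sd, total_sd,
               hemifield_densities(sc$sup_count_young %||% 44,
                                   sc$inf_count_young %||% 73),
               "young", derive_seed(seed, 1)),
    old = mk(sc$n_eyes_old, sc$old_mean %||% 54.7, old_sd, old_sd,
             (sc$total_mean_old %||% 165.5), old_total_between, 10,
             hemifield_densities(sc$sup_count_old %||% 24,
                                 sc$inf_count_old %||% 44),
             "old", derive_seed(seed, 2))
  )
}

# Flatten and segment both cohorts, apply exclusions, summarise and compare.
pipeline_segment <- function(oct, sc) {
  seg_cohort <- function(vols) lapply(vols, function(v) {
    flat <- flatten(v$volume, subsample = sc$flatten_subsample %||% 2L)
    segment_volume(flat)
  })
  young_seg <- seg_cohort(oct$young)
  old_seg <- seg_cohort(oct$old)
  summarise <- function(segs, what, label) {
    profs <- lapply(segs, function(s)
      exclude_regions(profile_from_segmentation(s, what)))
    profile_mean_sd(profs, per_eye = TRUE, group_label = label)
  }
  young_onl <- summarise(young_seg, "onl_plus", "young ONL+")
  old_onl <- summarise(old_seg, "onl_plus", "old ONL+")
  young_total <- summarise(young_seg, "total", "young total")
  cmp <- compare_groups(young_onl$eye_means, old_onl$eye_means)
  list(
    young_onl_mean = young_onl$mean, young_onl_sd = young_onl$sd,
    young_onl_n = young_onl$n,
    old_onl_mean = old_onl$mean, old_onl_sd = old_onl$sd,
    old_onl_n = old_onl$n,
    young_total_mean = young_total$mean, young_total_sd = young_total$sd,
    young_vs_old_t = cmp$t, young_vs_old_p = cmp$p,
    old_fraction_of_young = old_onl$mean / young_onl$mean
  )
}

# En-face rosette detection on raster phantoms.  Per-eye planted hemifield
# counts are drawn from the cohort count distributions (normal, rounded,
# floored at 0): default superior 44 +- 11, inferior 73 +- 12.
pipeline_enface <- function(sc, seed) {
  n_eyes <- sc$n_eyes
  counts <- matrix(0L, n_eyes, 2,
                   dimnames = list(NULL, c("superior", "inferior")))
  planted <- counts
  for (e in seq_len(n_eyes)) {
    se <- derive_seed(seed, e)
    draw <- with_seed(se, stats::rnorm(2))
    plant <- c(
      superior = max(0L, as.integer(round((sc$sup_mean %||% 44) +
                                            (sc$sup_sd %||% 11) * draw[1]))),
      inferior = max(0L, as.integer(round((sc$inf_mean %||% 73) +
                                            (sc$inf_sd %||% 12) * draw[2]))))
    planted[e, ] <- plant
    p <- oct_phantom_params(
      scan_mode = "raster",
      n_bscans = sc$raster_px %||% 120L,
      n_lrps_per_bscan = sc$raster_px %||% 120L,
      axial_px = sc$axial_px %||% 224L,
      field_diameter = 1.5,
      axial_scale = sc$axial_scale %||% 1.8,
      rosette_count_by_sector = plant,
      rosette_density_by_sector = c(superior = 1, inferior = 1),
      noise_sd = sc$noise_sd %||% 0.02,
      seed = derive_seed(se, 3))
    sim <- gen_oct_volume(p)
    flat <- flatten(sim$volume, subsample = sc$flatten_subsample %||% 3L)
    slab <- default_rosette_slab(flat)
    spots <- detect_spots(integrate_slab(flat, slab[1], slab[2]))
    ss <- sector_stats(spots, scheme = "halves")
    counts[e, ] <- ss$count[match(colnames(counts), ss$sector)]
  }
  ss_mean <- colMeans(counts)
  cmp <- compare_groups(counts[, "superior"], counts[, "inferior"])
  list(sector_table = data.frame(sector = colnames(counts),
                                 mean_count = as.numeric(ss_mean),
                                 sd_count = apply(counts, 2, stats::sd)),
       superior_vs_inferior_t = cmp$t, superior_vs_inferior_p = cmp$p,
       per_eye_counts = counts, planted_counts = planted)
}

#' Default en-face integration slab for a flattened volume
#'
#' Boundaries that envelope the rosette-bearing outer retina: from well
#' vitreal of the ONL (the flattened RPE depth minus the configured total
#' ONL+ span plus margin) down to the RPE.  Returns `c(z_top, z_bottom)` in
#' um.
#'
#' @param flat_volume a flattened `oct_volume` (attribute `rpe_target_um`).
#' @param span_um slab thickness vitreal of the RPE (um).
#' @export
default_rosette_slab <- function(flat_volume, span_um = 110) {
  rpe <- attr(flat_volume, "rpe_target_um")
  check_that(!is.null(rpe), "volume must be flattened first")
  c(rpe - span_um, rpe + 2 * flat_volume$axial_scale)
}
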