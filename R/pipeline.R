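#' Load and validate a pipeline run configuration
#'
#' Reads a YAML file and fills defaults; unknown keys and out-of-range
#' values are rejected. The defaults are the pipeline's canonical
#' settings: scales {0.5, 1, 2, 4, 8, 16, 32} km, background ratio 10,
#' training fraction 0.8, 10 suitability bins, 15 covariates kept,
#' top quartile 0.25, range buffer 100 km, PA filters 100 km^2 and
#' 3000 m.
#'
#' @param path YAML file; an empty/missing body yields all defaults.
#' @return A validated `run_config` (named list).
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    out_dir = "rsfscape-run",
    scales = default_scales(),
    background_ratio = 10L,
    train_fraction = 0.8,
    n_bins = 10L,
    n_keep = 15L,
    quartile = 0.25,
    buffer_km = 100,
    min_pa_area_km2 = 100,
    max_pa_elev_m = 3000,
    seed = 1L,
    # synthetic-run knobs
    n_rows = 100L, n_cols = 100L, resolution = 500,
    n_covariates = 5L, autocorr_range_m = 6000,
    n_individuals = 30L, sex_ratio = 0.5, n_locs = 200L,
    hr_km2 = 100, n_ecoregions = 3L, n_pas = 6L, n_countries = 3L
  )
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- utils::modifyList(defaults, user)
  check <- function(ok, field, range) {
    if (!ok) stop("config field '", field, "' out of range (", range, ")", call. = FALSE)
  }
  check(length(cfg$scales) >= 1 && all(cfg$scales > 0) &&
          !is.unsorted(cfg$scales, strictly = TRUE), "scales",
        "strictly increasing positive")
  check(cfg$background_ratio >= 1, "background_ratio", ">= 1")
  check(cfg$train_fraction > 0 && cfg$train_fraction < 1, "train_fraction", "(0,1)")
  check(cfg$n_bins >= 2, "n_bins", ">= 2")
  check(cfg$n_keep >= 1, "n_keep", ">= 1")
  check(cfg$quartile > 0 && cfg$quartile < 1, "quartile", "(0,1)")
  check(cfg$buffer_km >= 0, "buffer_km", ">= 0")
  check(cfg$min_pa_area_km2 >= 0, "min_pa_area_km2", ">= 0")
  check(cfg$max_pa_elev_m > 0, "max_pa_elev_m", "> 0")
  structure(cfg, class = "run_config")
}

pipeline_stages <- function() {
  c("simulate", "prep", "scale", "fit", "predict", "validate", "assess")
}

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates the full workflow on generated data in the canonical
#' order: simulate landscape/zones/telemetry, build the used/available
#' design, smooth covariates across scales and extract them, optimize
#' scales and select covariates, fit the final model, predict the
#' suitability surface, validate on held-out presences, and run the
#' conservation overlay. Every stage's artifacts are written under
#' `config$out_dir` and listed, with content hashes, in `manifest.json`.
#' Stage seeds derive from the master seed by stable hashing, so a rerun
#' with the same config and seed reproduces identical artifacts.
#'
#' @param config A [load_config()] result (or `NULL` for defaults).
#' @param stages Subset of stages to run (default: all, in order).
#' @return Invisibly, a list with the in-memory results of each stage run.
#' @export
run_pipeline <- function(config = NULL, stages = pipeline_stages()) {
  cfg <- config %||% load_config()
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(config = cfg)
  manifest <- list(config = unclass(cfg), stages = list())
  t_all <- Sys.time()
  log_stage <- function(name, t0, info) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    manifest$stages[[name]] <<- info
  }
  need <- function(what, stage_hint) {
    if (is.null(state[[what]])) {
      stop("missing upstream artifact '", what, "': run stage '", stage_hint,
           "' first", call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    grid <- grid_spec(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                      resolution = cfg$resolution)
    stack <- generate_covariate_stack(grid, cfg$n_covariates,
                                      autocorr_range = cfg$autocorr_range_m,
                                      seed = child_seed(cfg$seed, "landscape"))
    zones <- generate_zone_set(grid, cfg$n_ecoregions, cfg$n_pas,
                               seed = child_seed(cfg$seed, "zones"),
                               n_countries = cfg$n_countries)
    hr <- data.frame(region = "synthetic", sex = c("F", "M"),
                     hr_km2 = cfg$hr_km2)
    pop <- simulate_population(cfg$n_individuals, cfg$sex_ratio, hr, grid,
                               seed = child_seed(cfg$seed, "population"))
    n_active <- min(cfg$n_covariates, 3L)
    truth <- withr::with_seed(child_seed(cfg$seed, "truth"), {
      truth_bundle(
        beta = stats::setNames(c(1.5, -1, 0.75)[seq_len(n_active)],
                               names(stack$layers)[seq_len(n_active)]),
        scale_km = stats::setNames(sample(cfg$scales[cfg$scales <= 8],
                                          n_active, replace = TRUE),
                                   names(stack$layers)[seq_len(n_active)]),
        seed = cfg$seed)
    })
    telem <- simulate_telemetry(stack, pop, truth, cfg$n_locs,
                                seed = child_seed(cfg$seed, "telemetry"))
    state$grid <- grid; state$stack <- stack; state$zones <- zones
    state$population <- pop; state$truth <- truth; state$telemetry <- telem
    for (nm in names(stack$layers)) {
      write_ascii_grid(stack$layers[[nm]], grid,
                       file.path(cfg$out_dir, paste0("covariate_", nm, ".asc")))
    }
    write_zones_json(zones, file.path(cfg$out_dir, "zones.json"))
    write_telemetry_csv(telem, file.path(cfg$out_dir, "telemetry.csv"))
    jsonlite::write_json(list(beta = as.list(truth$beta),
                              scale_km = as.list(truth$scale_km),
                              seed = cfg$seed),
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("simulate", t0, list(n_fixes = nrow(telem),
                                   n_individuals = nrow(pop)))
  }

  if ("prep" %in% stages) {
    t0 <- Sys.time()
    need("telemetry", "simulate"); need("population", "simulate")
    ua <- build_use_available(state$telemetry, state$population, state$grid,
                              ratio = cfg$background_ratio,
                              seed = child_seed(cfg$seed, "background"))
    ua <- split_train_validate(ua, cfg$train_fraction,
                               seed = child_seed(cfg$seed, "split"))
    state$design_points <- ua
    write_design_csv(ua, file.path(cfg$out_dir, "use_available.csv"))
    log_stage("prep", t0, list(n_used = sum(ua$case == 1),
                               n_available = sum(ua$case == 0)))
  }

  if ("scale" %in% stages) {
    t0 <- Sys.time()
    need("stack", "simulate"); need("design_points", "prep")
    smoothed <- build_smoothed_stack(state$stack, cfg$scales)
    design <- extract_covariates(state$design_points, smoothed)
    state$smoothed <- smoothed; state$design <- design
    write_design_csv(design, file.path(cfg$out_dir, "design.csv"))
    log_stage("scale", t0, list(n_layers = length(smoothed$layers),
                                n_rows = nrow(design)))
  }

  if ("fit" %in% stages) {
    t0 <- Sys.time()
    need("design", "scale")
    covs <- unique(state$smoothed$index$covariate)
    train <- state$design[state$design$split == "train", ]
    sel_scales <- optimize_scales(train, covs, cfg$scales)
    opt_cols <- smoothed_key(names(sel_scales$chosen), unname(sel_scales$chosen))
    sp <- spearman_matrix(train, opt_cols)
    mr <- mrmr_select(sp, n_keep = min(cfg$n_keep, length(opt_cols)))
    fit <- fit_final_model(state$design, mr, sel_scales)
    state$scale_selection <- sel_scales; state$mrmr <- mr; state$model <- fit
    utils::write.csv(sel_scales$aicc_table,
                     file.path(cfg$out_dir, "scale_selection.csv"), row.names = FALSE)
    utils::write.csv(mr$trace, file.path(cfg$out_dir, "mrmr_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(coefficient_table(fit),
                     file.path(cfg$out_dir, "coefficients.csv"), row.names = FALSE)
    log_stage("fit", t0, list(aicc = fit$aicc, converged = fit$converged))
  }

  if ("predict" %in% stages) {
    t0 <- Sys.time()
    need("model", "fit"); need("smoothed", "scale")
    surface <- predict_surface(state$model, state$smoothed, n_bins = cfg$n_bins)
    state$surface <- surface
    write_ascii_grid(surface$w, state$grid, file.path(cfg$out_dir, "suitability.asc"))
    write_ascii_grid(surface$bins + 0, state$grid, file.path(cfg$out_dir, "bins.asc"))
    log_stage("predict", t0, list(n_valid = sum(!is.na(surface$w))))
  }

  if ("validate" %in% stages) {
    t0 <- Sys.time()
    need("surface", "predict"); need("design_points", "prep")
    held <- state$design_points[state$design_points$case == 1 &
                                  state$design_points$split == "validate", ]
    bi <- boyce_index(state$surface, held)
    state$boyce <- bi
    utils::write.csv(bi$table, file.path(cfg$out_dir, "boyce_bins.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(boyce = bi$boyce, n_eval = nrow(held)),
                         file.path(cfg$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("validate", t0, list(boyce = bi$boyce, n_eval = nrow(held)))
  }

  if ("assess" %in% stages) {
    t0 <- Sys.time()
    need("surface", "predict"); need("zones", "simulate")
    rng <- Filter(function(z) z$zone_type == "current_range", state$zones$zones)[[1]]
    buffered <- buffer_current_range(rng, state$grid, cfg$buffer_km)
    pas <- filter_protected_areas(state$zones, buffered,
                                  cfg$min_pa_area_km2, cfg$max_pa_elev_m)
    masks <- list(
      classify_high(state$surface, "range_based", quartile = cfg$quartile),
      classify_high(state$surface, "ecoregion_based", ecoregions = state$zones,
                    quartile = cfg$quartile)
    )
    zr <- zone_report(masks, state$surface, state$zones)
    cr <- country_report(masks, state$surface,
                         zones_of_type(state$zones, "country"), pas)
    state$zone_report <- zr; state$country_report <- cr; state$filtered_pas <- pas
    utils::write.csv(zr, file.path(cfg$out_dir, "zone_report.csv"), row.names = FALSE)
    utils::write.csv(cr, file.path(cfg$out_dir, "country_report.csv"),
                     row.names = FALSE)
    log_stage("assess", t0, list(n_pa_blocks = length(pas$zones)))
  }

  manifest$elapsed_s <- as.numeric(Sys.time() - t_all, units = "secs")
  arts <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest$artifacts <- lapply(arts, function(f) {
    p <- file.path(cfg$out_dir, f)
    list(file = f, bytes = file.info(p)$size,
         hash = fnv1a32(paste(readLines(p, warn = FALSE), collapse = "\n")))
  })
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(state)
}
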