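# Stage orchestration: each stage is a thin, file-based wrapper over the
# analysis functions, reading the previous stage's outputs from a study
# directory and writing its own together with a JSON manifest (input
# hashes, configuration snapshot, seed, package version) so any output is
# traceable and reruns are reproducible.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("simulate", "geolocate", "detect", "covariates",
                     "kde", "fit", "select", "report")

.default_config <- function() {
  list(
    dir = "study",
    seed = 1,
    scenario = list(days = 30, target_presences = 800),
    geodetic = list(earth_radius = 6371000, refraction_coefficient = 0.13,
                    reticle_spacing = 0.00497),
    detection = list(min_points = 20, ks_threshold = 0.1,
                     inflection_domain = "area",
                     species_caps = list(porpoise = 2, rissos = 2)),
    kde = list(n_per_sector = 100, levels = c(50, 60, 75, 95),
               min_n_scv = 25),
    model = list(W = 1000, n_per_scan = 2, weighted_cvll = TRUE,
                 terms = c("depth", "tidal_state"),
                 candidates = c("depth", "tidal_state", "slope",
                                "sd_current_speed")))
}

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the defaults; unknown keys at any level are
#' rejected by name.
#'
#' @param config Named list (possibly nested) of settings, or a YAML path.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  # the scenario block accepts any make_scenario() argument
  scen_keys <- setdiff(names(formals(make_scenario)), "seed")
  merge <- function(d, u, path = "") {
    allowed <- if (path == "scenario/") union(names(d), scen_keys)
    else names(d)
    bad <- setdiff(names(u), allowed)
    if (length(bad) > 0)
      stop("unknown configuration key: ", paste0(path, bad[1]))
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(u[[nm]]))
        merge(d[[nm]], u[[nm]], paste0(path, nm, "/")) else u[[nm]]
    }
    d
  }
  merge(def, config)
}

.stage_manifest <- function(dir, stage, config, inputs, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("shorewatch")),
    config = config,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.read_scans <- function(dir) {
  scans <- utils::read.csv(file.path(dir, "scans.csv"),
                           stringsAsFactors = FALSE)
  scans$start_time <- as.POSIXct(scans$start_time,
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  scans
}

.require_upstream <- function(dir, files, stage_needed) {
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0)
    stop(sprintf("missing %s; run the '%s' stage first",
                 paste(missing, collapse = ", "), stage_needed))
}

.load_env <- function(dir) {
  environment_bundle(read_ascii_grid(file.path(dir, "depth.asc")),
                     read_current_cycle(dir),
                     read_tide_table(file.path(dir, "tide.csv")))
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write a synthetic study), \code{geolocate}
#' (positions from bearings/reticles), \code{detect} (accumulation curves,
#' inflection limits and the detection filter), \code{covariates} (derived
#' environmental surfaces), \code{kde} (effort-balanced density surfaces and
#' core areas), \code{fit} (availability sampling and the IWLR fit),
#' \code{select} (forward CVLL selection) and \code{report} (effort table,
#' rate ratios, core-area percentages).  Each stage writes its outputs and a
#' manifest into the study directory.
#'
#' @param stage One of the stage names.
#' @param config Configuration list or YAML path (see [pipeline_config()]).
#' @return Invisibly, a list of the stage's main in-memory results.
#' @export
run_stage <- function(stage = PIPELINE_STAGES, config = list()) {
  stage <- match.arg(stage)
  config <- pipeline_config(config)
  dir <- config$dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(geodetic_config, config$geodetic)
  message(sprintf("[%s] stage starting in %s", stage, dir))
  out <- switch(stage,
    simulate = {
      sc <- do.call(make_scenario, c(list(seed = config$seed),
                                     config$scenario))
      sim <- simulate_dataset(sc, cfg = cfg)
      write_dataset(sim, dir)
      jsonlite::write_json(
        list(intercept = sim$truth$intercept,
             effects = sim$truth$effects,
             expected_count = sim$truth$expected_count),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      .stage_manifest(dir, stage, config, character(),
                      file.path(dir, c("scans.csv", "sightings.csv",
                                       "depth.asc", "tide.csv")))
      list(n_scans = nrow(sim$scans), n_sightings = nrow(sim$sightings))
    },
    geolocate = {
      .require_upstream(dir, c("scans.csv", "sightings.csv",
                               "platforms.yaml", "tide.csv"), "simulate")
      scans <- .read_scans(dir)
      sightings <- utils::read.csv(file.path(dir, "sightings.csv"),
                                   stringsAsFactors = FALSE)
      geo <- geolocate_sightings(sightings, scans,
                                 read_platforms(file.path(dir, "platforms.yaml")),
                                 read_tide_table(file.path(dir, "tide.csv")),
                                 cfg)
      utils::write.csv(geo, file.path(dir, "sightings_geo.csv"),
                       row.names = FALSE)
      .stage_manifest(dir, stage, config,
                      file.path(dir, c("scans.csv", "sightings.csv")),
                      file.path(dir, "sightings_geo.csv"))
      list(n = nrow(geo))
    },
    detect = {
      .require_upstream(dir, c("sightings_geo.csv", "scans.csv"), "geolocate")
      scans <- .read_scans(dir)
      geo <- utils::read.csv(file.path(dir, "sightings_geo.csv"),
                             stringsAsFactors = FALSE)
      m <- match(geo$scan_id, scans$scan_id)
      geo$site <- scans$site[m]; geo$sea_state <- scans$sea_state[m]
      lim <- list()
      for (sp in unique(geo$species)) for (st in unique(geo$site)) {
        for (ss in 0:4) {
          d <- geo$distance_m[geo$species == sp & geo$site == st &
                                geo$sea_state == ss]
          r <- if (length(d) >= config$detection$min_points)
            as.numeric(estimate_inflection(
              accumulation_curve(d), config$detection$min_points,
              domain = config$detection$inflection_domain))
          else NA
          lim[[length(lim) + 1]] <- data.frame(site = st, species = sp,
                                               sea_state = ss, radius_m = r)
        }
      }
      lim <- do.call(rbind, lim)
      # sparse strata inherit the nearest lower sea state's radius
      for (i in which(is.na(lim$radius_m))) {
        same <- lim[lim$site == lim$site[i] & lim$species == lim$species[i] &
                      !is.na(lim$radius_m), ]
        lim$radius_m[i] <- if (nrow(same) > 0)
          same$radius_m[which.min(abs(same$sea_state - lim$sea_state[i]))]
        else max(geo$distance_m)
      }
      limits <- suppressWarnings(
        detection_limits(lim$site, lim$species, lim$sea_state, lim$radius_m))
      write_detection_limits(limits, file.path(dir, "detection_limits.csv"))
      caps <- unlist(config$detection$species_caps)
      filt <- apply_detection_filter(geo, scans, limits, caps)
      utils::write.csv(filt, file.path(dir, "sightings_filtered.csv"),
                       row.names = FALSE)
      .stage_manifest(dir, stage, config,
                      file.path(dir, c("sightings_geo.csv", "scans.csv")),
                      file.path(dir, c("detection_limits.csv",
                                       "sightings_filtered.csv")))
      list(limits = limits, n_retained = nrow(filt))
    },
    covariates = {
      .require_upstream(dir, c("depth.asc", "currents.yaml", "tide.csv"),
                        "simulate")
      env <- .load_env(dir)
      for (nm in c("slope", "aspect", "sd_slope", "mean_strat"))
        write_ascii_grid(env[[nm]], file.path(dir, paste0(nm, ".asc")))
      .stage_manifest(dir, stage, config, file.path(dir, "depth.asc"),
                      file.path(dir, paste0(c("slope", "aspect", "sd_slope",
                                              "mean_strat"), ".asc")))
      list(env = env)
    },
    kde = {
      .require_upstream(dir, c("sightings_filtered.csv", "scans.csv",
                               "detection_limits.csv"), "detect")
      scans <- .read_scans(dir)
      filt <- utils::read.csv(file.path(dir, "sightings_filtered.csv"),
                              stringsAsFactors = FALSE)
      limits <- read_detection_limits(file.path(dir, "detection_limits.csv"))
      sc <- do.call(make_scenario, c(list(seed = config$seed),
                                     config$scenario))
      wedges <- scenario_wedges(sc)
      bal <- balance_effort(scans, filt, config$kde$n_per_sector,
                            seed = config$seed)
      results <- list()
      for (sp in unique(bal$sightings$species)) {
        pts <- bal$sightings[bal$sightings$species == sp, ]
        wp <- weight_overlap_sightings(pts, wedges)
        H <- scv_bandwidth(wp, min_n_scv = config$kde$min_n_scv)
        surf <- kde_surface(wp, H)
        vc <- volume_contours(surf, config$kde$levels)
        write_ascii_grid(surf, file.path(dir, paste0("kde_", sp, ".asc")))
        write_contours_geojson(vc, file.path(dir, paste0("contours_", sp,
                                                         ".geojson")),
                               properties = list(species = sp))
        results[[sp]] <- list(H = H, surface = surf, contours = vc)
      }
      .stage_manifest(dir, stage, config,
                      file.path(dir, "sightings_filtered.csv"),
                      file.path(dir, paste0("kde_",
                                            names(results), ".asc")))
      results
    },
    fit = {
      .require_upstream(dir, c("sightings_filtered.csv", "scans.csv",
                               "detection_limits.csv", "depth.asc"), "detect")
      pre <- .prepare_model_records(dir, config)
      terms <- .terms_from_names(config$model$terms)
      model <- fit_iwlr(pre$records, terms, W = config$model$W)
      summ <- list(deviance_explained = model$deviance_explained,
                   W = model$W,
                   coefficients = as.list(stats::coef(model$fit)),
                   rate_ratios = as.list(exp(stats::coef(model$fit))))
      jsonlite::write_json(summ, file.path(dir, "model_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      .stage_manifest(dir, stage, config,
                      file.path(dir, "sightings_filtered.csv"),
                      file.path(dir, "model_summary.json"))
      list(model = model)
    },
    select = {
      .require_upstream(dir, c("sightings_filtered.csv", "scans.csv",
                               "detection_limits.csv", "depth.asc"), "detect")
      pre <- .prepare_model_records(dir, config)
      cand <- .terms_from_names(config$model$candidates)
      sel <- forward_select(pre$records, cand, W = config$model$W,
                            weighted = config$model$weighted_cvll)
      utils::write.csv(sel$table, file.path(dir, "selection_table.csv"),
                       row.names = FALSE)
      .stage_manifest(dir, stage, config,
                      file.path(dir, "sightings_filtered.csv"),
                      file.path(dir, "selection_table.csv"))
      sel
    },
    report = {
      .require_upstream(dir, c("scans.csv", "sightings_filtered.csv"),
                        "detect")
      scans <- .read_scans(dir)
      filt <- utils::read.csv(file.path(dir, "sightings_filtered.csv"),
                              stringsAsFactors = FALSE)
      eff <- effort_summary(scans, filt)
      utils::write.csv(eff, file.path(dir, "effort_summary.csv"),
                       row.names = FALSE)
      lines <- render_effort_table(eff)
      if (file.exists(file.path(dir, "model_summary.json"))) {
        ms <- jsonlite::read_json(file.path(dir, "model_summary.json"))
        lines <- c(lines, "", "Rate ratios (multiplicative effect on sighting rate):",
                   vapply(names(ms$rate_ratios), function(nm)
                     sprintf("  %s: %.3g", nm,
                             as.numeric(ms$rate_ratios[[nm]])), ""))
      }
      if (file.exists(file.path(dir, "selection_table.csv"))) {
        tab <- utils::read.csv(file.path(dir, "selection_table.csv"))
        lines <- c(lines, "", "Forward selection (day-grouped CVLL):",
                   utils::capture.output(print(tab, row.names = FALSE)))
      }
      writeLines(lines, file.path(dir, "report.txt"))
      .stage_manifest(dir, stage, config,
                      file.path(dir, c("scans.csv", "sightings_filtered.csv")),
                      file.path(dir, c("effort_summary.csv", "report.txt")))
      list(effort = eff, report = lines)
    })
  message(sprintf("[%s] stage complete", stage))
  invisible(out)
}

# shared preparation for the fit/select stages: covariates at sightings,
# availability sampling, record assembly
.prepare_model_records <- function(dir, config) {
  scans <- .read_scans(dir)
  filt <- utils::read.csv(file.path(dir, "sightings_filtered.csv"),
                          stringsAsFactors = FALSE)
  limits <- read_detection_limits(file.path(dir, "detection_limits.csv"))
  env <- .load_env(dir)
  sc <- do.call(make_scenario, c(list(seed = config$seed), config$scenario))
  wedges <- scenario_wedges(sc)
  m <- match(filt$scan_id, scans$scan_id)
  pres <- sample_covariates(filt$x, filt$y,
                            as.POSIXct(scans$start_time[m], tz = "UTC"), env)
  pres$site <- scans$site[m]
  pres$sea_state <- scans$sea_state[m]
  pres$day_id <- scans$day_id[m]
  n_dropped <- sum(pres$missing_env)
  if (n_dropped > 0)
    message(sprintf("dropping %d presence record(s) on missing environment",
                    n_dropped))
  pres <- pres[!pres$missing_env, , drop = FALSE]
  lkey <- paste(limits$site, limits$species, limits$sea_state)
  radius_fn <- function(site, ss) {
    r <- limits$radius_m[match(paste(site, "porpoise", ss), lkey)]
    if (is.na(r)) stop("no detection limit for ", site, " sea state ", ss)
    r
  }
  # availability restricted to scan conditions usable for the species
  caps <- unlist(config$detection$species_caps)
  use_scans <- scans[scans$sea_state <= max(caps), , drop = FALSE]
  avail <- sample_availability(use_scans, wedges, env,
                               n_per_scan = config$model$n_per_scan,
                               seed = config$seed + 1L,
                               radius_fn = radius_fn)
  list(records = assemble_use_availability(pres, avail, W = config$model$W))
}

.terms_from_names <- function(names) {
  specs <- default_term_specs()
  unknown <- setdiff(names, names(specs))
  if (length(unknown) > 0)
    stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  specs[names]
}

#' Per-site effort and sighting summary
#'
#' The standard survey bookkeeping table: scans of effort and sightings
#' (with total animals) per survey site, with a TOTAL row.
#'
#' @param scans Data frame with site (one row per scan).
#' @param sightings Data frame with scan_id, species, group_size.
#' @return Data frame with columns site, effort_scans, and per species
#'   sightings and animals.
#' @export
effort_summary <- function(scans, sightings) {
  m <- match(sightings$scan_id, scans$scan_id)
  sightings$site <- scans$site[m]
  sites <- sort(unique(scans$site))
  out <- data.frame(site = sites,
                    effort_scans = as.integer(table(factor(scans$site,
                                                           sites))))
  for (sp in sort(unique(sightings$species))) {
    s <- sightings[sightings$species == sp, ]
    out[[paste0(sp, "_sightings")]] <-
      as.integer(table(factor(s$site, sites)))
    out[[paste0(sp, "_animals")]] <-
      as.integer(tapply(s$group_size, factor(s$site, sites), sum,
                        default = 0))
  }
  tot <- out[1, , drop = FALSE]
  tot$site <- "TOTAL"
  for (nm in names(out)[-1]) tot[[nm]] <- sum(out[[nm]])
  rbind(out, tot)
}

#' Render an effort summary as aligned text lines
#' @param eff Data frame from [effort_summary()].
#' @return Character vector of report lines.
#' @export
render_effort_table <- function(eff) {
  c("Survey effort and sightings by site:",
    utils::capture.output(print(eff, row.names = FALSE)))
}
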