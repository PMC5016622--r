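# Workflow plumbing: a single validated configuration drives
# build -> trace -> fit -> simulate -> validate, writing a manifest that
# reproduces the run.

default_config <- function() {
  list(
    site = list(latitude = 37.3, longitude = 127.0, utc_offset = 9,
                north_offset = 0),
    plant = list(spec_path = NULL, seed = 1),
    canopy = list(rows = 1, cols = 1, spacing = 0.8),
    optics = list(reflectance = 0.1, transmittance = 0.07),
    trace = list(n_rays = 2e5, max_impacts = 10, seed = 1),
    day = list(date = "2014-10-15", start_hour = 9, end_hour = 18,
               step_min = 30),
    weather = list(path = NULL, peak_ppfd = 1000, diffuse_fraction = 0.3),
    profile = list(path = NULL, curves_path = NULL, resp_rule = "table3",
                   theta = 0.75),
    ci_rule = list(mode = "ratio", ratio = 0.7, ca_pa = 140),
    chamber = list(log_path = NULL, subtract_leak = FALSE, leak_rate = 0.25),
    out_dir = "canopyray_run"
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(cond, path) if (!isTRUE(cond)) problems <<- c(problems, path)
  chk(abs(cfg$site$latitude) <= 90, "site.latitude in [-90, 90]")
  chk(cfg$canopy$rows >= 1 && cfg$canopy$cols >= 1, "canopy.rows/cols >= 1")
  chk(cfg$optics$reflectance + cfg$optics$transmittance <= 1,
      "optics reflectance + transmittance <= 1")
  chk(cfg$trace$n_rays >= 1, "trace.n_rays >= 1")
  chk(cfg$ci_rule$mode %in% c("ratio", "fixed"), "ci_rule.mode")
  for (p in c("plant.spec_path", "weather.path", "profile.path",
              "profile.curves_path", "chamber.log_path")) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(val) && !file.exists(val)) {
      problems <- c(problems, paste0(p, ": file not found: ", val))
    }
  }
  if (length(problems)) {
    stop("configuration errors:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg
}

#' Run the full build-trace-fit-simulate-validate workflow
#'
#' @param config A configuration list, or a path to a YAML file, merged
#'   over the documented defaults. All file paths are checked before any
#'   computation starts.
#' @return The output directory path (invisibly); writes `profile.csv`,
#'   `day_series.csv`, `scene.obj`, optionally `stats.json`, and
#'   `manifest.json` there.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(default_config(), config))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  spec <- if (is.null(cfg$plant$spec_path)) read_layer_spec()
          else read_layer_spec(cfg$plant$spec_path)
  plant <- build_plant(spec, seed = cfg$plant$seed)
  scene <- build_canopy(plant, cfg$canopy$rows, cfg$canopy$cols,
                        cfg$canopy$spacing)
  write_scene_obj(scene, file.path(out, "scene.obj"))

  profile <- if (!is.null(cfg$profile$curves_path)) {
    curves <- read_gasx_curves(cfg$profile$curves_path)
    fit_layer_profile(curves, resp_rule = cfg$profile$resp_rule)$profile
  } else if (!is.null(cfg$profile$path)) {
    read_photo_profile(cfg$profile$path)
  } else {
    read_photo_profile()
  }
  utils::write.csv(profile, file.path(out, "profile.csv"),
                   row.names = FALSE)

  weather <- if (!is.null(cfg$weather$path)) {
    w <- utils::read.csv(cfg$weather$path, stringsAsFactors = FALSE)
    w$timestamp <- as.POSIXct(w$timestamp, tz = "UTC")
    w
  } else {
    gen_weather_day(cfg$day$date, cfg$weather$peak_ppfd,
                    cfg$weather$diffuse_fraction, cfg$day$start_hour,
                    cfg$day$end_hour, cfg$day$step_min)
  }

  series <- simulate_day(
    scene, weather, profile, cfg$site,
    ci_rule = cfg$ci_rule,
    optics = optical_props(cfg$optics$reflectance,
                           cfg$optics$transmittance),
    config = trace_config(cfg$trace$n_rays, cfg$trace$max_impacts,
                          cfg$trace$seed),
    resp_rule = cfg$profile$resp_rule)

  stats <- NULL
  if (!is.null(cfg$chamber$log_path)) {
    log <- utils::read.csv(cfg$chamber$log_path, stringsAsFactors = FALSE)
    geom <- chamber_geometry(leak_rate = cfg$chamber$leak_rate)
    measured <- chamber_slope_to_rate(
      log, geom, window_s = cfg$day$step_min * 60,
      subtract_leak = cfg$chamber$subtract_leak)
    n <- min(nrow(measured), nrow(series))
    series$measured <- c(measured$rate_umol_s[seq_len(n)],
                         rep(NA, nrow(series) - n))
    stats <- goodness_of_fit(series$measured, series$estimated)
    jsonlite::write_json(stats, file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(series, file.path(out, "day_series.csv"),
                   row.names = FALSE)

  inputs <- Filter(Negate(is.null),
                   list(plant_spec = cfg$plant$spec_path,
                        weather = cfg$weather$path,
                        profile = cfg$profile$path,
                        curves = cfg$profile$curves_path,
                        chamber_log = cfg$chamber$log_path))
  manifest <- list(
    package = "canopyray",
    version = as.character(utils::packageVersion("canopyray")),
    r_version = R.version.string,
    config = cfg,
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Summarise a pipeline run
#'
#' Reads a [run_pipeline()] artifact directory and writes
#' `report.json` (layer profile, daily series summary, fit statistics) and,
#' when ggplot2 is installed, PDF plots of the parameter profile and the
#' daily photosynthesis course.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @return The report list, invisibly.
#' @export
report <- function(artifact_dir) {
  profile <- utils::read.csv(file.path(artifact_dir, "profile.csv"))
  series <- utils::read.csv(file.path(artifact_dir, "day_series.csv"))
  stats_path <- file.path(artifact_dir, "stats.json")
  stats <- if (file.exists(stats_path)) jsonlite::read_json(stats_path)
           else NULL
  rep <- list(
    profile = profile,
    daily_total_umol = sum(series$estimated) *
      diff(as.numeric(as.POSIXct(series$timestamp[1:2], tz = "UTC"))),
    peak_rate_umol_s = max(series$estimated),
    n_steps = nrow(series),
    stats = stats)
  jsonlite::write_json(rep, file.path(artifact_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    g1 <- ggplot2::ggplot(profile, ggplot2::aes(x = layer)) +
      ggplot2::geom_point(ggplot2::aes(y = vlo)) +
      ggplot2::geom_line(ggplot2::aes(y = vlo)) +
      ggplot2::labs(x = "Leaf layer", y = "Vlo (umol m-2 s-1)")
    ggplot2::ggsave(file.path(artifact_dir, "profile.pdf"), g1,
                    width = 5, height = 4)
    series$timestamp <- as.POSIXct(series$timestamp, tz = "UTC")
    g2 <- ggplot2::ggplot(series,
                          ggplot2::aes(timestamp, estimated)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = NULL, y = "Plant photosynthesis (umol s-1)")
    ggplot2::ggsave(file.path(artifact_dir, "day_series.pdf"), g2,
                    width = 6, height = 4)
  }
  invisible(rep)
}
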