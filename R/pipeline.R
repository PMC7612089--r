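#' Default pipeline configuration
#'
#' The full set of recognised configuration keys with their defaults. A user
#' configuration (a nested list, or a YAML file) may override any subset;
#' unknown keys are rejected.
#'
#' @return a nested list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    medium = "land",
    input = list(
      imu_csv = NULL,        # path or imu_series
      vps_csv = NULL,        # path or geo_track
      current_csv = NULL,    # path or current_field (optional)
      behaviour_csv = NULL,  # path or data.frame(time, state) (optional)
      column_map = NULL
    ),
    screening = list(enabled = TRUE, max_speed = 30),
    sensor = list(
      static_window_s = 2,
      vedba_smooth_s = 2,
      orientation_smooth_s = 1,
      heading_smooth_s = 1,
      declination = 0,
      calibrate = TRUE,
      fit_soft_iron = FALSE,
      tag_rotation = NULL,   # 3x3 matrix (row-major vector accepted)
      pressure = list(smoothness = 1e6, asymmetry = 0.01,
                      m_per_unit = 0.01, reference_hpa = 1013.25)
    ),
    speed = list(
      model = "vedba",       # vedba | behaviour | gps
      m = 1, c = 0,
      behaviour_speed_table = NULL,
      use_vertical = FALSE,
      pitch_threshold = 10,
      depth_threshold = 0.3,
      speed_cap = 3,
      gate = "none",         # none | vedba | labels
      vedba_threshold = 0.1,
      travelling_states = NULL
    ),
    correction = list(interval_s = 600),
    schedule = NULL,         # optional vector of intervals for the sweep
    start = NULL,            # c(lat, lon); default: first screened VP
    outdir = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file whose keys follow
#'   [default_pipeline_config()].
#' @return the merged, validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: no such file: ", path)
  .merge_config(yaml::read_yaml(path))
}

.merge_config <- function(user) {
  def <- default_pipeline_config()
  .check_keys(user, def, "config")
  utils::modifyList(def, user)
}

.check_keys <- function(user, def, where) {
  if (!is.list(user)) return(invisible())
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown configuration key(s) under ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      .check_keys(user[[k]], def[[k]], paste(where, k, sep = "$"))
    }
  }
  invisible()
}

.resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x) else x
}

#' Run the full VP-corrected dead-reckoning pipeline
#'
#' Executes, in order: VP screening, magnetometer calibration, tag rotation
#' and declination, posture + VeDBA + heading derivation, depth/altitude from
#' pressure, the configured speed model (with optional vertical-rate override
#' and movement gating), dead-reckoning integration (with optional current
#' integration), VP correction at the configured interval, net-error
#' evaluation against all screened VPs, and -- when a schedule is configured
#' -- the VP-thinning sweep. When `outdir` is set, the corrected track (CSV +
#' GeoJSON), correction report, net-error series, sweep table, resolved
#' configuration and a log are written there.
#'
#' @param config a nested configuration list (see
#'   [default_pipeline_config()]) or the path to a YAML file. Input entries
#'   may be file paths or in-memory objects.
#' @return an invisible list (the artifact bundle): `track_uncorrected`,
#'   `track_corrected`, `report`, `net_error`, `sweep`, `speed`, `heading`,
#'   `config`, `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else .merge_config(config)
  log <- character()
  note <- function(...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), sprintf(...))
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  imu <- stage("ingest", .resolve_input(cfg$input$imu_csv,
                                        function(p) read_imu_csv(p, cfg$input$column_map)))
  vps <- stage("ingest", .resolve_input(cfg$input$vps_csv, read_vps_csv))
  current <- stage("ingest", .resolve_input(cfg$input$current_csv, read_current_csv))
  behaviour <- stage("ingest", .resolve_input(cfg$input$behaviour_csv, utils::read.csv))
  if (is.null(imu) || is.null(vps)) stop("run_pipeline: imu and vps inputs are required")
  fs <- attr(imu, "fs")
  note("ingest: %d IMU samples @ %g Hz (%d dropped), %d VPs",
       nrow(imu), fs, attr(imu, "dropped"), nrow(vps))

  if (isTRUE(cfg$screening$enabled)) {
    vps <- stage("screening", screen_vps(vps, cfg$screening$max_speed))
    note("screening: %d fixes removed (> %g m/s)", attr(vps, "screened_out"),
         cfg$screening$max_speed)
  }

  cal <- stage("calibration", {
    base <- if (isTRUE(cfg$sensor$calibrate)) {
      calibrate_magnetometer(imu, fit_soft_iron = isTRUE(cfg$sensor$fit_soft_iron),
                             declination = cfg$sensor$declination)
    } else {
      calibration_model(declination = cfg$sensor$declination)
    }
    if (!is.null(cfg$sensor$tag_rotation)) {
      base$tag_rotation <- matrix(as.numeric(cfg$sensor$tag_rotation), 3L, 3L,
                                  byrow = TRUE)
      .check_rotation(base$tag_rotation)
    }
    base
  })
  if (!isTRUE(all.equal(cal$tag_rotation, diag(3)))) {
    imu <- stage("rotation", apply_tag_rotation(imu, cal))
    note("rotation: tag-to-body rotation applied")
  }

  split <- stage("orientation", separate_acceleration(imu, cfg$sensor$static_window_s))
  orient <- stage("orientation", estimate_pitch_roll(split, cfg$sensor$orientation_smooth_s))
  vedba <- stage("orientation", compute_vedba(split, cfg$sensor$vedba_smooth_s))
  magcal <- apply_calibration(imu, cal)
  heading <- stage("orientation",
                   tilt_compensated_heading(orient, magcal, cal,
                                            smooth_s = cfg$sensor$heading_smooth_s,
                                            fs = fs))
  note("orientation: %d posture-flagged, %d heading-flagged samples",
       sum(orient$unreliable), sum(heading$flagged))

  z <- rep(0, nrow(imu))
  if (cfg$medium != "land" && "pressure" %in% names(imu)) {
    z <- stage("vertical", {
      if (cfg$medium == "water") {
        bl <- pressure_baseline(imu$pressure,
                                smoothness = cfg$sensor$pressure$smoothness,
                                asymmetry = cfg$sensor$pressure$asymmetry)
        pressure_to_vertical(imu$pressure, bl, "water",
                             m_per_unit = cfg$sensor$pressure$m_per_unit)
      } else {
        pressure_to_vertical(imu$pressure, medium = "air",
                             reference = cfg$sensor$pressure$reference_hpa)
      }
    })
    note("vertical: z range [%.2f, %.2f] m", min(z), max(z))
  }

  states <- NULL
  if (!is.null(behaviour)) {
    states <- behaviour$state[match(round(imu$t, 6), round(behaviour$time, 6))]
    if (anyNA(states)) stop("run_pipeline: behaviour labels do not cover all samples")
  }
  smc <- speed_model_config(m = cfg$speed$m, c = cfg$speed$c,
                            behaviour_speed_table = unlist(cfg$speed$behaviour_speed_table),
                            pitch_threshold = cfg$speed$pitch_threshold,
                            depth_threshold = cfg$speed$depth_threshold,
                            speed_cap = cfg$speed$speed_cap,
                            vedba_threshold = cfg$speed$vedba_threshold,
                            travelling_states = cfg$speed$travelling_states)
  speed <- stage("speed", switch(cfg$speed$model,
    vedba = vedba_speed(vedba, smc),
    behaviour = behaviour_speed(states, smc),
    gps = vp_derived_speed(vps, imu$t),
    stop("unknown speed model: ", cfg$speed$model)))
  if (isTRUE(cfg$speed$use_vertical)) {
    speed <- stage("speed", vertical_rate_speed(z, orient$pitch, smc, speed, fs,
                                                smooth_s = cfg$sensor$orientation_smooth_s))
  }
  if (cfg$speed$gate != "none") {
    mask <- stage("speed", movement_gate(vedba, smc, states = states,
                                         mode = cfg$speed$gate))
    speed <- apply_gate(speed, mask)
    note("speed: %d of %d samples gated out", sum(!mask), length(mask))
  }
  note("speed: model '%s', mean %.3g m/s", cfg$speed$model, mean(speed$speed))

  n <- nrow(imu)
  tv <- travel_vectors(imu$t[-n], heading$heading[-n], speed$speed[-n],
                       dz = diff(z), medium = cfg$medium)
  start <- cfg$start %||% c(vps$lat[1L], vps$lon[1L])
  track <- stage("dead_reckoning", integrate_track(c(start, z[1L]), tv, current))
  note("dead_reckoning: %d positions%s", nrow(track),
       if (is.null(current)) "" else sprintf(", current integration on (%d grid misses)",
                                             current_misses(current)))

  thinned <- stage("correction", thin_vps(vps, cfg$correction$interval_s))
  cor <- stage("correction", correct_track(track, thinned, tv = tv))
  note("correction: interval %g s, %d segments, %d degenerate",
       cfg$correction$interval_s, nrow(cor$report$segments),
       cor$report$degenerate_segments)

  ne <- stage("metrics", net_error(cor$track, vps))
  note("metrics: mean net error %.3g m over %d VPs", attr(ne, "mean"), nrow(ne))
  mode <- if (cfg$medium == "land") "2d" else "3d"
  sweep <- NULL
  if (!is.null(cfg$schedule)) {
    sweep <- stage("metrics", thinning_sweep(track, vps, cfg$schedule, mode))
    note("metrics: thinning sweep over %d intervals", length(cfg$schedule))
  }

  bundle <- list(track_uncorrected = track, track_corrected = cor$track,
                 report = cor$report, net_error = ne, sweep = sweep,
                 speed = speed, heading = heading, config = cfg, log = log)
  if (!is.null(cfg$outdir)) .write_bundle(bundle, cfg)
  invisible(bundle)
}

.write_bundle <- function(bundle, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$outdir, f)
  cfg_out <- cfg
  for (k in names(cfg_out$input)) {
    if (!is.character(cfg_out$input[[k]]) && !is.null(cfg_out$input[[k]])) {
      cfg_out$input[[k]] <- "<in-memory>"
    }
  }
  yaml::write_yaml(cfg_out, pth("config_resolved.yaml"))
  hash <- unname(tools::md5sum(pth("config_resolved.yaml")))
  tr <- bundle$track_corrected
  tr$speed <- bundle$speed$speed
  tr$heading <- bundle$heading$heading
  tr$source <- bundle$speed$source
  write_track(tr, pth("track_corrected.csv"), "csv")
  write_track(bundle$track_corrected, pth("track_corrected.geojson"), "geojson")
  write_correction_report(bundle$report, pth("correction_report.csv"))
  utils::write.csv(as.data.frame(bundle$net_error), pth("net_error.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$sweep)) {
    utils::write.csv(bundle$sweep, pth("thinning_sweep.csv"), row.names = FALSE)
  }
  header <- c(sprintf("# vptrack %s", as.character(utils::packageVersion("vptrack"))),
              sprintf("# config md5 %s", hash))
  writeLines(c(header, bundle$log), pth("pipeline.log"))
  invisible(cfg$outdir)
}
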