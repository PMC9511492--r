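# Pipeline orchestration: simulate -> segment -> fit -> train -> solve ->
# check-geometry over a YAML run configuration.

default_demo_sheets <- function() {
  beta <- c(1, 0.45, 0.3, 0.25, 0.15, -0.1, 0.2)
  list(list(center = c(18, 22), side = 13, phi_deg = 25, theta_deg = 23,
            beta = beta, scale = 1),
       list(center = c(47, 26), side = 13, phi_deg = 85, theta_deg = 23,
            beta = beta, scale = 1.3))
}

#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a two-sheet synthetic scene at
#' tilt 23 degrees with a 60 degree in-plane offset, a reduced-size
#' training run, and ROI boxes over each sheet. All angles at this boundary
#' are in degrees.
#'
#' @param out_dir output directory for artifacts.
#' @param seed base seed; per-stage seeds derive from it unless given
#'   explicitly in the config.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("vsfg-run-"), seed = 1) {
  list(version = 1,
       out_dir = out_dir,
       seed = seed,
       stages = c("simulate", "segment", "fit", "train", "solve",
                  "check_geometry"),
       scene = list(dim = c(48, 64), snr = 56, baseline = 10,
                    sheets = default_demo_sheets()),
       segmentation = list(k = 3),
       rois = list(list(box = c(12, 34, 10, 36), sheet_id = "sheet1"),
                   list(box = c(38, 60, 12, 40), sheet_id = "sheet2")),
       solver = list(n_train = 20000, epochs = 200, batch_size = 100,
                     hidden = c(200, 100, 50), lr = 2e-3, lr_decay = 0.99,
                     val_frac = 0.1),
       observation = list(delta_phi_deg = 60),
       geometry = list(h_observed = 2.9, h_upright = 3.1))
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  base <- demo_config()
  known <- c(names(base), "seeds")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  # shallow merge: scalar blocks inherit defaults field-by-field, while
  # positional lists (sheets, rois, stages) are replaced wholesale
  cfg <- base
  for (nm in names(config)) {
    if (nm %in% c("scene", "segmentation", "solver", "observation",
                  "geometry") && is.list(config[[nm]])) {
      for (f in names(config[[nm]])) cfg[[nm]][[f]] <- config[[nm]][[f]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  if (is.null(config$stages)) cfg$stages <- base$stages
  cfg$stages <- as.character(cfg$stages)
  bad <- setdiff(cfg$stages, c("simulate", "segment", "fit", "train",
                               "solve", "check_geometry"))
  if (length(bad)) stop("unknown pipeline stages: ", paste(bad, collapse = ", "))
  if (is.null(cfg$seeds)) cfg$seeds <- list()
  for (s in c("simulate", "segment", "train")) {
    if (is.null(cfg$seeds[[s]])) {
      cfg$seeds[[s]] <- cfg$seed + match(s, c("simulate", "segment", "train"))
    }
  }
  cfg
}

file_hash <- function(path) unname(tools::md5sum(path))

require_artifact <- function(path, producer, consumer) {
  if (!file.exists(path)) {
    stop("stage '", consumer, "' needs ", basename(path),
         "; run stage '", producer, "' first")
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order: `simulate` renders the synthetic
#' two-sheet cube; `segment` computes the spectral-class label map; `fit`
#' sums the configured ROIs, fits the CH-stretch multipeak model and writes
#' the per-sheet susceptibility magnitudes; `train` generates a training
#' set and trains the network solver; `solve` inverts the measured
#' magnitudes under the two-sheet constraint; `check_geometry` runs the
#' stacking-height and steric consistency checks against the recovered
#' tilt. Every artifact is content-hashed into the run report, and every
#' stochastic stage draws from an explicit seed recorded there.
#'
#' @param config a config list or path to a YAML file; see [demo_config()].
#' @return The run report (list), invisibly written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = demo_config()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(cube = file.path(cfg$out_dir, "cube.rds"),
                labels = file.path(cfg$out_dir, "labels.rds"),
                susceptibilities = file.path(cfg$out_dir, "susceptibilities.csv"),
                solver = file.path(cfg$out_dir, "solver.rds"),
                solution = file.path(cfg$out_dir, "solution.json"),
                geometry = file.path(cfg$out_dir, "geometry.json"),
                report = file.path(cfg$out_dir, "report.json"))
  report <- list(config = cfg, stages = list())

  for (stage in cfg$stages) {
    info <- switch(stage,
      simulate = {
        sheets <- lapply(cfg$scene$sheets, function(sh) {
          sh$beta <- as.numeric(sh$beta); sh$center <- as.numeric(sh$center); sh
        })
        scene <- sheet_scene(dim = unlist(cfg$scene$dim),
                             sheets = sheets,
                             baseline = cfg$scene$baseline,
                             snr = cfg$scene$snr)
        cube <- gen_cube(scene, seed = cfg$seeds$simulate)
        write_cube(cube, paths$cube)
        list(seed = cfg$seeds$simulate, artifact = paths$cube,
             hash = file_hash(paths$cube))
      },
      segment = {
        require_artifact(paths$cube, "simulate", "segment")
        cube <- read_cube(paths$cube)
        lm <- segment_spectral_classes(cube, k = cfg$segmentation$k,
                                       seed = cfg$seeds$segment)
        saveRDS(lm, paths$labels)
        list(seed = cfg$seeds$segment, artifact = paths$labels,
             hash = file_hash(paths$labels),
             counts = lm$counts, no_structure = lm$no_structure)
      },
      fit = {
        require_artifact(paths$cube, "simulate", "fit")
        require_artifact(paths$labels, "segment", "fit")
        cube <- read_cube(paths$cube)
        lm <- readRDS(paths$labels)
        mags <- lapply(cfg$rois, function(roi) {
          mask <- roi_box_mask(lm, unlist(roi$box))
          extract_roi_susceptibilities(cube, mask)
        })
        names(mags) <- vapply(cfg$rois, function(r) r$sheet_id, character(1))
        write_susceptibilities(mags, paths$susceptibilities)
        list(artifact = paths$susceptibilities,
             hash = file_hash(paths$susceptibilities),
             pixel_counts = vapply(mags, function(m)
               as.integer(attr(m, "pixel_count")), integer(1)))
      },
      train = {
        ts <- gen_training_set(cfg$solver$n_train, seed = cfg$seeds$train)
        sc <- solver_config(hidden = unlist(cfg$solver$hidden),
                            epochs = cfg$solver$epochs,
                            batch_size = cfg$solver$batch_size,
                            val_frac = cfg$solver$val_frac,
                            lr = cfg$solver$lr,
                            lr_decay = cfg$solver$lr_decay,
                            seed = cfg$seeds$train)
        model <- train_solver(ts, sc)
        save_solver(model, paths$solver)
        list(seed = cfg$seeds$train, artifact = paths$solver,
             hash = file_hash(paths$solver),
             final_train_loss = utils::tail(model$history$train, 1),
             final_validation_loss = utils::tail(model$history$validation, 1))
      },
      solve = {
        require_artifact(paths$susceptibilities, "fit", "solve")
        require_artifact(paths$solver, "train", "solve")
        mags <- read_susceptibilities(paths$susceptibilities)
        model <- load_solver(paths$solver)
        obs <- two_sheet_observation(rbind(mags[[1]], mags[[2]]),
                                     delta_phi_deg =
                                       cfg$observation$delta_phi_deg,
                                     sheet_ids = names(mags))
        sol <- solve_orientation(obs, model)
        write_solution(sol, paths$solution)
        list(artifact = paths$solution, hash = file_hash(paths$solution),
             theta_deg = sol$theta_deg, phi1_deg = sol$phi1_deg,
             susceptibility_mse = sol$susceptibility_mse)
      },
      check_geometry = {
        tilt_h <- tilt_from_heights(cfg$geometry$h_observed,
                                    cfg$geometry$h_upright)
        tilt_nn <- if (file.exists(paths$solution)) {
          jsonlite::read_json(paths$solution)$theta_deg
        } else NA_real_
        steric <- if (is.finite(tilt_nn)) {
          steric_class(packing_model(tilt_deg = min(tilt_nn, 90)))
        } else NULL
        out <- list(tilt_from_heights_deg = tilt_h,
                    tilt_from_solver_deg = tilt_nn,
                    consistent_within_deg = if (is.finite(tilt_nn))
                      abs(tilt_h - tilt_nn) else NA_real_,
                    steric = steric)
        jsonlite::write_json(out, paths$geometry, auto_unbox = TRUE,
                             digits = NA)
        c(out[1:3], list(artifact = paths$geometry,
                         hash = file_hash(paths$geometry)))
      })
    report$stages[[stage]] <- info
  }
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
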