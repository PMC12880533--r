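# Configuration, file formats and pipeline orchestration. All tabular
# artifacts are plain text written at full precision so that a write/read
# round trip is bit-stable.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a sensor stream as CSV
#'
#' Column layout: `time_s` then the six channels in the fixed
#' [channel_names()] order; a second header line records the units.
#' Values are written at full (17 significant digit) precision, so a
#' round trip reproduces the stream exactly.
#'
#' @param stream A `sensor_stream`.
#' @param path Output path.
#' @return Invisibly, `path` (write) / the `sensor_stream` (read).
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  cols <- colnames(stream$data)
  writeLines(paste(c("time_s", cols), collapse = ","), con)
  writeLines(paste(c(sprintf("# units: s, %s; rate_hz: %g", stream$units,
                             stream$rate)), collapse = ","), con)
  body <- cbind(stream$time, stream$data)
  writeLines(apply(body, 1, function(r) paste(fmt_num(r), collapse = ",")),
             con)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[2], "# units:"))
    stop("malformed stream CSV at line 2: missing units header", call. = FALSE)
  header <- strsplit(lines[1], ",")[[1]]
  meta <- regmatches(lines[2],
                     regexec("# units: s, ([^;]+); rate_hz: ([0-9.]+)", lines[2]))[[1]]
  if (length(meta) != 3L)
    stop("malformed units header at line 2", call. = FALSE)
  if (length(lines) > 2L) {
    vals <- do.call(rbind, lapply(strsplit(lines[-(1:2)], ","), as.numeric))
  } else vals <- matrix(numeric(0), 0, length(header))
  data <- vals[, -1, drop = FALSE]
  colnames(data) <- header[-1]
  st <- sensor_stream(data, rate = as.numeric(meta[3]),
                      start = if (nrow(vals)) vals[1, 1] else 0,
                      units = meta[2])
  st
}

#' Write / read a labeled dataset as CSV
#'
#' @param data A `labeled_dataset`.
#' @param path Output path.
#' @return Invisibly `path` (write) / the `labeled_dataset` (read).
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  need <- c("condition_id", "d_set_mm", "f_set_mm_s")
  if (!all(need %in% names(df)))
    stop("malformed dataset CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  fn <- setdiff(names(df), need)
  mode <- if (all(startsWith(fn, "v_"))) "bridge"
  else if (all(startsWith(fn, "dt_"))) "compensated" else "temperature"
  structure(df, feature_names = fn, mode = mode,
            class = c("labeled_dataset", "data.frame"))
}

#' Write / read fold assignments as CSV
#' @param folds A `fold_assignment`.
#' @param path Output path.
#' @return Invisibly `path` (write) / the `fold_assignment` (read).
#' @export
write_folds_csv <- function(folds, path) {
  stopifnot(inherits(folds, "fold_assignment"))
  utils::write.csv(folds$assignment, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_folds_csv
#' @export
read_folds_csv <- function(path) {
  asg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("condition_id", "fold") %in% names(asg)))
    stop("malformed folds CSV", call. = FALSE)
  structure(list(assignment = asg, k = max(asg$fold)),
            class = "fold_assignment")
}

#' Save / load a thermal field
#'
#' Portable text container: a JSON file with the grid metadata (cell
#' counts, spacing, coordinate origin, material labels) next to a CSV
#' holding one row per cell (material id and temperature at full
#' precision, x-fastest ordering).
#'
#' @param field A `thermal_field`.
#' @param path Base path; `.json` and `.csv` are appended.
#' @return Invisibly the base path (write) / the `thermal_field` (read).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "thermal_field"))
  g <- field$grid
  meta <- list(nx = g$nx, ny = g$ny, nz = g$nz, nz_solid = g$nz_solid,
               spacing = g$spacing, x0 = g$x[1], y0 = g$y[1], z0 = g$z[1],
               labels = g$labels, channel_radius = g$channel_radius,
               channel_axis_z = g$channel_axis_z,
               fluid_section_cells = g$fluid_section_cells,
               steady = isTRUE(field$steady), time = field$time,
               relres = field$relres)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  df <- data.frame(material = as.vector(g$material),
                   temperature_c = fmt_num(as.vector(field$temperature)))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  dims <- c(meta$nx, meta$ny, meta$nz)
  h <- meta$spacing
  grid <- structure(list(
    nx = meta$nx, ny = meta$ny, nz = meta$nz, nz_solid = meta$nz_solid,
    spacing = h,
    x = meta$x0 + (seq_len(meta$nx) - 1) * h,
    y = meta$y0 + (seq_len(meta$ny) - 1) * h,
    z = meta$z0 + (seq_len(meta$nz) - 1) * h,
    material = array(as.integer(df$material), dim = dims),
    labels = meta$labels, channel_radius = meta$channel_radius,
    channel_axis_z = meta$channel_axis_z,
    fluid_section_cells = meta$fluid_section_cells), class = "tf_grid")
  structure(list(temperature = array(df$temperature_c, dim = dims),
                 grid = grid, steady = isTRUE(meta$steady),
                 relres = meta$relres,
                 time = if (is.null(meta$time)) NA_real_ else meta$time),
            class = "thermal_field")
}

#' Read a scenario from a structured text (YAML) config
#'
#' Recognised blocks: `geometry` (block, channel_diameter_mm,
#' vessel_depth_mm, wall_thickness_mm), `materials` (named entries with
#' conductivity_w_mk, specific_heat_j_kgk, density_kg_m3), `actuator`
#' (diameter_mm, power_mw), `layout` (lateral_offset_mm,
#' interlayer_spacing_mm), `ambient` (ambient_c, h_w_m2k, bottom_c,
#' inlet_c), `flow` (speed_mm_s, profile), `spacing_mm`. Missing blocks
#' fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A `tf_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- default_scenario()
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    sc$geometry <- phantom_geometry(
      block = if (!is.null(g$block_mm)) unlist(g$block_mm) else sc$geometry$block,
      channel_diameter = g$channel_diameter_mm %||% sc$geometry$channel_diameter,
      vessel_depth = g$vessel_depth_mm %||% sc$geometry$vessel_depth,
      wall_thickness = g$wall_thickness_mm %||% 0)
  }
  if (!is.null(cfg$materials)) {
    for (nm in names(cfg$materials)) {
      m <- cfg$materials[[nm]]
      sc$materials[[nm]] <- material_properties(
        nm, m$conductivity_w_mk, m$specific_heat_j_kgk, m$density_kg_m3)
    }
  }
  if (!is.null(cfg$actuator))
    sc$actuator <- actuator_spec(cfg$actuator$diameter_mm %||% 3.5,
                                 cfg$actuator$power_mw %||% 56.7)
  if (!is.null(cfg$layout))
    sc$layout <- sensor_layout(cfg$layout$lateral_offset_mm %||% 3.5,
                               cfg$layout$interlayer_spacing_mm %||% 1.5,
                               actuator_diameter = sc$actuator$diameter)
  if (!is.null(cfg$ambient))
    sc$ambient <- ambient_conditions(cfg$ambient$ambient_c %||% 25,
                                     cfg$ambient$h_w_m2k %||% 15,
                                     cfg$ambient$bottom_c %||% 25,
                                     cfg$ambient$inlet_c %||% 25)
  if (!is.null(cfg$flow))
    sc$flow <- flow_condition(cfg$flow$speed_mm_s %||% 1,
                              cfg$flow$profile %||% "plug")
  if (!is.null(cfg$spacing_mm)) sc$spacing <- cfg$spacing_mm
  scenario(sc$geometry, sc$materials, sc$actuator, sc$layout, sc$ambient,
           sc$flow, sc$spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# master seed -> per-stage seed by a fixed counter offset
stage_seed <- function(master, stage) {
  offsets <- c(simulate = 0L, dataset = 1L, train = 2L, crossval = 3L,
               sensitivity = 4L, dynamic = 5L, `bp-demo` = 6L, ambient = 7L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(master) * 11L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run a pipeline stage
#'
#' Thin orchestration over the package functions: reads an optional
#' scenario config, runs one stage and writes its artifacts plus a JSON
#' manifest (stage, seed, config digest) into the output directory.
#' Re-running with identical inputs reproduces identical outputs.
#'
#' @param stage One of `"simulate"`, `"dataset"`, `"crossval"`,
#'   `"sensitivity"`, `"dynamic"`, `"bp-demo"`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional path to a YAML scenario config.
#' @param seed Master seed; expanded to per-stage seeds by a fixed
#'   counter scheme.
#' @param depths,flows,replicates Condition-grid settings for dataset-like
#'   stages.
#' @param epochs Training epochs for learning stages.
#' @return Invisibly, a list of the artifacts produced (also on disk).
#' @export
run_pipeline <- function(stage = c("simulate", "dataset", "crossval",
                                   "sensitivity", "dynamic", "bp-demo"),
                         out_dir = ".", config = NULL, seed = 0L,
                         depths = c(1, 1.5, 2), flows = 1:10,
                         replicates = 50, epochs = 300) {
  stage <- match.arg(stage)
  sc <- if (!is.null(config)) read_scenario_config(config) else default_scenario()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seed(seed, stage)
  result <- switch(stage,
    simulate = {
      grid <- build_grid(sc$geometry, sc$actuator, sc$layout, sc$spacing)
      field <- solve_steady(grid, sc$materials, sc$ambient, sc$flow,
                            sc$actuator$power)
      write_field(field, file.path(out_dir, "field"))
      list(field = field)
    },
    dataset = {
      cg <- condition_grid(depths, flows, replicates)
      ds <- generate_dataset(cg, sc, noise_model(seed = sseed))
      write_dataset_csv(ds, file.path(out_dir, "dataset.csv"))
      folds <- grouped_kfold(cg, min(5L, nrow(cg$conditions)), seed = sseed)
      write_folds_csv(folds, file.path(out_dir, "folds.csv"))
      list(dataset = ds, folds = folds)
    },
    crossval = {
      ds_path <- file.path(out_dir, "dataset.csv")
      if (!file.exists(ds_path))
        stop("missing upstream artifact dataset.csv: run the dataset stage first",
             call. = FALSE)
      ds <- read_dataset_csv(ds_path)
      folds <- read_folds_csv(file.path(out_dir, "folds.csv"))
      rep <- crossval_evaluate(ds, folds, regressor_spec(),
                               training_config(epochs = epochs, seed = sseed))
      utils::write.csv(rep$predictions,
                       file.path(out_dir, "cv_predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(metric = c("rmse_f", "rmse_d", "q95_f",
                                             "q95_d"),
                                  value = c(rep$rmse_f, rep$rmse_d,
                                            rep$q95_f, rep$q95_d)),
                       file.path(out_dir, "cv_metrics.csv"),
                       row.names = FALSE)
      list(report = rep)
    },
    sensitivity = {
      sw <- sensitivity_sweep("wall_stiffness", c(130, 180), 5, sc)
      utils::write.csv(data.frame(parameter = "wall_stiffness",
                                  delta_sn = sw$delta_sn),
                       file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
      list(sweep = sw)
    },
    dynamic = {
      cg <- condition_grid(depths, flows, max(2L, min(replicates, 10L)))
      ds <- generate_dataset(cg, sc, noise_model(seed = sseed))
      model <- fit_regressor(ds, regressor_spec(),
                             training_config(epochs = epochs, seed = sseed))
      dt <- dynamic_tracking_eval(model, sc)
      utils::write.csv(dt$predictions, file.path(out_dir, "tracking.csv"),
                       row.names = FALSE)
      list(tracking = dt)
    },
    `bp-demo` = {
      demo <- run_bp_demo(cardio_config(seed = sseed), seed = sseed)
      utils::write.csv(demo$predictions$fused,
                       file.path(out_dir, "bp_fused.csv"), row.names = FALSE)
      utils::write.csv(demo$predictions$ppg_only,
                       file.path(out_dir, "bp_ppg_only.csv"),
                       row.names = FALSE)
      list(demo = demo)
    })
  manifest <- list(stage = stage, master_seed = as.integer(seed),
                   stage_seed = as.integer(sseed),
                   config = if (!is.null(config)) basename(config) else "default",
                   package_version = as.character(utils::packageVersion("thermoflow")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
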