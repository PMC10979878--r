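# Serialisation and pipeline orchestration. Recordings are stored as a
# flat channel-major float64 binary matrix plus a human-readable JSON
# sidecar and a TSV channel table: language-agnostic, diff-able metadata,
# lossless round trips.

#' Write / read a recording
#'
#' `write_recording` writes `<path>.dat` (channel-major float64, tesla),
#' `<path>.json` (sample rate, dimensions, units, triggers, loop mode,
#' seed, processing history), `<path>.channels.tsv` (+ sidecar) with the
#' sensor array, and `<path>.flags.bin` when railing flags are present.
#' `read_recording` reverses this losslessly; missing or inconsistent
#' files raise explicit format errors. Simulation ground truth is not
#' serialised.
#'
#' @param rec An [opm_recording()].
#' @param path Path prefix (no extension).
#' @return `write_recording`: `path`, invisibly. `read_recording`: an
#'   [opm_recording()].
#' @export
write_recording <- function(rec, path) {
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 8, endian = "little")
  close(con)
  write_sensor_array(rec$array, paste0(path, ".channels.tsv"))
  if (!is.null(rec$flags)) {
    fcon <- file(paste0(path, ".flags.bin"), "wb")
    writeBin(as.raw(rec$flags), fcon)
    close(fcon)
  }
  meta <- rec$meta
  meta$hfc_projector <- NULL   # large; recomputable from the channel table
  side <- list(format = "opmsim-recording-v1", units = "T",
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               sample_rate = rec$sample_rate,
               byte_order = "little", sample_major = TRUE,
               triggers = rec$triggers,
               has_flags = !is.null(rec$flags),
               meta = meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidef <- paste0(path, ".json")
  if (!file.exists(sidef))
    stop("format error: missing recording sidecar ", sidef)
  side <- jsonlite::read_json(sidef, simplifyVector = TRUE)
  if (!identical(side$format, "opmsim-recording-v1"))
    stop("format error: unrecognised recording format")
  if (!identical(side$units, "T"))
    stop("format error: unit mismatch (expected tesla)")
  array <- read_sensor_array(paste0(path, ".channels.tsv"))
  if (n_channels(array) != side$n_channels)
    stop("format error: channel table has ", n_channels(array),
         " channels but sidecar declares ", side$n_channels)
  nval <- side$n_channels * side$n_samples
  con <- file(paste0(path, ".dat"), "rb")
  raw <- readBin(con, "numeric", n = nval, size = 8, endian = "little")
  close(con)
  if (length(raw) != nval)
    stop("format error: data file holds ", length(raw),
         " values, expected ", nval)
  data <- t(matrix(raw, nrow = side$n_samples))
  flags <- NULL
  if (isTRUE(side$has_flags)) {
    fcon <- file(paste0(path, ".flags.bin"), "rb")
    fl <- readBin(fcon, "raw", n = nval)
    close(fcon)
    flags <- matrix(as.logical(fl), nrow = side$n_channels)
  }
  triggers <- as.data.frame(side$triggers)
  opm_recording(data, side$sample_rate, array, triggers, flags = flags,
                meta = as.list(side$meta))
}

#' Export a statistical image as a voxel table
#'
#' Writes a TSV with columns `x, y, z, value` (metres, statistic value).
#' With `nifti = TRUE` (requires the RNifti package) a volume resampled
#' onto the grid lattice is also written as `<path>.nii.gz`.
#'
#' @param image A `stat_image`.
#' @param path Output TSV path.
#' @param nifti Also write a NIfTI volume.
#' @return `path`, invisibly.
#' @export
write_stat_image <- function(image, path, nifti = FALSE) {
  g <- image$grid$positions
  df <- data.frame(x = g[, 1], y = g[, 2], z = g[, 3],
                   value = image$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI export requires the RNifti package")
    sp <- image$grid$spacing
    ax <- lapply(1:3, function(k) sort(unique(g[, k])))
    dims <- vapply(ax, length, 0L)
    vol <- array(NA_real_, dims)
    idx <- cbind(match(g[, 1], ax[[1]]), match(g[, 2], ax[[2]]),
                 match(g[, 3], ax[[3]]))
    vol[idx] <- image$values
    nii <- RNifti::asNifti(vol, pixdim = rep(sp * 1000, 3))
    RNifti::writeNifti(nii, paste0(sub("\\.tsv$", "", path), ".nii.gz"))
  }
  invisible(path)
}

#' Export a time-frequency spectrogram as TSV
#'
#' Long-format table with columns `band_low, band_high, time, value`.
#'
#' @param tfs An `opm_tfs`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tfs <- function(tfs, path) {
  nb <- nrow(tfs$values)
  nt <- ncol(tfs$values)
  df <- data.frame(band_low = rep(tfs$bands[, 1], times = nt),
                   band_high = rep(tfs$bands[, 2], times = nt),
                   time = rep(tfs$times, each = nb),
                   value = as.numeric(tfs$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(kind = "phantom_linearity",
       seed = 1,
       helmet = list(n_sensors = 64, head_radius = 0.09, standoff = 0.015),
       sensor_model = list(loop_mode = "closed", sample_rate = 375,
                           noise_density = 15e-15),
       phantom = list(conditions = c("open", "closed"), slot_sensor = 1),
       beamformer = list(band = c(13, 30), reg_fraction = 0.01,
                         grid_spacing = 0.004),
       tfs = list(control_window = c(6.5, 7.5)))
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

params_from_config <- function(cfg, loop_mode = NULL) {
  sm <- cfg$sensor_model
  if (!is.null(loop_mode)) sm$loop_mode <- loop_mode
  do.call(sensor_model_params, sm)
}

#' Run a configured end-to-end pipeline
#'
#' Executes simulate -> analyse for one of the bundled run kinds and
#' writes all artefacts (recordings, tables, images, reports, log) into
#' `out_dir`. Identical config + seed give identical outputs. Bundled
#' example configs live under `system.file("extdata/configs",
#' package = "opmsim")`.
#'
#' \describe{
#'   \item{phantom_linearity}{8 x 8 burst protocol in each configured
#'     condition; writes burst tables and the open-vs-closed linearity
#'     fit.}
#'   \item{phantom_sweep}{0-8 nT background sweep; writes burst tables
#'     and background-error statistics.}
#'   \item{sit_to_stand}{movement session; writes a beta pseudo-T image
#'     and a TFS at the image extremum.}
#' }
#'
#' @param config Config list or path to a YAML file; missing entries fall
#'   back to defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of result objects; artefact paths in
#'   `$artifacts`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("opmsim_run_")) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgfile <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfgfile)
  cfg_hash <- unname(tools::md5sum(cfgfile))
  art <- character()
  res <- list()
  helmet <- do.call(build_synthetic_helmet,
                    c(cfg$helmet, list(seed = cfg$seed)))
  if (cfg$kind %in% c("phantom_linearity", "phantom_sweep")) {
    protocol <- if (cfg$kind == "phantom_linearity") "linearity" else
      "background_sweep"
    tables <- list()
    for (cond in cfg$phantom$conditions) {
      params <- params_from_config(cfg, loop_mode = cond)
      rec <- simulate_phantom_protocol(helmet, protocol, params,
                                       seed = cfg$seed,
                                       slot_sensor = cfg$phantom$slot_sensor)
      tab <- extract_burst_amplitudes(rec)
      f <- file.path(out_dir, sprintf("bursts_%s.tsv", cond))
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art <- c(art, f)
      tables[[cond]] <- tab
      rm(rec)
    }
    res$tables <- tables
    if (cfg$kind == "phantom_linearity" && length(tables) == 2) {
      res$linearity <- linearity_comparison(tables$open, tables$closed)
      f <- file.path(out_dir, "linearity.json")
      jsonlite::write_json(res$linearity[c("slope", "intercept",
                                           "r_squared")],
                           f, auto_unbox = TRUE, digits = NA)
      art <- c(art, f)
    }
    if (cfg$kind == "phantom_sweep") {
      res$error_stats <- lapply(tables, background_error_stats, top_k = 10)
      f <- file.path(out_dir, "error_stats.json")
      jsonlite::write_json(lapply(res$error_stats, function(s)
        s[c("mean_percent", "sd_percent", "channels")]),
        f, auto_unbox = TRUE, digits = NA)
      art <- c(art, f)
    }
  } else if (cfg$kind == "sit_to_stand") {
    params <- params_from_config(cfg)
    rec <- simulate_sit_to_stand_session(helmet,
                                         n_trials = cfg$n_trials %||% 20,
                                         params = params, seed = cfg$seed)
    sphere <- rec$truth$sphere
    rec_f <- homogeneous_field_correction(apply_filters(rec))
    ep <- segment_trials(rec_f, 4L, c(0, 8))
    ep2 <- segment_trials(rec_f, 5L, c(0, 8))
    ep$data <- abind_trials(ep$data, ep2$data)
    ep$retained_trial_ids <- seq_len(dim(ep$data)[1])
    model <- compute_covariance(ep, band = cfg$beamformer$band,
                                reg_fraction = cfg$beamformer$reg_fraction)
    grid <- make_source_grid(sphere,
                             spacing = cfg$beamformer$grid_spacing,
                             centre = c(0, 0.01, 0.055),
                             half_width = 0.03)
    lf <- build_lead_fields(helmet, grid, sphere)
    model <- lcmv_weights(model, lf)
    epb <- filter_epochs(ep, cfg$beamformer$band)
    img <- pseudo_t_image(epb, model, active = c(2, 3),
                          control = c(6.5, 7.5))
    f <- file.path(out_dir, "pseudo_t_beta.tsv")
    write_stat_image(img, f)
    art <- c(art, f)
    peak <- peak_voxel(img, "min")
    ve <- virtual_electrode(ep, model, peak$position)
    tfs <- time_frequency_spectrogram(
      ve, control_window = cfg$tfs$control_window)
    f <- file.path(out_dir, "tfs.tsv")
    write_tfs(tfs, f)
    art <- c(art, f)
    res$image <- img
    res$tfs <- tfs
    res$peak <- peak
  } else {
    stop("unknown run kind: ", cfg$kind)
  }
  log <- list(package_version = as.character(utils::packageVersion("opmsim")),
              config_hash = cfg_hash, seed = cfg$seed, kind = cfg$kind,
              artifacts = basename(art))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  res$artifacts <- art
  res$out_dir <- out_dir
  res$config_hash <- cfg_hash
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abind_trials <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
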