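# Sensor-array geometry: triaxial helmet construction and serialisation.

#' Construct a sensor array from channel geometry
#'
#' A sensor array describes the 3 N channels of N triaxial OPM sensors: each
#' sensor contributes three channels with a shared position and mutually
#' orthonormal sensitive axes. Stored as a data frame with one row per
#' channel plus frame metadata.
#'
#' @param channels Data frame with columns `sensor_id`, `axis_label`
#'   (one of "X","Y","Z"), `pos_x`,`pos_y`,`pos_z` (metres) and
#'   `ori_x`,`ori_y`,`ori_z` (unit sensitive-axis direction).
#' @param frame_name Text label for the coordinate frame.
#' @param helmet_origin 3-vector, metres; centre of the helmet sphere.
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(channels, frame_name = "head",
                         helmet_origin = c(0, 0, 0)) {
  req <- c("sensor_id", "axis_label", "pos_x", "pos_y", "pos_z",
           "ori_x", "ori_y", "ori_z")
  if (!all(req %in% names(channels)))
    stop("channel table must have columns: ", paste(req, collapse = ", "))
  channels <- as.data.frame(channels)[, req]
  channels$sensor_id <- as.integer(channels$sensor_id)
  ori <- as.matrix(channels[, c("ori_x", "ori_y", "ori_z")])
  nrm <- sqrt(rowSums(ori^2))
  if (any(abs(nrm - 1) > 1e-10))
    stop("channel orientations must be unit vectors")
  per <- table(channels$sensor_id)
  if (any(per != 3L))
    stop("every sensor_id must have exactly 3 channels")
  # orthonormality of each triad
  for (sid in unique(channels$sensor_id)) {
    O <- ori[channels$sensor_id == sid, , drop = FALSE]
    G <- O %*% t(O)
    if (max(abs(G - diag(3))) > 1e-8)
      stop("sensor ", sid, ": channel axes are not orthonormal")
  }
  structure(list(channels = channels,
                 frame_name = frame_name,
                 helmet_origin = as.numeric(helmet_origin)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%d triaxial sensors), frame '%s'\n",
              nrow(x$channels), length(unique(x$channels$sensor_id)),
              x$frame_name))
  invisible(x)
}

n_channels <- function(array) nrow(array$channels)

channel_positions <- function(array)
  as.matrix(array$channels[, c("pos_x", "pos_y", "pos_z")])

channel_orientations <- function(array)
  as.matrix(array$channels[, c("ori_x", "ori_y", "ori_z")])

sensor_ids <- function(array) unique(array$channels$sensor_id)

# Rows (channel indices) of one sensor's triad, in X, Y, Z axis order.
triad_rows <- function(array, sid) which(array$channels$sensor_id == sid)

#' Build a synthetic triaxial OPM helmet
#'
#' Places `n_sensors` triaxial sensors quasi-uniformly (Fibonacci lattice) on
#' a spherical cap of radius `head_radius + standoff` centred on the origin,
#' covering polar angles up to `cap_angle`. Each sensor's Z axis points
#' radially outward and its X/Y axes span the tangential plane. The lattice
#' is deterministic; `seed` only sets a global azimuthal rotation so that
#' differently seeded helmets are rotated copies of the same lattice.
#'
#' @param n_sensors Number of triaxial sensors (>= 4; 64 in the reference
#'   array, giving 192 channels).
#' @param head_radius Modelled head (conductor) radius, metres.
#' @param standoff Scalp-to-cell distance, metres.
#' @param seed Integer seed (azimuthal registration of the lattice).
#' @param cap_angle Maximum polar angle of the cap, radians (default 2.1,
#'   i.e. the helmet wraps below the equator as a real helmet does).
#' @return A [sensor_array()] with `3 * n_sensors` channels.
#' @export
build_synthetic_helmet <- function(n_sensors = 64, head_radius = 0.09,
                                   standoff = 0.015, seed = 1,
                                   cap_angle = 2.1) {
  if (!is_number(n_sensors) || n_sensors < 4)
    stop("invalid parameter: n_sensors must be >= 4")
  stopifnot_number(head_radius, "head_radius", positive = TRUE)
  stopifnot_number(standoff, "standoff", positive = TRUE)
  if (!is_number(cap_angle) || cap_angle <= 0 || cap_angle > pi)
    stop("invalid parameter: cap_angle must be in (0, pi]")
  R <- head_radius + standoff
  n <- as.integer(n_sensors)
  golden <- pi * (3 - sqrt(5))
  phi0 <- (derive_seed(seed, 1L) %% 360L) * pi / 180
  k <- seq_len(n) - 0.5
  # uniform in cos(theta) over the cap => equal-area placement
  cth <- 1 - (k / n) * (1 - cos(cap_angle))
  th <- acos(cth)
  ph <- phi0 + k * golden
  pos <- R * cbind(sin(th) * cos(ph), sin(th) * sin(ph), unname(cth))
  dimnames(pos) <- NULL
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    r <- unitv(pos[s, ])
    tb <- tangential_basis(r)
    ori <- unname(rbind(tb[1, ], tb[2, ], r))
    rows[[s]] <- data.frame(sensor_id = s,
                            axis_label = c("X", "Y", "Z"),
                            pos_x = pos[s, 1], pos_y = pos[s, 2],
                            pos_z = pos[s, 3],
                            ori_x = ori[, 1], ori_y = ori[, 2],
                            ori_z = ori[, 3])
  }
  sensor_array(do.call(rbind, rows), frame_name = "head",
               helmet_origin = c(0, 0, 0))
}

#' Write / read a sensor array as a TSV channel table
#'
#' The channel table is written with SI units (metres; unit orientation
#' vectors) plus a small JSON sidecar carrying the frame name and helmet
#' origin, so the array round-trips losslessly.
#'
#' @param array A [sensor_array()].
#' @param path Path of the TSV file; the sidecar is written as
#'   `<path>.json`.
#' @return `write_sensor_array` returns `path` invisibly;
#'   `read_sensor_array` returns a [sensor_array()].
#' @export
write_sensor_array <- function(array, path) {
  df <- array$channels
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "sensor_id"
  df[num] <- lapply(df[num], function(x) format(x, digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(frame_name = array$frame_name,
                            helmet_origin = array$helmet_origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sensor-array sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sensor_id = "integer",
                                         axis_label = "character"))
  sensor_array(df, frame_name = meta$frame_name,
               helmet_origin = meta$helmet_origin)
}
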