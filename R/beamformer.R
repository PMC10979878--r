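# Scalar LCMV beamforming: regularised covariance, power-maximising
# orientation in the tangential plane, unit-gain weights, pseudo-T /
# pseudo-Z volumetric images, virtual electrodes, and run-comparison
# metrics.

#' Estimate a band-limited, regularised data covariance
#'
#' Band-passes every trial (zero phase), concatenates all trials, computes
#' the sample covariance, and regularises it by adding
#' `reg_fraction * lambda_max` to the diagonal (1% of the largest
#' eigenvalue of the unregularised matrix by default).
#'
#' @param ep An [opm_epochs()] object.
#' @param band Length-2 Hz interval; `NULL` if the epochs are already
#'   band-limited.
#' @param reg_fraction Diagonal loading as a fraction of the maximum
#'   eigenvalue (default 0.01).
#' @return Object of class `beamformer_model` with `covariance`,
#'   `covariance_reg`, `lambda_max`, `reg_fraction`, `band`, `window`.
#' @export
compute_covariance <- function(ep, band = NULL, reg_fraction = 0.01) {
  nch <- dim(ep$data)[2]
  ntot <- dim(ep$data)[1] * dim(ep$data)[3]
  if (ntot <= nch)
    stop("need more total samples than channels for covariance estimation")
  epf <- filter_epochs(ep, band)
  X <- matrix(aperm(epf$data, c(2, 3, 1)), nrow = nch)  # ch x (samples*trials)
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / (ncol(X) - 1)
  lmax <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (reg_fraction == 0 && ntot < 2 * nch)
    warning("covariance may be rank deficient with reg_fraction = 0")
  structure(list(covariance = C,
                 covariance_reg = C + reg_fraction * lmax * diag(nch),
                 lambda_max = lmax, reg_fraction = reg_fraction,
                 band = if (is.null(band)) ep$band else band,
                 window = ep$window,
                 weights = NULL, orientations = NULL, grid = NULL),
            class = "beamformer_model")
}

#' Compute LCMV weights with orientation optimisation
#'
#' For every voxel the source orientation is chosen in the tangential plane
#' to maximise beamformer output power (the generalised-eigenvalue solution
#' over the two-orientation lead-field pair: the minimising eigenvector of
#' `L' C^-1 L`), then the scalar unit-gain weight
#' `w = C^-1 l / (l' C^-1 l)` is formed.
#'
#' @param model A [compute_covariance()] model.
#' @param leadfields A [build_lead_fields()] object.
#' @param grid The [make_source_grid()] the lead fields were built on
#'   (defaults to `leadfields$grid`).
#' @return The model with `weights` (voxels x channels), `orientations`
#'   (voxels x 3) and `grid` filled in.
#' @export
lcmv_weights <- function(model, leadfields, grid = leadfields$grid) {
  Ci <- tryCatch(chol2inv(chol(model$covariance_reg)),
                 error = function(e)
                   stop("linear-algebra error: regularised covariance is ",
                        "numerically singular"))
  L <- leadfields$L
  nv <- dim(L)[3]
  nch <- dim(L)[1]
  W <- matrix(0, nv, nch)
  orient <- matrix(0, nv, 3)
  Lm <- matrix(L, nrow = nch)              # ch x (2 nv)
  CiL <- Ci %*% Lm
  for (v in seq_len(nv)) {
    cols <- (2 * v - 1):(2 * v)
    A <- crossprod(Lm[, cols], CiL[, cols])          # 2x2, l' Ci l
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    o <- eg$vectors[, 2]                             # smallest eigenvalue
    l <- Lm[, cols] %*% o
    Cil <- CiL[, cols] %*% o
    denom <- sum(l * Cil)
    W[v, ] <- Cil / denom
    orient[v, ] <- o[1] * leadfields$tangentials[v, 1, ] +
      o[2] * leadfields$tangentials[v, 2, ]
  }
  model$weights <- W
  model$orientations <- orient
  model$grid <- grid
  model$leadfields <- leadfields
  model
}

stat_image <- function(values, statistic, grid, band = NULL,
                       active_window = NULL, control_window = NULL,
                       latency = NULL) {
  structure(list(values = values, statistic = statistic, grid = grid,
                 band = band, active_window = active_window,
                 control_window = control_window, latency = latency),
            class = "stat_image")
}

#' @export
print.stat_image <- function(x, ...) {
  cat(sprintf("<stat_image> %s over %d voxels, range [%.3g, %.3g]\n",
              x$statistic, length(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Peak voxel of a statistical image
#'
#' @param image A `stat_image`.
#' @param extremum "max" (ERS / evoked) or "min" (ERD).
#' @return List with `index`, `position` (metres) and `value`.
#' @export
peak_voxel <- function(image, extremum = c("max", "min")) {
  extremum <- match.arg(extremum)
  i <- if (extremum == "max") which.max(image$values) else
    which.min(image$values)
  list(index = i, position = image$grid$positions[i, ],
       value = image$values[i])
}

# Concatenate the samples of a window across trials: channels x (ns * nt).
window_samples <- function(ep, window) {
  t <- epoch_times(ep)
  sel <- which(t >= window[1] & t < window[2])
  if (length(sel) == 0) stop("window contains no samples")
  nch <- dim(ep$data)[2]
  matrix(aperm(ep$data[, , sel, drop = FALSE], c(2, 3, 1)), nrow = nch)
}

check_window_inside <- function(window, ep) {
  if (window[1] < ep$window[1] - 1e-9 || window[2] > ep$window[2] + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] lies outside the epoch window")
}

#' Pseudo-T statistical image
#'
#' Per voxel, `pseudo_T = (P_active - P_control) / (P_active + P_control)`
#' where `P` is the beamformed power summed over trials in the window.
#' Bounded in [-1, 1] and antisymmetric under swapping the windows. Voxels
#' with zero total power are marked `NA`.
#'
#' @param ep Band-limited [opm_epochs()] (same band as the model).
#' @param model A [lcmv_weights()] model.
#' @param active,control Length-2 second intervals inside the epoch
#'   window (disjoint windows in normal use; identical windows give an
#'   exactly zero image, which is useful as a null check).
#' @return A `stat_image` with statistic `"pseudo_t"`.
#' @export
pseudo_t_image <- function(ep, model, active, control) {
  if (is.null(model$weights)) stop("model has no weights; run lcmv_weights")
  check_window_inside(active, ep)
  check_window_inside(control, ep)
  Pa <- rowSums((model$weights %*% window_samples(ep, active))^2)
  Pc <- rowSums((model$weights %*% window_samples(ep, control))^2)
  tot <- Pa + Pc
  vals <- ifelse(tot > 0, (Pa - Pc) / tot, NA_real_)
  stat_image(vals, "pseudo_t", model$grid, band = model$band,
             active_window = active, control_window = control)
}

#' Pseudo-Z statistical image
#'
#' Per voxel, the magnitude of the trial-averaged beamformed amplitude at
#' `latency`, normalised by the projected sensor-noise standard deviation
#' under a scaled-identity noise model
#' (`sigma^2 = reg_fraction * lambda_max`).
#'
#' @param ep An [opm_epochs()] object.
#' @param model A [lcmv_weights()] model.
#' @param latency Seconds (inside the epoch window).
#' @return A `stat_image` with statistic `"pseudo_z"`.
#' @export
pseudo_z_image <- function(ep, model, latency) {
  if (is.null(model$weights)) stop("model has no weights; run lcmv_weights")
  t <- epoch_times(ep)
  if (latency < ep$window[1] || latency >= ep$window[2])
    stop("bounds error: latency outside the epoch window")
  i <- which.min(abs(t - latency))
  slice <- matrix(ep$data[, , i], nrow = n_trials(ep))  # trials x channels
  evoked <- colMeans(slice)
  a <- as.numeric(model$weights %*% evoked)
  sigma2 <- model$reg_fraction * model$lambda_max
  z <- abs(a) / sqrt(sigma2 * rowSums(model$weights^2))
  stat_image(z, "pseudo_z", model$grid, band = model$band,
             latency = latency)
}

#' Virtual electrode: beamformed timecourse at a voxel
#'
#' Projects every trial through the voxel's unit-gain spatial filter. The
#' sign convention is fixed by the unit-gain constraint (`w'l = 1`), so a
#' positive source moment along the optimised orientation maps to positive
#' output.
#'
#' @param ep An [opm_epochs()] object.
#' @param model A [lcmv_weights()] model.
#' @param voxel 3-vector position on the model grid (or a voxel index).
#' @return Object of class `virtual_electrode`: `timecourse` (trials x
#'   samples), `average`, `times`, `voxel`, `band`.
#' @export
virtual_electrode <- function(ep, model, voxel) {
  if (is.null(model$weights)) stop("model has no weights; run lcmv_weights")
  i <- if (length(voxel) == 1) as.integer(voxel) else
    grid_voxel_index(model$grid, voxel)
  if (i < 1 || i > nrow(model$weights))
    stop("lookup error: voxel is not on the model grid")
  w <- model$weights[i, ]
  nt <- n_trials(ep)
  ns <- dim(ep$data)[3]
  tc <- matrix(0, nt, ns)
  for (tr in seq_len(nt)) tc[tr, ] <- w %*% ep$data[tr, , ]
  structure(list(timecourse = tc, average = colMeans(tc),
                 times = epoch_times(ep),
                 voxel = model$grid$positions[i, ], voxel_index = i,
                 band = model$band, sample_rate = ep$sample_rate),
            class = "virtual_electrode")
}

ve_average <- function(x) {
  if (inherits(x, "virtual_electrode")) x$average else as.numeric(x)
}

#' Compare two localisations / timecourses
#'
#' Reports the Euclidean distance (mm) between the extremum voxels of two
#' statistical images on the same grid (maximum for ERS/evoked, minimum
#' for ERD) and the Pearson correlation between two (trial-averaged)
#' timecourses.
#'
#' @param imageA,imageB `stat_image`s sharing a grid.
#' @param veA,veB [virtual_electrode()] objects (their `average` is used)
#'   or plain numeric timecourses of equal length.
#' @param extremum "max" or "min".
#' @return List with `peak_distance_mm` and `correlation`.
#' @export
compare_localisations <- function(imageA, imageB, veA, veB,
                                  extremum = c("max", "min")) {
  if (!isTRUE(all.equal(imageA$grid$positions, imageB$grid$positions)))
    stop("incompatible images: grids differ")
  extremum <- match.arg(extremum)
  pa <- peak_voxel(imageA, extremum)$position
  pb <- peak_voxel(imageB, extremum)$position
  ta <- ve_average(veA)
  tb <- ve_average(veB)
  if (length(ta) != length(tb))
    stop("incompatible timecourses: lengths differ")
  list(peak_distance_mm = 1000 * vnorm(pa - pb),
       correlation = stats::cor(ta, tb))
}
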