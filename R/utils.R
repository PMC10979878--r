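# Small numeric helpers shared across modules.

MU0_4PI <- 1e-7  # mu0 / (4 pi), T m / A

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

#' Orthonormal tangential basis at a point
#'
#' Returns two orthonormal vectors perpendicular to the radial direction
#' `radial`, built by Gram-Schmidt from a fixed reference axis (z by
#' default). When `radial` is within ~1 degree of the reference axis the
#' fallback axis (x) is used, so the basis is defined everywhere including
#' the pole.
#'
#' @param radial Unit (or unnormalised) radial 3-vector.
#' @param reference Reference axis seeding the Gram-Schmidt step.
#' @param fallback Axis used when `radial` is parallel to `reference`.
#' @return 2 x 3 matrix; rows are the two tangential unit vectors.
#' @export
tangential_basis <- function(radial, reference = c(0, 0, 1),
                             fallback = c(1, 0, 0)) {
  r <- unitv(radial)
  ref <- reference
  if (abs(sum(ref * r)) > 0.9998) ref <- fallback
  t1 <- unitv(ref - sum(ref * r) * r)
  t2 <- cross3(r, t1)
  rbind(t1, t2, deparse.level = 0)
}

# First-order (single-pole) low-pass filter with state initialised at the
# first sample, so constant inputs pass through unchanged from t = 0.
lowpass1 <- function(x, fc, fs) {
  if (!is.finite(fc) || fc <= 0) return(x)
  alpha <- 1 - exp(-2 * pi * fc / fs)
  stats::filter(x * alpha, 1 - alpha, method = "recursive",
                init = x[1L])[seq_along(x)]
}

# Derive a stream-specific 32-bit seed from a base seed (keeps seeds < 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %%
               2147483647)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
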