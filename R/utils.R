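# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("fog_format_error", "fog_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("fog_config_error", "fog_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("fog_data_error", "fog_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_config(sprintf("'%s' must be a single finite number in [%s, %s]",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

# Draws a uniform random rotation matrix (Haar measure) from the current RNG
# state via QR decomposition of a Gaussian matrix with sign correction.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  d <- sign(diag(qr.R(qr_m)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# A random rigid motion (rotation + translation of the given scale, in A).
random_rigid_transform <- function(translation_scale = 10) {
  list(rotation = random_rotation(),
       translation = stats::rnorm(3L, sd = translation_scale))
}

#' Apply a rigid transform to a coordinate matrix
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param transform list with elements `rotation` (3 x 3 matrix with
#'   determinant +1) and `translation` (length-3 vector).
#' @return the transformed n x 3 coordinate matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3L, byrow = TRUE)
}
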