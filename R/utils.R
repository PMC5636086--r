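# Internal helpers shared across modules: condition classes, coordinate
# layout conversions, rigid-body bases, and small geometry utilities.

stop_usage <- function(...) {
  stop(structure(class = c("ngeni_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("ngeni_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numerical <- function(...) {
  stop(structure(class = c("ngeni_numerical_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Degree-of-freedom layout: residue i occupies vector entries 3(i-1)+1..3i.
vec_to_coords <- function(v, n) {
  t(matrix(v, nrow = 3L, ncol = n))
}

coords_to_vec <- function(m) {
  as.vector(t(m))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the unit direction of `axis`.
#'
#' @param axis length-3 direction vector (need not be normalized).
#' @param angle rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Orthonormal basis of the 6 rigid-body directions (3 translations,
# 3 infinitesimal rotations about the centroid) for a given conformation.
# Returns a 3n x 6 matrix with orthonormal columns.
rigid_body_basis <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  # rotation about axis e_a: delta_i = e_a x (x_i - ctr)
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(xc, 1, function(x) c(axes[2, a] * x[3] - axes[3, a] * x[2],
                                        axes[3, a] * x[1] - axes[1, a] * x[3],
                                        axes[1, a] * x[2] - axes[2, a] * x[1])))
    B[, 3 + a] <- coords_to_vec(rot)
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

# Deterministic sign convention for eigenvectors: the largest-magnitude
# component of every column is made positive.
fix_mode_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

`%||%` <- function(a, b) if (is.null(a)) b else a
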