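# Elastic network construction, coarse-grained Hessian assembly, and
# normal mode extraction (dense and sparse shift-invert eigensolvers).

#' Build an elastic network from a cutoff contact rule
#'
#' Connects residue pairs by identical Hookean springs. Two contact rules
#' are supported:
#' \describe{
#'   \item{`"current"`}{spring (i,j) exists iff the pair is within `cutoff`
#'     in the given conformation. Used for the normal-mode network, which
#'     is recomputed on every intermediate.}
#'   \item{`"union"`}{spring (i,j) exists iff the pair is within `cutoff`
#'     in *either* end-point conformation of a pair. Used for the
#'     distance-interpolation cost network, so that every spring has a
#'     defined start and end distance; held fixed along the pathway.}
#' }
#'
#' @param x a [cg_structure] (rule `"current"`) or a `structure_pair`
#'   (rule `"union"`).
#' @param cutoff contact cutoff in Angstrom (default 12, the common
#'   Calpha-network choice).
#' @param rule contact rule, see above.
#' @return object of class `elastic_network`: fields `edges` (E x 2 matrix
#'   of 1-based index pairs, i < j), `n`, `cutoff`, `rule`, `density`
#'   (fraction of nonzero off-diagonal entries of the linking matrix).
#' @export
build_network <- function(x, cutoff = 12, rule = c("current", "union")) {
  rule <- match.arg(rule)
  if (cutoff <= 0) stop_usage("cutoff must be positive")
  if (rule == "current") {
    stopifnot(inherits(x, "cg_structure"))
    n <- n_residues(x)
    close_mat <- as.matrix(stats::dist(x$coords)) <= cutoff
  } else {
    stopifnot(inherits(x, "structure_pair"))
    n <- n_residues(x$start)
    close_mat <- (as.matrix(stats::dist(x$start$coords)) <= cutoff) |
                 (as.matrix(stats::dist(x$end$coords)) <= cutoff)
  }
  idx <- which(close_mat & upper.tri(close_mat), arr.ind = TRUE)
  edges <- unname(cbind(idx[, 1], idx[, 2]))
  net <- structure(list(edges = edges, n = n, cutoff = cutoff, rule = rule,
                        density = 2 * nrow(edges) / (n * (n - 1))),
                   class = "elastic_network")
  comp <- network_components(net)
  if (comp$no > 1L)
    stop_data("elastic network is disconnected at cutoff ", cutoff,
              " A: component sizes ", paste(comp$csize, collapse = ", "))
  net
}

network_components <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, net$n - igraph::vcount(g)))
  igraph::components(g)
}

#' Linking matrix of an elastic network
#'
#' @param net an `elastic_network`.
#' @return sparse symmetric n x n binary matrix (zero diagonal).
#' @export
linking_matrix <- function(net) {
  Matrix::sparseMatrix(i = c(net$edges[, 1], net$edges[, 2]),
                       j = c(net$edges[, 2], net$edges[, 1]),
                       x = 1, dims = c(net$n, net$n))
}

#' Export network edges as a coordinate-list text file
#'
#' Writes one `i j` pair (1-based, i < j) per line, for inspection of the
#' linking-matrix topology.
#' @param net an `elastic_network`.
#' @param file output path.
#' @export
write_network <- function(net, file) {
  utils::write.table(net$edges, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network: n = %d, %d springs, cutoff %.1f A, rule '%s', density %.3f>\n",
              x$n, nrow(x$edges), x$cutoff, x$rule, x$density))
  invisible(x)
}

# Assemble 3x3-block triplets common to the Hessian and the quadratic-cost
# matrix: for each edge, a per-edge 3x3 block B_e = w1_e*I + w2_e * d dT
# placed as +B on (i,i),(j,j) and -B on (i,j),(j,i).
assemble_block_matrix <- function(n, ii, jj, D, w1, w2) {
  E <- length(ii)
  ti <- tj <- integer(36L * E)
  tx <- numeric(36L * E)
  pos <- 0L
  for (a in 1:3) for (b in 1:3) {
    v <- w2 * D[, a] * D[, b]
    if (a == b) v <- v + w1
    ra <- 3L * (ii - 1L) + a; rb <- 3L * (ii - 1L) + b
    sa <- 3L * (jj - 1L) + a; sb <- 3L * (jj - 1L) + b
    sel <- pos + seq_len(4L * E)
    ti[sel] <- c(ra, sa, ra, sa)
    tj[sel] <- c(rb, sb, sb, rb)
    tx[sel] <- c(v, v, -v, -v)
    pos <- pos + 4L * E
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(3L * n, 3L * n))
}

#' Assemble the coarse-grained elastic-network Hessian
#'
#' Standard anisotropic-network stiffness matrix with uniform spring
#' constant 1: each spring (i,j) contributes the 3x3 super-element
#' \eqn{d d^T / \|d\|^2} with \eqn{d = x_i - x_j}, negated on off-diagonal
#' blocks. The result is symmetric positive semidefinite with exactly six
#' zero (rigid-body) eigenvalues for a connected network.
#'
#' @param structure a [cg_structure].
#' @param network an `elastic_network` built on (or valid for) `structure`.
#' @return sparse symmetric 3n x 3n matrix.
#' @export
build_hessian <- function(structure, network) {
  n <- n_residues(structure)
  if (network$n != n)
    stop_data("network size (", network$n, ") does not match structure (", n, ")")
  ii <- network$edges[, 1]; jj <- network$edges[, 2]
  D <- structure$coords[ii, , drop = FALSE] - structure$coords[jj, , drop = FALSE]
  r2 <- rowSums(D * D)
  if (any(r2 < 1e-12))
    stop_data("coincident connected residues (distance < 1e-6 A)")
  assemble_block_matrix(n, ii, jj, D, w1 = numeric(length(ii)), w2 = 1 / r2)
}

#' Extract the lowest non-rigid-body normal modes
#'
#' Computes the `m` lowest eigenpairs of the elastic-network Hessian after
#' excluding the six zero-eigenvalue rigid-body modes. A sparse
#' shift-invert Lanczos solver (ARPACK through \pkg{igraph}, with a sparse
#' Cholesky factorization) is used for large systems at small `m`; a dense
#' symmetric eigendecomposition is the fallback for small problems or
#' near-full mode counts. The number of eigenvalues below the rigid-body
#' threshold (1e-8 relative to the spectral scale) is hard-checked to be
#' exactly six. Eigenvector signs are fixed deterministically (largest-
#' magnitude component positive).
#'
#' @param hessian 3n x 3n stiffness matrix from [build_hessian].
#' @param m number of non-rigid modes requested, 1 <= m <= 3n - 6.
#' @param solver `"auto"`, `"dense"` or `"sparse"`.
#' @return object of class `mode_basis`: `modes` (3n x m, orthonormal
#'   columns), `eigenvalues` (ascending), `m`, `n`, and `ops` (count of
#'   dominant floating-point operations spent in the solve).
#' @export
compute_modes <- function(hessian, m, solver = c("auto", "dense", "sparse")) {
  solver <- match.arg(solver)
  N <- nrow(hessian)
  n <- N / 3L
  if (m < 1L || m > N - 6L)
    stop_usage("m must be in [1, 3n-6] = [1, ", N - 6L, "], got ", m)
  if (solver == "auto")
    solver <- if (N <= 600L || m + 6L > (N - 6L) / 3L) "dense" else "sparse"
  if (solver == "dense") res <- modes_dense(hessian, m)
  else res <- modes_sparse(hessian, m)
  res$modes <- fix_mode_signs(res$modes)
  structure(c(res, list(m = m, n = n)), class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("<mode_basis: %d modes of a %d-residue network, eigenvalues %.3g .. %.3g>\n",
              x$m, x$n, x$eigenvalues[1], x$eigenvalues[x$m]))
  invisible(x)
}

rigid_tol <- 1e-8

modes_dense <- function(hessian, m) {
  H <- as.matrix(hessian)
  e <- eigen(H, symmetric = TRUE)
  vals <- rev(e$values)                       # ascending
  vecs <- e$vectors[, rev(seq_len(ncol(H))), drop = FALSE]
  scale <- max(abs(vals))
  nzero <- sum(vals < rigid_tol * scale)
  if (nzero != 6L)
    stop_numerical("expected exactly 6 rigid-body modes, found ", nzero,
                   " eigenvalues below threshold")
  sel <- 7L:(6L + m)
  list(modes = vecs[, sel, drop = FALSE], eigenvalues = vals[sel],
       ops = as.numeric(nrow(H))^3)
}

# Shift-invert Lanczos: factor (H + sigma I) once (sparse Cholesky), then
# find the largest eigenvalues of its inverse, i.e. the smallest of H.
modes_sparse <- function(hessian, m) {
  N <- nrow(hessian)
  H <- methods::as(Matrix::forceSymmetric(hessian), "CsparseMatrix")
  scale <- max(Matrix::rowSums(abs(H)))       # Gershgorin bound
  sigma <- 1e-6 * scale
  ch <- Matrix::Cholesky(H + sigma * Matrix::Diagonal(N), LDL = FALSE)
  nnz_factor <- Matrix::nnzero(methods::as(ch, "CsparseMatrix"))
  ncall <- 0L
  fn <- function(x, extra) {
    ncall <<- ncall + 1L
    as.vector(Matrix::solve(ch, x, system = "A"))
  }
  nev <- m + 6L
  ncv <- min(N, max(2L * nev + 1L, 40L))
  ar <- tryCatch(
    igraph::arpack(fn, sym = TRUE,
                   options = list(n = N, nev = nev, ncv = ncv,
                                  which = "LA", maxiter = 5000)),
    error = function(e) stop_numerical("sparse eigensolver failed after ",
                                       ncall, " operator applications: ",
                                       conditionMessage(e)))
  vals <- 1 / ar$values - sigma
  ord <- order(vals)
  vals <- vals[ord]
  vecs <- ar$vectors[, ord, drop = FALSE]
  nzero <- sum(vals < rigid_tol * scale)
  if (nzero != 6L)
    stop_numerical("expected exactly 6 rigid-body modes, found ", nzero)
  sel <- 7L:(6L + m)
  list(modes = vecs[, sel, drop = FALSE],
       eigenvalues = pmax(vals[sel], 0),
       ops = ncall * (2 * nnz_factor + Matrix::nnzero(H)))
}
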