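# Pathway-quality metrics: inter-pathway average RMSD, convergence against
# experimental resolution, mode weighting-constant profiles and their
# correlation, and Calpha pseudo-bond geometry.

#' Compare two pathways step by step
#'
#' Superposed Calpha RMSD between corresponding intermediate conformations
#' at every iteration step, and its average over all steps. If one pathway
#' is longer by exactly one conformation (a trailing appended end point),
#' the longer one is truncated.
#'
#' @param p1,p2 `transition_pathway` objects over the same residues.
#' @return object of class `pathway_comparison`: `per_step_rmsd`,
#'   `average_rmsd`.
#' @export
compare_pathways <- function(p1, p2) {
  c1 <- p1$conformations; c2 <- p2$conformations
  if (abs(length(c1) - length(c2)) == 1L) {
    L <- min(length(c1), length(c2))
    c1 <- c1[seq_len(L)]; c2 <- c2[seq_len(L)]
  }
  if (length(c1) != length(c2))
    stop_data("pathways have incompatible step counts (", length(c1), " vs ",
              length(c2), ")")
  if (n_residues(c1[[1]]) != n_residues(c2[[1]]))
    stop_data("pathways have different residue counts")
  per <- vapply(seq_along(c1), function(k) rmsd_ca(c1[[k]], c2[[k]]),
                numeric(1))
  structure(list(per_step_rmsd = per, average_rmsd = mean(per)),
            class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat(sprintf("<pathway_comparison: %d steps, average RMSD %.4g A, max %.4g A>\n",
              length(x$per_step_rmsd), x$average_rmsd, max(x$per_step_rmsd)))
  invisible(x)
}

#' Convergence check against experimental resolution
#'
#' A pathway satisfies the convergence condition when the RMSD between the
#' last computed conformation (the pathway terminus) and the given end
#' structure is below the pair's experimental resolution.
#'
#' @param pathway a `transition_pathway`.
#' @param end end-point [cg_structure] (defaults to the pathway's own).
#' @param resolution resolution threshold in Angstrom.
#' @return list with `pass` (logical) and `residual` (Angstrom).
#' @export
convergence_check <- function(pathway, end = pathway$pair$end, resolution) {
  if (resolution <= 0) stop_usage("resolution must be positive")
  L <- length(pathway$conformations)
  residual <- rmsd_ca(pathway$conformations[[L]], end)
  list(pass = residual < resolution, residual = residual)
}

#' Per-mode contribution profile
#'
#' Mean absolute weighting constant of every mode over all iteration
#' steps. Absolute values are used so the profile is invariant under the
#' sign ambiguity of eigenvectors.
#'
#' @param pathway a `transition_pathway` produced by [run_ngeni].
#' @return object of class `mode_profile`: `mean_abs_weights` (length m),
#'   `m`.
#' @export
mode_profile <- function(pathway) {
  W <- pathway$weights
  if (is.null(W)) stop_data("pathway carries no mode weights")
  W <- abs(as.matrix(W))
  structure(list(mean_abs_weights = colMeans(W), m = ncol(W)),
            class = "mode_profile")
}

#' Correlation between two mode-contribution profiles
#'
#' Pearson correlation of the first `k` per-mode mean absolute weights.
#'
#' @param a,b `mode_profile` objects covering at least `k` modes.
#' @param k number of leading modes to compare.
#' @return correlation coefficient.
#' @export
profile_correlation <- function(a, b, k = min(a$m, b$m)) {
  if (a$m < k || b$m < k)
    stop_usage("profiles cover fewer than k = ", k, " modes")
  va <- a$mean_abs_weights[seq_len(k)]
  vb <- b$mean_abs_weights[seq_len(k)]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_data("undefined correlation: zero variance in a profile")
  stats::cor(va, vb)
}

#' Calpha pseudo-bond geometry along a pathway
#'
#' For every conformation: the mean consecutive Calpha-Calpha pseudo-bond
#' length and the mean pseudo-bond angle over residue triplets
#' (i-1, i, i+1). Only pairs/triplets within one chain and with unit
#' residue-number increments contribute (chain breaks are excluded). Also
#' reports the maximum deviation of the per-step mean bond length from the
#' average of the two end-point means, the geometric-realism figure used
#' to validate coarse-grained intermediates.
#'
#' @param pathway a `transition_pathway`.
#' @return list with `per_step` (data.frame: step, mean_bond_length,
#'   mean_bond_angle degrees) and `max_bond_dev` (Angstrom).
#' @export
bond_geometry <- function(pathway) {
  confs <- pathway$conformations
  rid <- confs[[1]]$residue_ids
  n <- nrow(rid)
  if (n < 3L) stop_data("need at least 3 residues for bond geometry")
  bonded <- which(rid$chain[-n] == rid$chain[-1] &
                  rid$resno[-1] - rid$resno[-n] == 1L)
  if (!length(bonded)) stop_data("no consecutive residue pairs found")
  triplet <- intersect(bonded, bonded - 1L)  # i with bonds (i,i+1),(i+1,i+2)
  stats_one <- function(coords) {
    d <- coords[bonded + 1L, , drop = FALSE] - coords[bonded, , drop = FALSE]
    bl <- sqrt(rowSums(d * d))
    ang <- NA_real_
    if (length(triplet)) {
      u <- coords[triplet, , drop = FALSE] - coords[triplet + 1L, , drop = FALSE]
      v <- coords[triplet + 2L, , drop = FALSE] - coords[triplet + 1L, , drop = FALSE]
      cosang <- rowSums(u * v) /
        sqrt(rowSums(u * u) * rowSums(v * v))
      ang <- mean(acos(pmin(1, pmax(-1, cosang)))) * 180 / pi
    }
    c(mean(bl), ang)
  }
  st <- t(vapply(confs, function(s) stats_one(s$coords), numeric(2)))
  per_step <- data.frame(step = seq_len(nrow(st)) - 1L,
                         mean_bond_length = st[, 1],
                         mean_bond_angle = st[, 2])
  end_mean <- mean(c(st[1, 1], st[nrow(st), 1]))
  list(per_step = per_step,
       max_bond_dev = max(abs(st[, 1] - end_mean)))
}

#' Per-step metrics as CSV
#'
#' Writes the pathway's per-step table (step, alpha, rmsd_prev,
#' rmsd_to_end, cost_exact, cost_quad, n_modes, ops) with a versioned
#' schema header comment.
#'
#' @param pathway a `transition_pathway`.
#' @param file output path.
#' @param weights if TRUE, append the weighting constants c_1..c_m as
#'   extra columns.
#' @export
write_metrics_csv <- function(pathway, file, weights = FALSE) {
  df <- pathway$per_step
  if (weights && !is.null(pathway$weights)) {
    W <- as.matrix(pathway$weights)
    colnames(W) <- paste0("c_", seq_len(ncol(W)))
    pad <- matrix(NA_real_, nrow(df), ncol(W),
                  dimnames = list(NULL, colnames(W)))
    pad[1L + seq_len(nrow(W)), ] <- W
    df <- cbind(df, pad)
  }
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(c("# ngeni per-step metrics, schema v1",
               sprintf("# method=%s modes=%s cutoff=%g",
                       pathway$method, paste(pathway$config$modes),
                       pathway$config$cutoff)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
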