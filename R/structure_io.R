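# Coarse-grained structure input/output: Calpha extraction from PDB files,
# residue correspondence between end-point structures, Kabsch superposition
# and RMSD, and multi-model PDB trajectory output.

#' Coarse-grained Calpha structure
#'
#' Container for an ordered set of Calpha positions with residue labels.
#' This is the coordinate representation on which the whole elastic-network
#' machinery operates: one bead per residue, coordinates in Angstrom.
#'
#' @param residue_ids data.frame with columns `chain`, `resno` (integer),
#'   `icode` (insertion code, `""` if absent) and `resname`.
#' @param coords numeric n x 3 matrix of Calpha positions (Angstrom).
#' @param label free-text provenance tag (PDB id or fixture name).
#' @return object of class `cg_structure`.
#' @export
cg_structure <- function(residue_ids, coords, label = "") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  if (!is.data.frame(residue_ids) ||
      !all(c("chain", "resno", "icode", "resname") %in% names(residue_ids)))
    stop_data("residue_ids must have columns chain, resno, icode, resname")
  n <- nrow(residue_ids)
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop_data("coords must be an n x 3 matrix matching residue_ids")
  if (n < 3L)
    stop_data("a coarse-grained structure needs at least 3 residues, got ", n)
  if (!all(is.finite(coords)))
    stop_data("non-finite coordinates in structure '", label, "'")
  keys <- residue_keys_df(residue_ids)
  if (anyDuplicated(keys))
    stop_data("duplicate residue identifiers in structure '", label, "'")
  structure(list(residue_ids = residue_ids, coords = coords,
                 label = as.character(label)),
            class = "cg_structure")
}

residue_keys_df <- function(residue_ids) {
  paste0(residue_ids$chain, "|", residue_ids$resno, residue_ids$icode)
}

#' Residue identity keys of a structure
#'
#' `chain|resno` + insertion-code keys, the identifiers used for residue
#' correspondence in [pair_structures].
#' @param s a [cg_structure].
#' @return character vector of length n.
#' @export
residue_keys <- function(s) residue_keys_df(s$residue_ids)

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure '%s': %d residues, chains %s>\n", x$label,
              nrow(x$coords), paste(unique(x$residue_ids$chain), collapse = ",")))
  invisible(x)
}

n_residues <- function(s) nrow(s$coords)

#' Read Calpha coordinates from a PDB file
#'
#' Parses a PDB file (via \code{bio3d::read.pdb}) and extracts one Calpha
#' bead per residue from standard-residue ATOM records, in chain-then-
#' residue-number order. Alternate locations are resolved to the highest
#' occupancy (ties: first encountered); residues without a CA record are
#' skipped with a warning.
#'
#' @param pdb_source path to a PDB file.
#' @param chains optional character vector of chain ids to keep (default:
#'   all chains).
#' @param model 1-based model index for multi-model files (default 1,
#'   i.e. the lowest model index).
#' @param label provenance label; defaults to the file base name.
#' @return a [cg_structure].
#' @export
read_calpha <- function(pdb_source, chains = NULL, model = 1L, label = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(pdb_source, multi = model > 1L, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop_data("cannot parse PDB '", pdb_source, "': ",
                                  conditionMessage(e)))
  at <- pdb$atom
  at$row <- seq_len(nrow(at))
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(at$chain))
    if (length(missing_ch))
      stop_data("chain(s) not present in '", pdb_source, "': ",
                paste(missing_ch, collapse = ","))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop_data("no protein ATOM records selected from '", pdb_source, "'")
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$key <- paste0(at$chain, "|", at$resno, at$icode)
  ca <- at[at$elety == "CA", , drop = FALSE]
  n_skipped <- length(setdiff(unique(at$key), unique(ca$key)))
  if (n_skipped > 0L)
    warning(n_skipped, " residue(s) without a CA record skipped in '",
            pdb_source, "'", call. = FALSE)
  if (nrow(ca) == 0L)
    stop_data("no Calpha atoms after selection in '", pdb_source, "'")
  # altloc resolution: highest occupancy per residue, first on ties
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), ca$key), function(idx) {
    idx[which.max(occ[idx])]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  ord <- order(ca$chain, ca$resno, ca$icode)
  ca <- ca[ord, , drop = FALSE]
  if (model > 1L) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model)
      stop_data("model ", model, " not present in '", pdb_source, "'")
    xyz <- pdb$xyz[model, bio3d::atom2xyz(ca$row)]
    coords <- matrix(xyz, ncol = 3L, byrow = TRUE)
  } else {
    coords <- as.matrix(ca[, c("x", "y", "z")])
  }
  cg_structure(
    residue_ids = data.frame(chain = ca$chain, resno = ca$resno,
                             icode = ca$icode, resname = ca$resid,
                             stringsAsFactors = FALSE),
    coords = unname(coords),
    label = label %||% sub("\\.pdb$", "", basename(pdb_source),
                           ignore.case = TRUE))
}

#' Pair two structures by residue identity
#'
#' Matches residues by (chain, residue number, insertion code). Residues
#' present in only one structure are dropped from both (with a message
#' reporting the count), yielding a one-to-one correspondence.
#'
#' @param a,b [cg_structure] objects for the start and end conformations.
#' @param resolution representative experimental resolution in Angstrom
#'   (conventionally the smaller of the two end-point resolutions); used by
#'   convergence checks. `NA` if unknown.
#' @return object of class `structure_pair` with fields `start`, `end`,
#'   `resolution`.
#' @export
pair_structures <- function(a, b, resolution = NA_real_) {
  ka <- residue_keys(a)
  kb <- residue_keys(b)
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stop_data("fewer than 3 residues in common (", length(common),
              "): cannot pair structures")
  dropped <- (length(ka) - length(common)) + (length(kb) - length(common))
  if (dropped > 0L)
    message(dropped, " residue(s) without a partner dropped during pairing")
  ia <- which(ka %in% common)
  sel_a <- cg_structure(a$residue_ids[ia, , drop = FALSE],
                        a$coords[ia, , drop = FALSE], a$label)
  ib <- match(residue_keys(sel_a), kb)
  sel_b <- cg_structure(b$residue_ids[ib, , drop = FALSE],
                        b$coords[ib, , drop = FALSE], b$label)
  if (!is.na(resolution) && resolution <= 0)
    stop_data("resolution must be positive")
  structure(list(start = sel_a, end = sel_b, resolution = resolution),
            class = "structure_pair")
}

#' @export
print.structure_pair <- function(x, ...) {
  cat(sprintf("<structure_pair %s -> %s: n = %d, resolution = %s A>\n",
              x$start$label, x$end$label, n_residues(x$start),
              format(x$resolution)))
  invisible(x)
}

#' Reverse a structure pair
#'
#' Swaps start and end conformations, for generating reverse transition
#' pathways.
#' @param pair a `structure_pair`.
#' @export
reverse_pair <- function(pair) {
  structure(list(start = pair$end, end = pair$start,
                 resolution = pair$resolution),
            class = "structure_pair")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' sum_i ||R m_i + t - t_i||^2 and the associated RMSD. The reflection
#' branch is corrected so the returned rotation always has det = +1.
#'
#' @param mobile,target [cg_structure] objects (or bare n x 3 matrices)
#'   with equal residue counts.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom). The superposed mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
superpose <- function(mobile, target) {
  A <- if (inherits(mobile, "cg_structure")) mobile$coords else as.matrix(mobile)
  B <- if (inherits(target, "cg_structure")) target$coords else as.matrix(target)
  if (!identical(dim(A), dim(B)))
    stop_data("superpose: dimension mismatch (", nrow(A), " vs ", nrow(B),
              " residues)")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- crossprod(Ac, Bc)          # 3x3 covariance
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.vector(cb - R %*% ca)
  res <- Ac %*% t(R) - Bc
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(res * res))))
}

#' Calpha RMSD after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(mobile, target) superpose(mobile, target)$rmsd

#' Apply a rigid transform to a structure
#' @keywords internal
transform_structure <- function(s, rotation, translation) {
  cg_structure(s$residue_ids,
               sweep(s$coords %*% t(rotation), 2, -translation),
               s$label)
}

#' Write a transition pathway as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformation, in pathway order. Each model
#' carries a REMARK line recording the iteration index and the
#' interpolation scale factor alpha. Calpha ATOM records keep the original
#' chain/residue identifiers, so each model can be read back with
#' [read_calpha].
#'
#' @param pathway a `transition_pathway` (see [run_ngeni]).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_pathway <- function(pathway, file) {
  stopifnot(inherits(pathway, "transition_pathway"))
  confs <- pathway$conformations
  if (length(confs) == 0L) stop_data("empty pathway")
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (k in seq_along(confs)) {
    s <- confs[[k]]
    alpha <- pathway$per_step$alpha[k]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK   6 NGENI ITERATION %d ALPHA %.6f",
                       k - 1L, alpha), con)
    rid <- s$residue_ids
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(rid)), substr(rid$resname, 1, 3), rid$chain, rid$resno,
      ifelse(rid$icode == "", " ", rid$icode),
      s$coords[, 1], s$coords[, 2], s$coords[, 3], 1, 0)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
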