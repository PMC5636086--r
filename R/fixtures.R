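# Deterministic synthetic two-conformation fixtures: two compact
# "domains" (serpentine bead blocks on a cubic lattice, consecutive beads
# exactly one bond length apart) joined by a short non-collinear neck of
# linker beads. Hinge, shear and twist motions move the second domain
# rigidly about/along the neck, emulating the domain-hinge phenomenology
# of real two-state proteins: internally stiff domains, a soft
# inter-domain degree of freedom, and a dense 3D contact map. Everything
# is testable without any external structure file.

#' Specify a synthetic two-conformation fixture
#'
#' @param kind one of `"hinge"`, `"shear"`, `"twist"`,
#'   `"random-perturb"`. Hinge rotates the second domain about an axis
#'   through the middle neck bead perpendicular to the inter-domain axis
#'   (a rigid sub-motion that preserves every pseudo-bond); twist rotates
#'   it about the inter-domain axis; shear slides the second domain
#'   laterally, with the displacement ramped across the neck beads so no
#'   single pseudo-bond absorbs the whole slide; random-perturb adds
#'   seeded Gaussian jitter to every bead.
#' @param n total number of beads (>= 6; each domain gets (n - 3) / 2
#'   beads, the neck 3).
#' @param bond_length consecutive-bead distance in Angstrom (default 3.8,
#'   the canonical Calpha virtual bond).
#' @param hinge_angle hinge/twist rotation in degrees, in [0, 180) (0
#'   yields the identity motion). Default 80, a large open-to-closed
#'   domain rotation.
#' @param shear_dist lateral translation of the second domain in Angstrom
#'   (default 6).
#' @param perturb_sd Gaussian jitter s.d. in Angstrom (random-perturb;
#'   default 0.35, a distortion well inside the elastic regime).
#' @param seed integer seed, used only by the random-perturb kind.
#' @param domain_width beads per lattice side of the domain cross-section
#'   (default 4, a compact globular domain; 2 gives a slender elongated
#'   domain whose per-residue contact count is independent of chain
#'   length, the constant-density family used for complexity
#'   experiments). `NA` picks 2 for domains under 16 beads, else 4.
#' @return validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("hinge", "shear", "twist", "random-perturb"),
                         n = 128L, bond_length = 3.8, hinge_angle = 80,
                         shear_dist = 6, perturb_sd = 0.35, seed = 1L,
                         domain_width = NA) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 6L) stop_usage("fixture needs n >= 6 beads")
  if (bond_length <= 0) stop_usage("bond_length must be positive")
  if (hinge_angle < 0 || hinge_angle >= 180)
    stop_usage("hinge_angle must be in [0, 180) degrees")
  if (!is.na(domain_width) && !domain_width %in% c(2, 4))
    stop_usage("domain_width must be 2 or 4")
  structure(list(kind = kind, n = n, bond_length = bond_length,
                 hinge_angle = hinge_angle, shear_dist = shear_dist,
                 perturb_sd = perturb_sd, seed = as.integer(seed),
                 domain_width = domain_width),
            class = "fixture_spec")
}

# Compact domain: the chain snakes through an nx x ny x nz cubic lattice
# (x fastest with alternating direction, then y, then z), so every
# consecutive pair is exactly one lattice spacing apart and the block is
# densely 3D-connected under the default network cutoff.
serpentine_block <- function(nb, nx, ny, spacing) {
  A <- nx * ny
  i0 <- seq_len(nb) - 1L
  z <- i0 %/% A
  r <- i0 %% A
  r <- ifelse(z %% 2L == 1L, A - 1L - r, r)
  y <- r %/% nx
  x <- r %% nx
  x <- ifelse(y %% 2L == 1L, nx - 1L - x, x)
  spacing * cbind(x, y, z)
}

fixture_structure <- function(coords, label) {
  n <- nrow(coords)
  cg_structure(data.frame(chain = "A", resno = seq_len(n), icode = "",
                          resname = "ALA", stringsAsFactors = FALSE),
               coords, label)
}

# Reference (start) geometry: domain 1, a 3-bead zigzag neck climbing
# along +z with lateral offsets (non-collinear, so the neck braces the
# inter-domain torsion), then domain 2. The neck length keeps the two
# domain faces farther apart than the default 12 A network cutoff, so the
# domains couple only through the neck: the softest modes are the
# inter-domain hinge/twist rotations, as in real two-domain proteins.
fixture_reference <- function(n, bond, domain_width = NA) {
  n_linker <- 3L
  n1 <- (n - n_linker) %/% 2L
  n2 <- n - n_linker - n1
  grid <- function(nb) {
    if (!is.na(domain_width)) return(as.integer(domain_width))
    if (nb < 16L) 2L else 4L
  }
  b1 <- serpentine_block(n1, grid(n1), grid(n1), bond)
  top <- b1[n1, ]
  offs <- bond * rbind(c(0, 0), c(0.53, 0), c(0, 0.53), c(0, 0))
  lk <- matrix(0, n_linker, 3)
  z <- 0
  for (i in seq_len(n_linker)) {
    dxy <- offs[i + 1L, ] - offs[i, ]
    z <- z + sqrt(bond^2 - sum(dxy^2))
    lk[i, ] <- top + c(offs[i + 1L, 1], offs[i + 1L, 2], z)
  }
  b2 <- serpentine_block(n2, grid(n2), grid(n2), bond)
  b2 <- sweep(b2, 2, b2[1L, ])
  b2 <- sweep(b2, 2, -(lk[n_linker, ] + c(0, 0, bond)))
  list(coords = rbind(b1, lk, b2), pivot = n1 + 2L, n1 = n1,
       n_linker = n_linker)
}

#' Build a synthetic two-conformation structure pair
#'
#' The start conformation is the two-domain reference geometry; the end
#' conformation applies the sub-motion named by the spec to the second
#' domain (everything past the middle neck bead). Deterministic given the
#' spec; the seed enters only for the random-perturb kind.
#'
#' @param spec a [fixture_spec].
#' @return a `structure_pair` (resolution `NA`).
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ref <- fixture_reference(spec$n, spec$bond_length, spec$domain_width)
  start <- ref$coords
  end <- start
  sel <- (ref$pivot + 1L):spec$n
  pivot <- start[ref$pivot, ]
  if (spec$kind == "hinge") {
    R <- rotation_about_axis(c(1, 0, 0), spec$hinge_angle * pi / 180)
    end[sel, ] <- sweep(sweep(start[sel, , drop = FALSE], 2, pivot) %*% t(R),
                        2, -pivot)
  } else if (spec$kind == "twist") {
    R <- rotation_about_axis(c(0, 0, 1), spec$hinge_angle * pi / 180)
    end[sel, ] <- sweep(sweep(start[sel, , drop = FALSE], 2, pivot) %*% t(R),
                        2, -pivot)
  } else if (spec$kind == "shear") {
    ramp <- numeric(spec$n)
    lk_idx <- ref$n1 + seq_len(ref$n_linker)
    ramp[lk_idx] <- seq_len(ref$n_linker) / (ref$n_linker + 1L)
    ramp[(ref$n1 + ref$n_linker + 1L):spec$n] <- 1
    end[, 1] <- end[, 1] + spec$shear_dist * ramp
  } else {
    set.seed(spec$seed)
    end <- start + matrix(stats::rnorm(3L * spec$n, sd = spec$perturb_sd),
                          ncol = 3L)
  }
  label <- sprintf("%s-n%d", spec$kind, spec$n)
  pair_structures(fixture_structure(start, paste0(label, "-start")),
                  fixture_structure(end, paste0(label, "-end")))
}

#' Render a structure as single-model PDB text
#'
#' @param structure a [cg_structure].
#' @return character scalar of PDB text, parseable by [read_calpha].
#' @export
make_pdb_text <- function(structure) {
  rid <- structure$residue_ids
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(rid)), substr(rid$resname, 1, 3), rid$chain, rid$resno,
    ifelse(rid$icode == "", " ", rid$icode),
    structure$coords[, 1], structure$coords[, 2], structure$coords[, 3], 1, 0)
  paste(c(lines, "END", ""), collapse = "\n")
}
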