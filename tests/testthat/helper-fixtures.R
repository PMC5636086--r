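# Shared helpers: tiny structures and pathway runs reused across tests.

# bare cg_structure from a coordinate matrix, residues 1..n on chain A
cg_from_coords <- function(coords, label = "test", chain = "A",
                           resno = seq_len(nrow(coords))) {
  cg_structure(data.frame(chain = chain, resno = resno, icode = "",
                          resname = "ALA", stringsAsFactors = FALSE),
               coords, label)
}

# small hinge pair used by many tests (cached per session)
hinge_pair_10 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_pair(fixture_spec("hinge", n = 10,
                                                     hinge_angle = 30))
    val
  }
})

hinge_pair_20 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_pair(fixture_spec("hinge", n = 20,
                                                     hinge_angle = 60))
    val
  }
})

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_copy <- function(s, R, t) {
  cg_structure(s$residue_ids, sweep(s$coords %*% t(R), 2, -t), s$label)
}
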