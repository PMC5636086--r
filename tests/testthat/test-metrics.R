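test_that("pathway comparison is zero for identical or rigidly moved copies", {
  pair <- hinge_pair_10()
  pw <- quiet(run_ngeni(pair, modes = 8, steps = 5))
  expect_equal(compare_pathways(pw, pw)$average_rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(7)
  moved <- pw
  moved$conformations <- lapply(pw$conformations, rigid_copy, R = R,
                                t = c(1, -2, 3))
  cmp <- compare_pathways(pw, moved)
  expect_equal(cmp$average_rmsd, 0, tolerance = 1e-8)
  # symmetry
  p2 <- quiet(run_ngeni(pair, modes = 4, steps = 5))
  expect_equal(compare_pathways(pw, p2)$average_rmsd,
               compare_pathways(p2, pw)$average_rmsd, tolerance = 1e-12)
})

test_that("comparison rejects incompatible pathways", {
  pair <- hinge_pair_10()
  p5 <- quiet(run_ngeni(pair, modes = 4, steps = 5))
  p9 <- quiet(run_ngeni(pair, modes = 4, steps = 9))
  expect_error(compare_pathways(p5, p9), class = "ngeni_data_error")
})

test_that("convergence condition compares the terminus to the resolution", {
  pair <- hinge_pair_20()
  pw <- run_ngeni(pair, modes = "full")
  cc <- convergence_check(pw, resolution = 2)
  expect_true(cc$pass)
  expect_equal(cc$residual, pw$final_residual, tolerance = 1e-12)
  p4 <- quiet(run_ngeni(pair, modes = 4))
  c4 <- convergence_check(p4, resolution = 0.01)
  expect_false(c4$pass)
  # monotone in resolution: pass at r implies pass at r' > r
  for (r in c(0.5, 1, 3)) {
    if (convergence_check(p4, resolution = r)$pass)
      expect_true(convergence_check(p4, resolution = r + 1)$pass)
  }
  expect_error(convergence_check(pw, resolution = 0),
               class = "ngeni_usage_error")
})

test_that("mode profile averages |c_k| and ignores global sign flips", {
  pair <- hinge_pair_10()
  pw <- quiet(run_ngeni(pair, modes = 6, steps = 5))
  pr <- mode_profile(pw)
  expect_length(pr$mean_abs_weights, 6L)
  expect_true(all(pr$mean_abs_weights >= 0))
  expect_equal(pr$mean_abs_weights, colMeans(abs(pw$weights)))
  flipped <- pw
  flipped$weights[, 2] <- -flipped$weights[, 2]
  expect_equal(mode_profile(flipped)$mean_abs_weights, pr$mean_abs_weights)
  eni <- run_eni(pair, steps = 5)
  expect_error(mode_profile(eni), class = "ngeni_data_error")
})

test_that("a transition along one mode concentrates the profile on it", {
  pair <- hinge_pair_20()
  s <- pair$start
  basis <- compute_modes(build_hessian(s, build_network(s)), 10)
  disp <- 0.3 * sqrt(n_residues(s)) * basis$modes[, 1]
  end <- cg_structure(s$residue_ids,
                      s$coords + ngeni:::vec_to_coords(disp, n_residues(s)),
                      "mode1-end")
  pw <- quiet(run_ngeni(pair_structures(s, end), modes = 10))
  pr <- mode_profile(pw)
  expect_gt(pr$mean_abs_weights[1], 10 * max(pr$mean_abs_weights[-1]))
})

test_that("profile correlation: identity, scale invariance, anti-ordering", {
  mkp <- function(w) structure(list(mean_abs_weights = w, m = length(w)),
                               class = "mode_profile")
  a <- mkp(seq(1, 30) / 10)
  expect_equal(profile_correlation(a, a, 30), 1)
  expect_equal(profile_correlation(a, mkp(2 * a$mean_abs_weights), 30), 1)
  expect_equal(profile_correlation(a, mkp(rev(a$mean_abs_weights)), 30), -1)
  expect_error(profile_correlation(a, mkp(rep(1, 30)), 30),
               class = "ngeni_data_error")
  expect_error(profile_correlation(a, mkp(1:5), 30),
               class = "ngeni_usage_error")
})

test_that("pseudo-bond statistics on known geometries", {
  # straight 4-bead chain spaced 3.8 A
  chain <- cg_from_coords(cbind(3.8 * (0:3), 0, 0))
  pw <- structure(list(conformations = list(chain, chain),
                       per_step = data.frame(alpha = c(0, 1))),
                  class = "transition_pathway")
  bg <- bond_geometry(pw)
  expect_equal(bg$per_step$mean_bond_length, c(3.8, 3.8))
  expect_equal(bg$per_step$mean_bond_angle, c(180, 180), tolerance = 1e-8)
  expect_equal(bg$max_bond_dev, 0)
  # chain break: residue-number gap excluded from the statistics
  gap <- cg_from_coords(rbind(c(0, 0, 0), c(3.8, 0, 0), c(30, 0, 0),
                              c(33.8, 0, 0)), resno = c(1, 2, 10, 11))
  pwg <- structure(list(conformations = list(gap),
                        per_step = data.frame(alpha = 0)),
                   class = "transition_pathway")
  expect_equal(bond_geometry(pwg)$per_step$mean_bond_length, 3.8)
})

test_that("metrics CSV round-trips with schema header and weights", {
  pair <- hinge_pair_10()
  pw <- quiet(run_ngeni(pair, modes = 4, steps = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(pw, f, weights = TRUE)
  txt <- readLines(f)
  expect_match(txt[1], "schema v1")
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(df), nrow(pw$per_step))
  expect_true(all(c("step", "alpha", "rmsd_to_end", "c_1", "c_4") %in%
                  names(df)))
  expect_equal(df$c_2[-1], pw$weights[, 2], tolerance = 1e-12)
})
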