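# Superposition, B-factors, backbone torsions, periodic-KDE entropy, 2D RMSD.

test_that("superposition removes rigid motion and rejects degenerate input", {
  sc <- gen_backbone_scaffold(4)
  base <- sc$xyz[1, , ]
  rot <- base %*% t(rot_z(90))
  rot <- sweep(rot, 2, c(5, -2, 1), `+`)
  xyz <- array(0, dim = c(2, nrow(base), 3))
  xyz[1, , ] <- base; xyz[2, , ] <- rot
  ens <- frame_ensemble(sc$atoms, xyz)
  al <- kabsch_superpose(ens, select_atoms(ens, "name N CA C"))
  expect_lt(al$per_frame_rmsd[2], 1e-8)
  expect_equal(al$per_frame_rmsd[1], 0)

  # identical frames: all zero
  xyz2 <- array(0, dim = c(3, nrow(base), 3))
  for (f in 1:3) xyz2[f, , ] <- base
  al2 <- kabsch_superpose(frame_ensemble(sc$atoms, xyz2))
  expect_true(all(al2$per_frame_rmsd < 1e-10))

  # collinear selection is refused
  atoms <- do.call(rbind, lapply(1:4, function(i)
    atom_row("CA", "C", "A", i, i * 1.5, 0, 0)))
  lin <- make_ensemble(list(atoms))
  expect_error(kabsch_superpose(lin, select_atoms(lin, "name CA")),
               "degenerate")
})

test_that("a mirrored frame is never fit with a reflection", {
  set.seed(21)
  P <- matrix(rnorm(15, sd = 2), 5, 3)
  atoms <- do.call(rbind, lapply(1:5, function(i)
    atom_row("CA", "C", "A", i, P[i, 1], P[i, 2], P[i, 3])))
  mir <- P %*% diag(c(1, 1, -1))           # improper transform of frame 1
  fr2 <- atoms; fr2$x <- mir[, 1]; fr2$y <- mir[, 2]; fr2$z <- mir[, 3]
  ens <- make_ensemble(list(atoms, fr2))
  al <- kabsch_superpose(ens, select_atoms(ens, "name CA"))
  # a reflection would give 0; the proper-rotation optimum matches the oracle
  expect_gt(al$per_frame_rmsd[2], 0.1)
  expect_lt(abs(al$per_frame_rmsd[2] - oracle_min_rmsd(mir, P)), 1e-4)
})

test_that("small displaced toys match the quaternion-search oracle", {
  set.seed(31)
  for (case in 1:4) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n, sd = 2), n, 3)
    Q <- P %*% t(rot_z(35)) + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i)
      atom_row("CA", "C", "A", i, P[i, 1], P[i, 2], P[i, 3])))
    fr2 <- atoms; fr2$x <- Q[, 1]; fr2$y <- Q[, 2]; fr2$z <- Q[, 3]
    ens <- make_ensemble(list(atoms, fr2))
    al <- kabsch_superpose(ens, select_atoms(ens, "name CA"))
    expect_lt(abs(al$per_frame_rmsd[2] - oracle_min_rmsd(Q, P)), 1e-4)
  }
})

test_that("Kabsch agrees with the bio3d fitter on a realistic ensemble", {
  g <- gen_coordinate_ensemble(c(0, 0, 0.4, 0.4, 0), M = 5, seed = 9,
                               rigid_jitter = TRUE)
  ens <- g$ensemble
  sel <- select_atoms(ens, "name CA")
  al <- kabsch_superpose(ens, sel)
  m <- n_frames(ens)
  flat <- matrix(aperm(ens$xyz, c(3, 2, 1)), nrow = m, byrow = TRUE)
  ref_fit <- bio3d::fit.xyz(flat[1, ], flat,
                            fixed.inds = bio3d::atom2xyz(sel$indices),
                            mobile.inds = bio3d::atom2xyz(sel$indices))
  ref_rmsd <- bio3d::rmsd(ref_fit[1, ], ref_fit,
                          a.inds = bio3d::atom2xyz(sel$indices),
                          b.inds = bio3d::atom2xyz(sel$indices))
  expect_equal(al$per_frame_rmsd, as.numeric(ref_rmsd), tolerance = 1e-3)
})

test_that("B-factors obey the (8 pi^2 / 3) MSF identity and its anchors", {
  # static ensemble: exactly zero
  sc <- gen_backbone_scaffold(3)
  xyz <- array(0, dim = c(4, n_atoms(sc), 3))
  for (f in 1:4) xyz[f, , ] <- sc$xyz[1, , ]
  bf0 <- calpha_bfactors(frame_ensemble(sc$atoms, xyz))
  expect_true(all(bf0$bfactor == 0))

  # CA alternating between two points 2 A apart: MSF = 1, B = 8 pi^2 / 3
  atoms <- rbind(atom_row("CA", "C", "A", 1, 0, 0, 0),
                 atom_row("CA", "C", "A", 2, 5, 0, 0),
                 atom_row("CA", "C", "A", 3, 0, 5, 0))
  fr2 <- atoms; fr2$z[1] <- 2
  ens <- make_ensemble(list(atoms, fr2))
  bf <- calpha_bfactors(ens)
  expect_equal(bf$msf[1], 1)
  expect_equal(bf$bfactor[1], 8 * pi^2 / 3)
  expect_equal(bf$bfactor, (8 * pi^2 / 3) * bf$msf)

  # residues without CA are skipped with a warning
  atoms2 <- rbind(atoms, atom_row("O", "O", "A", 4, 1, 1, 1))
  ens2 <- make_ensemble(list(atoms2))
  expect_warning(bf2 <- calpha_bfactors(ens2), "without CA")
  expect_equal(nrow(bf2), 3L)
})

test_that("isotropic Gaussian fluctuation recovers B = 8 pi^2 sigma^2", {
  g <- gen_coordinate_ensemble(c(rep(0, 8), 0.5, rep(0, 8)), M = 4000,
                               seed = 13, rigid_jitter = FALSE)
  bf <- calpha_bfactors(g$ensemble)
  got <- bf$bfactor[bf$residue == "A:9"]
  expect_lt(abs(got / ((8 * pi^2 / 3) * 3 * 0.25) - 1), 0.08)
})

test_that("torsion geometry anchors: anti is -180, syn is 0", {
  # four coplanar atoms, anti arrangement
  anti <- rbind(atom_row("C", "C", "A", 1, -1, 1, 0),
                atom_row("N", "N", "A", 1, 0, 0, 0),
                atom_row("CA", "C", "A", 1, 1, 0, 0),
                atom_row("CB", "C", "A", 1, 2, -1, 0))
  ens <- make_ensemble(list(anti))
  tor <- specflex:::.torsion_deg(matrix(ens$xyz[1, 1, ], 1),
                                 matrix(ens$xyz[1, 2, ], 1),
                                 matrix(ens$xyz[1, 3, ], 1),
                                 matrix(ens$xyz[1, 4, ], 1))
  expect_equal(tor, -180)             # 180 maps onto -180 in [-180, 180)

  syn <- rbind(atom_row("C", "C", "A", 1, -1, 1, 0),
               atom_row("N", "N", "A", 1, 0, 0, 0),
               atom_row("CA", "C", "A", 1, 1, 0, 0),
               atom_row("CB", "C", "A", 1, 2, 1, 0))
  ens2 <- make_ensemble(list(syn))
  tor2 <- specflex:::.torsion_deg(matrix(ens2$xyz[1, 1, ], 1),
                                  matrix(ens2$xyz[1, 2, ], 1),
                                  matrix(ens2$xyz[1, 3, ], 1),
                                  matrix(ens2$xyz[1, 4, ], 1))
  expect_equal(tor2, 0)
})

test_that("built torsions are recovered exactly and match bio3d's convention", {
  sc <- gen_backbone_scaffold(6, phi = -57, psi = -47)
  ser <- backbone_dihedrals(sc)
  phis <- vapply(ser[grep("^phi", names(ser))], function(s) s$values, numeric(1))
  psis <- vapply(ser[grep("^psi", names(ser))], function(s) s$values, numeric(1))
  expect_equal(unname(phis), rep(-57, 5), tolerance = 1e-6)
  expect_equal(unname(psis), rep(-47, 5), tolerance = 1e-6)
  # first residue has no phi, last no psi
  expect_false("phi A:1" %in% names(ser))
  expect_false("psi A:6" %in% names(ser))

  # independent sign check against bio3d on one phi quadruple
  idx <- c(which(atom_residue_keys(sc) == "A:1" & sc$atoms$elety == "C"),
           which(atom_residue_keys(sc) == "A:2" & sc$atoms$elety %in%
                   c("N", "CA", "C")))
  co <- as.vector(t(sc$xyz[1, idx, ]))
  expect_equal(ser[["phi A:2"]]$values,
               as.numeric(bio3d::torsion.xyz(co, atm.inc = 4)),
               tolerance = 1e-6)
})

test_that("chain breaks and missing atoms suppress the affected series", {
  sc <- gen_backbone_scaffold(6)
  xyz <- sc$xyz
  akeys <- atom_residue_keys(sc)
  far <- akeys %in% c("A:4", "A:5", "A:6")
  xyz[1, far, 1] <- xyz[1, far, 1] + 100       # break between 3 and 4
  ens <- frame_ensemble(sc$atoms, xyz)
  ser <- backbone_dihedrals(ens)
  expect_false("phi A:4" %in% names(ser))      # no phi across the break
  expect_false("psi A:3" %in% names(ser))
  expect_true("phi A:5" %in% names(ser))

  # drop residue 3's CA: its phi and psi vanish, neighbours keep theirs
  keep <- !(akeys == "A:3" & sc$atoms$elety == "CA")
  ens2 <- frame_ensemble(sc$atoms[keep, ], sc$xyz[, keep, , drop = FALSE])
  expect_message(ser2 <- backbone_dihedrals(ens2), "incomplete backbone")
  expect_false("phi A:3" %in% names(ser2))
  expect_false("psi A:3" %in% names(ser2))
  expect_true("psi A:2" %in% names(ser2))
})

test_that("periodic KDE is flat for uniform data and mode-safe at the seam", {
  set.seed(41)
  kde <- periodic_kde(runif(50000, -180, 180))
  expect_equal(sum(kde$density) * 360 / kde$grid_points, 1, tolerance = 1e-6)
  expect_lt(max(abs(kde$density - 1 / 360)) / (1 / 360), 0.15)

  # cluster straddling the -180/180 seam: one mode at the seam, not two edges
  x <- c(rnorm(3000, 179.5, 0.5), rnorm(3000, -179.5, 0.5))
  x <- ((x + 180) %% 360) - 180
  kde2 <- periodic_kde(x)
  at <- function(deg) kde2$density[which.min(abs(kde2$grid - deg))]
  expect_gt(min(at(-179.9), at(179.9)), at(170) * 2)
  expect_gt(min(at(-179.9), at(179.9)), at(0) * 50)

  expect_error(periodic_kde(5), "at least 2")
  expect_error(periodic_kde(c(1, 2), bandwidth = -1), "positive")
  expect_warning(periodic_kde(rep(10, 100)), "degenerate")
})

test_that("periodic KDE tracks the analytic von Mises density", {
  set.seed(43)
  x <- rvonmises(50000, 20, 4)
  kde <- periodic_kde(x)
  ref <- specflex:::.vm_mixture_density(kde$grid,
                                        list(list(mean = 20, kappa = 4,
                                                  weight = 1)))
  l1 <- sum(abs(kde$density - ref)) * 360 / kde$grid_points
  expect_lt(l1, 0.02)
})

test_that("dihedral entropy is shift-invariant and scales as R ln w", {
  set.seed(47)
  x <- rvonmises(20000, -60, 3)
  s0 <- dihedral_entropy(x)
  for (off in c(90, 180, 277)) {
    expect_lt(abs(dihedral_entropy(((x + off + 180) %% 360) - 180) - s0), 0.1)
  }
  # uniform boxes of width w: entropy ~ R ln w, strictly increasing
  widths <- c(1, 10, 60, 360)
  ests <- vapply(widths, function(w)
    dihedral_entropy(runif(50000, -w / 2, w / 2)), numeric(1))
  expect_true(all(diff(ests) > 0))
  expect_true(all(abs(ests - RGAS * log(widths)) < 1))
})

test_that("entropy quadrature is stable under grid refinement", {
  set.seed(53)
  x <- rvonmises(20000, 10, 8)
  e1 <- dihedral_entropy(x, grid_points = 720)
  e2 <- dihedral_entropy(x, grid_points = 1440)
  expect_lt(abs(e1 - e2), 0.05)
})

test_that("the entropy profile maps per-residue phi/psi series", {
  g <- gen_dihedral_ensemble(list("phi A:2" = list(mean = -57, kappa = 8),
                                  "psi A:2" = list(mean = -47, kappa = 2)),
                             M = 20000, seed = 3)
  prof <- dihedral_entropy_profile(g$series)
  expect_equal(prof$residue, "A:2")
  expect_lt(abs(prof$s_phi - g$truth[["phi A:2"]]), 1)
  expect_lt(abs(prof$s_psi - g$truth[["psi A:2"]]), 1)
  expect_lt(prof$s_phi, prof$s_psi)   # higher concentration, lower entropy
})

test_that("2D RMSD matrices are symmetric, zero-diagonal and oracle-exact", {
  sc <- gen_backbone_scaffold(4)
  base <- sc$xyz[1, , ]
  # identical frames: zero matrix
  xyz <- array(0, dim = c(3, nrow(base), 3))
  for (f in 1:3) xyz[f, , ] <- base
  rm0 <- rmsd_matrix(frame_ensemble(sc$atoms, xyz),
                     select_atoms(sc, "name CA"))
  expect_true(all(abs(rm0$values) < 1e-10))

  # a rigid-rotated copy gives zero off-diagonal
  xyz2 <- array(0, dim = c(2, nrow(base), 3))
  xyz2[1, , ] <- base
  xyz2[2, , ] <- sweep(base %*% t(rot_z(65)), 2, c(1, 2, 3), `+`)
  rm1 <- rmsd_matrix(frame_ensemble(sc$atoms, xyz2),
                     select_atoms(sc, "name N CA C"))
  expect_lt(rm1$values[1, 2], 1e-8)

  # 5-frame noisy toy: every entry matches the quaternion oracle
  set.seed(59)
  g <- gen_coordinate_ensemble(c(0.4, 0.5, 0.3, 0.2), M = 5, seed = 61)
  sel <- select_atoms(g$ensemble, "name N CA C")
  rm2 <- rmsd_matrix(g$ensemble, sel)
  expect_equal(rm2$values, t(rm2$values))
  expect_true(all(diag(rm2$values) == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    P <- g$ensemble$xyz[i, sel$indices, ]
    Q <- g$ensemble$xyz[j, sel$indices, ]
    expect_lt(abs(rm2$values[i, j] - oracle_min_rmsd(P, Q)), 1e-4)
  }
})

test_that("subset-support ensembles show no new conformational space", {
  # wide ensemble samples clusters A and B; narrow ensemble only cluster A:
  # cross-RMSD between the two stays within the wide ensemble's own spread
  set.seed(67)
  sc <- gen_backbone_scaffold(5)
  base <- sc$xyz[1, , ]
  altern <- base + matrix(rnorm(nrow(base) * 3, sd = 1.5), nrow(base), 3)
  mk <- function(centers, m) {
    xyz <- array(0, dim = c(m, nrow(base), 3))
    for (f in 1:m) {
      ctr <- centers[[(f %% length(centers)) + 1]]
      xyz[f, , ] <- ctr + matrix(rnorm(nrow(base) * 3, sd = 0.1),
                                 nrow(base), 3)
    }
    xyz
  }
  wide <- mk(list(base, altern), 8)
  narrow <- mk(list(base), 6)
  all_xyz <- array(0, dim = c(14, nrow(base), 3))
  all_xyz[1:8, , ] <- wide; all_xyz[9:14, , ] <- narrow
  ens <- frame_ensemble(sc$atoms, all_xyz)
  rm <- rmsd_matrix(ens, select_atoms(ens, "name CA"))
  within_wide <- max(rm$values[1:8, 1:8])
  cross <- max(rm$values[9:14, 1:8])
  expect_lte(cross, within_wide + 1e-8)
})
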