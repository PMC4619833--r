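# Flexibility metrics from conformational ensembles.
#
# Three per-residue flexibility measures are provided:
#   * Calpha B-factors after a single global rigid-body (Kabsch) alignment:
#     B = (8 pi^2 / 3) * MSF, MSF the mean-square fluctuation about the
#     ensemble-mean position.
#   * Backbone dihedral entropies S_phi / S_psi: a Gaussian kernel density
#     estimate of the torsion distribution (data periodically duplicated at
#     +/-360 deg to avoid boundary decay), integrated as
#     S = -R * integral p(a) ln p(a) da over one 360 deg period, density per
#     degree, R = 8.314 J/(mol K). A delta-like peak of ~1 deg width gives
#     S ~ 0; the uniform distribution gives R*ln(360) ~ 48.94 J/(mol K).
#   * Two-dimensional RMSD matrices over a selection, each entry the minimal
#     RMSD after pairwise superposition.

# ---- Kabsch superposition ---------------------------------------------------

# optimal rotation (3x3, row-vector convention: centered P %*% U ~ centered Q),
# reflection-safe via the determinant correction
.kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

.frame_coords <- function(ensemble, i, idx = NULL) {
  x <- ensemble$xyz[i, , , drop = FALSE]
  dim(x) <- dim(ensemble$xyz)[2:3]
  if (!is.null(idx)) x <- x[idx, , drop = FALSE]
  x
}

#' Superpose all frames onto a reference (Kabsch)
#'
#' Each frame is rigid-body transformed (rotation + translation, never a
#' reflection) to minimize the RMSD of the selected atoms against the
#' reference; the transformation is applied to all atoms of the frame.
#'
#' @param ensemble a `FrameEnsemble`.
#' @param selection an `AtomSelection` with at least 3 non-collinear atoms
#'   (default: all `CA` atoms).
#' @param reference frame index used as reference (default 1), or a matrix of
#'   reference coordinates for the selected atoms (`length(selection) x 3`).
#' @return A `SuperpositionResult`: list with `aligned_ensemble`
#'   (`FrameEnsemble`), `per_frame_rmsd` (Angstrom, over the selection) and
#'   `reference`.
#' @export
kabsch_superpose <- function(ensemble, selection = NULL, reference = 1L) {
  if (is.null(selection)) selection <- select_atoms(ensemble, "name CA")
  idx <- selection$indices
  if (length(idx) < 3L) stop("superposition needs >= 3 selected atoms")
  if (is.matrix(reference)) {
    ref <- reference
    ref_is_frame <- FALSE
    if (nrow(ref) != length(idx) || ncol(ref) != 3L)
      stop("external reference must be a length(selection) x 3 matrix")
  } else {
    ref <- .frame_coords(ensemble, reference, idx)
    ref_is_frame <- TRUE
  }
  refc <- colMeans(ref)
  ref0 <- sweep(ref, 2L, refc)
  sv <- svd(ref0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate selection: reference atoms are collinear or coincident")
  m <- n_frames(ensemble)
  out <- ensemble$xyz
  rmsd <- numeric(m)
  for (i in seq_len(m)) {
    P <- .frame_coords(ensemble, i, idx)
    pc <- colMeans(P)
    U <- .kabsch_rotation(sweep(P, 2L, pc), ref0)
    all_i <- .frame_coords(ensemble, i)
    moved <- sweep(sweep(all_i, 2L, pc) %*% U, 2L, refc, `+`)
    out[i, , ] <- moved
    rmsd[i] <- sqrt(mean(rowSums((moved[idx, , drop = FALSE] - ref)^2)))
  }
  structure(list(aligned_ensemble = frame_ensemble(ensemble$atoms, out,
                                                   ensemble$frame_labels),
                 per_frame_rmsd = rmsd,
                 reference = if (ref_is_frame) reference else "external",
                 selection = selection),
            class = "SuperpositionResult")
}

# ---- B-factors --------------------------------------------------------------

#' Residue-wise Calpha B-factors from an aligned ensemble
#'
#' For each residue with a `CA` atom, the mean-square fluctuation is
#' `MSF = mean_f ||r_f - <r>||^2` and `B = (8 pi^2 / 3) * MSF`. Input should
#' already be superposed ([kabsch_superpose()]) so that rigid-body motion does
#' not inflate the fluctuations; a raw `FrameEnsemble` is accepted as-is.
#'
#' @param aligned a `SuperpositionResult` or `FrameEnsemble`.
#' @return A `BFactorProfile`: data.frame with columns `residue` (key),
#'   `msf` (Angstrom^2) and `bfactor` (Angstrom^2).
#' @export
calpha_bfactors <- function(aligned) {
  ens <- if (inherits(aligned, "SuperpositionResult")) aligned$aligned_ensemble
         else aligned
  keys <- residue_keys(ens)
  akeys <- atom_residue_keys(ens)
  ca <- which(ens$atoms$elety == "CA")
  ca_key <- akeys[ca]
  missing <- setdiff(keys, ca_key)
  if (length(missing) > 0L)
    warning("residue(s) without CA skipped: ", paste(missing, collapse = ", "))
  keep <- keys[keys %in% ca_key]
  msf <- vapply(keep, function(k) {
    j <- ca[match(k, ca_key)]
    x <- ens$xyz[, j, , drop = FALSE]
    dim(x) <- c(dim(ens$xyz)[1], 3L)
    mu <- colMeans(x)
    mean(rowSums(sweep(x, 2L, mu)^2))
  }, numeric(1))
  structure(data.frame(residue = keep, msf = as.numeric(msf),
                       bfactor = (8 * pi^2 / 3) * as.numeric(msf),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("BFactorProfile", "data.frame"))
}

# ---- backbone dihedrals -----------------------------------------------------

# torsion of the 4-point chains given as M x 3 matrices; IUPAC sign, [-180,180)
.torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2n)
  ang <- atan2(-rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang >= 180] <- ang[ang >= 180] - 360
  ang[ang < -180] <- ang[ang < -180] + 360
  ang
}

#' Backbone phi/psi dihedral series
#'
#' Computes, for every residue with complete backbone atoms,
#' `phi(i) = C(i-1)-N(i)-CA(i)-C(i)` and `psi(i) = N(i)-CA(i)-C(i)-N(i+1)`
#' across all frames (IUPAC sign convention, degrees in `[-180, 180)`).
#' The first residue of a chain has no phi, the last no psi; chain breaks are
#' detected where the `C(i-1)`--`N(i)` distance exceeds 2.5 Angstrom in the
#' first frame. Residues with missing backbone atoms are skipped with a
#' message.
#'
#' @param ensemble a `FrameEnsemble` whose residues carry `N`, `CA`, `C`
#'   atoms.
#' @return A named list of `DihedralSeries` (names `"phi <key>"` /
#'   `"psi <key>"`), each a list with `angle_kind`, `residue` and `values`
#'   (length M, degrees).
#' @export
backbone_dihedrals <- function(ensemble) {
  a <- ensemble$atoms
  akeys <- atom_residue_keys(ensemble)
  keys <- residue_keys(ensemble)
  at_idx <- function(k, name) {
    j <- which(akeys == k & a$elety == name)
    if (length(j) == 0L) NA_integer_ else j[1]
  }
  bb <- data.frame(key = keys,
                   chain = a$chain[match(keys, akeys)],
                   N = vapply(keys, at_idx, integer(1), name = "N"),
                   CA = vapply(keys, at_idx, integer(1), name = "CA"),
                   C = vapply(keys, at_idx, integer(1), name = "C"),
                   stringsAsFactors = FALSE)
  m <- n_frames(ensemble)
  coords <- function(j) {
    x <- ensemble$xyz[, j, , drop = FALSE]; dim(x) <- c(m, 3L); x
  }
  series <- list()
  for (i in seq_len(nrow(bb))) {
    prev_ok <- i > 1L && bb$chain[i - 1L] == bb$chain[i]
    next_ok <- i < nrow(bb) && bb$chain[i + 1L] == bb$chain[i]
    if (prev_ok && !is.na(bb$C[i - 1L]) && !is.na(bb$N[i])) {
      gap <- sqrt(sum((ensemble$xyz[1, bb$C[i - 1L], ] -
                         ensemble$xyz[1, bb$N[i], ])^2))
      prev_ok <- gap <= 2.5
    }
    if (next_ok && !is.na(bb$C[i]) && !is.na(bb$N[i + 1L])) {
      gap <- sqrt(sum((ensemble$xyz[1, bb$C[i], ] -
                         ensemble$xyz[1, bb$N[i + 1L], ])^2))
      next_ok <- gap <= 2.5
    }
    if (any(is.na(c(bb$N[i], bb$CA[i], bb$C[i])))) {
      message("residue ", bb$key[i], ": incomplete backbone, dihedrals skipped")
      next
    }
    if (prev_ok && !is.na(bb$C[i - 1L])) {
      series[[paste("phi", bb$key[i])]] <- structure(
        list(angle_kind = "phi", residue = bb$key[i],
             values = .torsion_deg(coords(bb$C[i - 1L]), coords(bb$N[i]),
                                   coords(bb$CA[i]), coords(bb$C[i]))),
        class = "DihedralSeries")
    }
    if (next_ok && !is.na(bb$N[i + 1L])) {
      series[[paste("psi", bb$key[i])]] <- structure(
        list(angle_kind = "psi", residue = bb$key[i],
             values = .torsion_deg(coords(bb$N[i]), coords(bb$CA[i]),
                                   coords(bb$C[i]), coords(bb$N[i + 1L]))),
        class = "DihedralSeries")
    }
  }
  series
}

# ---- periodic KDE and dihedral entropy --------------------------------------

# circular standard deviation in degrees
.circ_sd_deg <- function(deg) {
  th <- deg * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (rbar >= 1) return(0)
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' Periodic kernel density estimate of an angle sample
#'
#' Gaussian KDE on the circle: the sample is duplicated at -360 and +360
#' degrees so the kernel does not decay at the -180/180 boundary, the density
#' is evaluated on a regular grid over one period and renormalized so it
#' integrates (per degree) to 1 over 360 degrees.
#'
#' The bandwidth `"auto"` uses Silverman's rule on the circular standard
#' deviation, `0.9 * sd_circ * n^(-1/5)`; a degenerate sample (zero circular
#' spread) falls back to a 1-degree bandwidth with a warning. The grid is
#' refined automatically (powers of 2) whenever its spacing would exceed a
#' third of the bandwidth, so narrow peaks stay resolved.
#'
#' @param angles numeric vector of angles in degrees (any real values;
#'   reduced mod 360 into `[-180, 180)`).
#' @param bandwidth Gaussian kernel standard deviation in degrees, or
#'   `"auto"`.
#' @param grid_points minimum number of grid points over the period
#'   (default 720).
#' @return A `PeriodicKDE`: list with `grid` (degrees, `[-180, 180)`),
#'   `density` (per degree), `bandwidth`, `grid_points` (actual), `n`.
#' @export
periodic_kde <- function(angles, bandwidth = "auto", grid_points = 720L) {
  x <- angles[is.finite(angles)]
  if (length(x) < 2L) stop("periodic KDE needs at least 2 samples")
  x <- ((x + 180) %% 360) - 180
  if (identical(bandwidth, "auto")) {
    s <- .circ_sd_deg(x)
    bw <- 0.9 * s * length(x)^(-1 / 5)
    if (!is.finite(bw) || bw < 1e-6) {
      warning("degenerate sample (zero circular spread): using 1-degree bandwidth")
      bw <- 1
    }
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0)
      stop("bandwidth must be positive or 'auto'")
    bw <- bandwidth
  }
  ng <- as.integer(grid_points)
  if (ng < 8L) stop("grid_points must be >= 8")
  if (360 / ng > bw / 3) ng <- 2^ceiling(log2(3 * 360 / bw))
  ng <- min(ng, 2L^18L)
  x3 <- c(x - 360, x, x + 360)
  d <- stats::density(x3, bw = bw, from = -180, to = 180, n = ng + 1L)
  grid <- d$x[seq_len(ng)]
  dens <- d$y[seq_len(ng)]
  dens[dens < 0] <- 0
  step <- 360 / ng
  total <- sum(dens) * step           # periodic grid: rectangle == trapezoid
  if (total <= 0) stop("density integrated to zero; bad input")
  dens <- dens / total
  structure(list(grid = grid, density = dens, bandwidth = bw,
                 grid_points = ng, n = length(x)),
            class = "PeriodicKDE")
}

#' Dihedral entropy of an angle sample
#'
#' Integrates `S = -R * sum p ln p * dalpha` over one period on the KDE grid
#' (R = 8.314462618 J/(mol K); density per degree; grid points where the
#' density underflows are treated as 0 ln 0 = 0). A sample concentrated in a
#' ~1 degree window yields an entropy near 0; a uniform circular sample
#' yields `R * ln 360` (about 48.94 J/(mol K)).
#'
#' @param angles numeric vector of angles in degrees, or a `DihedralSeries`.
#' @inheritParams periodic_kde
#' @return Entropy in J/(mol K) (scalar).
#' @export
dihedral_entropy <- function(angles, bandwidth = "auto", grid_points = 720L) {
  if (inherits(angles, "DihedralSeries")) angles <- angles$values
  kde <- periodic_kde(angles, bandwidth = bandwidth, grid_points = grid_points)
  p <- kde$density
  step <- 360 / kde$grid_points
  ok <- p > 1e-300
  -.RGAS * sum(p[ok] * log(p[ok])) * step
}

#' Per-residue dihedral entropy profile
#'
#' Applies [dihedral_entropy()] to every phi and psi series of an ensemble
#' (or to a precomputed series list from [backbone_dihedrals()] or
#' [gen_dihedral_ensemble()]).
#'
#' @param x a `FrameEnsemble` or a named list of `DihedralSeries`.
#' @inheritParams periodic_kde
#' @return A `DihedralEntropyProfile`: data.frame with columns `residue`,
#'   `s_phi`, `s_psi` (J/(mol K); `NA` where the series is absent), plus the
#'   KDE settings as attributes.
#' @export
dihedral_entropy_profile <- function(x, bandwidth = "auto", grid_points = 720L) {
  series <- if (inherits(x, "FrameEnsemble")) backbone_dihedrals(x) else x
  if (length(series) == 0L) stop("no dihedral series available")
  res <- unique(vapply(series, function(s) s$residue, character(1)))
  get_s <- function(kind, key) {
    s <- series[[paste(kind, key)]]
    if (is.null(s)) return(NA_real_)
    dihedral_entropy(s$values, bandwidth, grid_points)
  }
  out <- data.frame(residue = res,
                    s_phi = vapply(res, get_s, numeric(1), kind = "phi"),
                    s_psi = vapply(res, get_s, numeric(1), kind = "psi"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "grid_points") <- grid_points
  class(out) <- c("DihedralEntropyProfile", "data.frame")
  out
}

# ---- 2D RMSD ----------------------------------------------------------------

# minimal RMSD between two point sets after optimal superposition
.pair_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2L, colMeans(P))
  Q0 <- sweep(Q, 2L, colMeans(Q))
  U <- .kabsch_rotation(P0, Q0)
  sqrt(mean(rowSums((P0 %*% U - Q0)^2)))
}

#' Pairwise (two-dimensional) RMSD matrix
#'
#' Entry `(i, j)` is the minimal RMSD between frames `i` and `j` after
#' pairwise Kabsch superposition on the selection. The matrix is symmetric
#' with a zero diagonal.
#'
#' @param ensemble a `FrameEnsemble`.
#' @param selection an `AtomSelection` (>= 3 atoms; default all `CA`).
#' @param stride keep every `stride`-th frame (default 1).
#' @return An `RmsdMatrix`: list with `values` (M' x M' matrix, Angstrom),
#'   `frames` (original frame indices) and `selection`.
#' @export
rmsd_matrix <- function(ensemble, selection = NULL, stride = 1L) {
  if (is.null(selection)) selection <- select_atoms(ensemble, "name CA")
  if (stride < 1L) stop("stride must be >= 1")
  idx <- selection$indices
  if (length(idx) < 3L) stop("rmsd_matrix needs >= 3 selected atoms")
  frames <- seq(1L, n_frames(ensemble), by = stride)
  mm <- length(frames)
  coords <- lapply(frames, function(i) .frame_coords(ensemble, i, idx))
  vals <- matrix(0, mm, mm)
  for (i in seq_len(mm)) {
    for (j in seq_len(mm)) {
      if (j <= i) next
      vals[i, j] <- vals[j, i] <- .pair_rmsd(coords[[i]], coords[[j]])
    }
  }
  structure(list(values = vals, frames = frames, selection = selection),
            class = "RmsdMatrix")
}
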