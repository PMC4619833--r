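# Synthetic-data generators with known ground truth.
#
# Every generator is deterministic given (spec, seed) and returns the planted
# ground truth alongside the data, so recovery tests never have to recompute
# truth with the estimator under test. Torsion samples are i.i.d. draws from
# von Mises (mixtures); coordinate ensembles use isotropic per-residue
# Gaussian displacements on an ideal backbone scaffold; the toy complex uses
# idealized bond lengths (N-H 1.01 A) so hydrogen-bond criteria are exercised
# exactly at their thresholds. No force field, no solvent: statistical
# structure only.

# ---- von Mises --------------------------------------------------------------

#' Sample from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampling; `kappa = 0` gives the circular uniform
#' distribution. Angles are returned in degrees in `[-180, 180)`.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @return Numeric vector of `n` angles in degrees.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    got <- 0L
    while (got < n) {
      todo <- n - got
      u1 <- stats::runif(todo); u2 <- stats::runif(todo); u3 <- stats::runif(todo)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      acc <- which(ok)
      if (length(acc) > 0L) {
        take <- acc[seq_len(min(length(acc), todo))]
        th[(got + 1L):(got + length(take))] <-
          sign(u3[take] - 0.5) * acos(pmin(1, pmax(-1, f[take])))
        got <- got + length(take)
      }
    }
  }
  deg <- th * 180 / pi + mu_deg
  ((deg + 180) %% 360) - 180
}

#' Closed-form von Mises dihedral entropy (degree measure)
#'
#' Differential entropy of the von Mises distribution,
#' `h = ln(2 pi I0(kappa)) - kappa I1(kappa)/I0(kappa)` (nats, radian
#' measure), converted to degree measure and multiplied by the gas constant:
#' `S = R * (h + ln(180/pi))` in J/(mol K). `kappa = 0` gives `R ln 360`.
#'
#' @param kappa concentration parameter, `>= 0`.
#' @return Entropy in J/(mol K).
#' @export
vonmises_entropy <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  h_rad <- vapply(kappa, function(k) {
    if (k > 1e5) {
      # Gaussian limit: von Mises(kappa) -> N(0, 1/kappa) on the circle
      return(0.5 * log(2 * pi * exp(1) / k))
    }
    # exponentially scaled Bessel functions avoid overflow at large kappa
    i0s <- besselI(k, 0, expon.scaled = TRUE)
    i1s <- besselI(k, 1, expon.scaled = TRUE)
    log(2 * pi * i0s) + k - k * i1s / i0s
  }, numeric(1))
  .RGAS * (h_rad + log(180 / pi))
}

# analytic von Mises(-mixture) density per degree on a degree grid
.vm_mixture_density <- function(theta_deg, components) {
  th <- theta_deg * pi / 180
  dens <- 0
  for (cmp in components) {
    mu <- cmp$mean * pi / 180
    k <- cmp$kappa
    w <- if (is.null(cmp$weight)) 1 / length(components) else cmp$weight
    d <- exp(k * (cos(th - mu) - 1)) / (2 * pi * besselI(k, 0, expon.scaled = TRUE))
    dens <- dens + w * d
  }
  dens * pi / 180                     # per degree
}

#' Ground-truth entropy of a von Mises mixture by quadrature
#'
#' High-resolution numerical integration of `-R p ln p` over the analytic
#' mixture density (degree measure). For a single component this agrees with
#' [vonmises_entropy()].
#'
#' @param components list of components, each a list with `mean` (deg),
#'   `kappa` and optional `weight` (weights must sum to 1; equal weights if
#'   omitted).
#' @param n_grid quadrature grid size (default 100001).
#' @return Entropy in J/(mol K).
#' @export
vonmises_mixture_entropy <- function(components, n_grid = 100001L) {
  w <- vapply(components, function(c)
    if (is.null(c$weight)) 1 / length(components) else c$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(vapply(components, function(c) c$kappa < 0, logical(1))))
    stop("kappa must be >= 0")
  grid <- seq(-180, 180, length.out = n_grid)
  p <- .vm_mixture_density(grid, components)
  step <- grid[2] - grid[1]
  ok <- p > 1e-300
  # trapezoid over the closed period (first == last point)
  f <- -p * log(pmax(p, 1e-300))
  f[!ok] <- 0
  .RGAS * (sum(f) - (f[1] + f[n_grid]) / 2) * step
}

# sample one von Mises mixture
.rvm_mixture <- function(n, components) {
  w <- vapply(components, function(c)
    if (is.null(c$weight)) 1 / length(components) else c$weight, numeric(1))
  pick <- sample.int(length(components), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (j in seq_along(components)) {
    idx <- which(pick == j)
    if (length(idx) > 0L)
      out[idx] <- rvonmises(length(idx), components[[j]]$mean,
                            components[[j]]$kappa)
  }
  out
}

# ---- substrate tables -------------------------------------------------------

#' Generate a substrate table with planted positional distributions
#'
#' Draws `n` i.i.d. residues per position from the given distributions. The
#' ground truth for each position is the normalized Shannon entropy
#' `-sum p log20 p` of the *planted* distribution (not of the sample).
#'
#' @param dists named list: position label -> named probability vector over
#'   one-letter residue codes (must sum to 1, non-negative).
#' @param n number of substrates.
#' @param seed RNG seed.
#' @param source provenance string for the table.
#' @return list with `table` (a `SubstrateTable`) and `truth` (named numeric:
#'   planted normalized entropies per position).
#' @export
gen_substrate_table <- function(dists, n, seed = 1L,
                                source = "synthetic substrate table") {
  stopifnot(n >= 1L)
  for (p in names(dists)) {
    pr <- dists[[p]]
    if (any(pr < 0)) stop("negative probabilities at ", p)
    if (abs(sum(pr) - 1) > 1e-9) stop("probabilities at ", p, " must sum to 1")
    if (!all(names(pr) %in% .AA20))
      stop("unknown residue code(s) at ", p, ": ",
           paste(setdiff(names(pr), .AA20), collapse = ","))
  }
  set.seed(seed)
  rec <- data.frame(substrate_id = sprintf("syn%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  truth <- numeric(0)
  for (p in names(dists)) {
    pr <- dists[[p]]
    rec[[p]] <- sample(names(pr), n, replace = TRUE, prob = pr)
    q <- pr[pr > 0]
    truth[p] <- -sum(q * log(q)) / log(20)
  }
  list(table = substrate_table(rec, positions = names(dists), source = source),
       truth = truth)
}

# ---- dihedral series --------------------------------------------------------

#' Generate torsion-angle series with von Mises(-mixture) dispersion
#'
#' Stands in for the torsion output of a long MD trajectory: each requested
#' series gets `M` i.i.d. draws from its von Mises mixture. Ground-truth
#' entropies are closed form for single components and high-resolution
#' quadrature of the analytic mixture density otherwise.
#'
#' @param specs named list: series name (conventionally `"phi <reskey>"` or
#'   `"psi <reskey>"`) -> either a single component `list(mean=, kappa=)` or
#'   a list of such components with `weight`s.
#' @param M number of frames (>= 2).
#' @param seed RNG seed.
#' @return list with `series` (named list of `DihedralSeries`) and `truth`
#'   (named numeric entropies, J/(mol K)).
#' @export
gen_dihedral_ensemble <- function(specs, M, seed = 1L) {
  if (M < 2L) stop("need M >= 2 frames")
  set.seed(seed)
  series <- list()
  truth <- numeric(0)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    comps <- if (!is.null(sp$kappa)) list(sp) else sp
    for (cmp in comps) if (cmp$kappa < 0) stop("kappa must be >= 0 in ", nm)
    vals <- .rvm_mixture(M, comps)
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    kind <- if (parts[1] %in% c("phi", "psi")) parts[1] else "phi"
    resid <- if (length(parts) > 1L) parts[2] else nm
    series[[nm]] <- structure(list(angle_kind = kind, residue = resid,
                                   values = vals),
                              class = "DihedralSeries")
    truth[nm] <- if (length(comps) == 1L) vonmises_entropy(comps[[1]]$kappa)
                 else vonmises_mixture_entropy(comps)
  }
  list(series = series, truth = truth)
}

# ---- coordinate ensembles ---------------------------------------------------

# NeRF atom placement: D bonded to C (length r), angle B-C-D = theta_deg,
# torsion A-B-C-D = chi_deg
.place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180; chi <- chi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  C + cbind(bc, m, n) %*% d2
}

#' Build an ideal backbone scaffold from torsions
#'
#' Places `N`, `CA`, `C` atoms for `n_residues` residues (chain `A`, glycine
#' names) with ideal bond lengths/angles and the requested phi/psi torsions
#' (omega fixed at 180, trans). Useful as a geometric fixture: recomputing
#' torsions from the built coordinates returns the inputs.
#'
#' @param n_residues number of residues.
#' @param phi,psi torsion angles in degrees; scalars are recycled. `phi[1]`
#'   and `psi[n]` are undefined on a chain and ignored.
#' @param chain chain identifier.
#' @return A single-frame `FrameEnsemble`.
#' @export
gen_backbone_scaffold <- function(n_residues, phi = -120, psi = 130,
                                  chain = "A") {
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  # ideal geometry (lengths in A, angles in degrees)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7
  coords <- matrix(0, nrow = 3L * n_residues, ncol = 3L)
  # first residue laid out in the xy-plane
  coords[1, ] <- c(0, 0, 0)                          # N1
  coords[2, ] <- c(b_NCa, 0, 0)                      # CA1
  th <- a_NCaC * pi / 180
  coords[3, ] <- coords[2, ] + b_CaC * c(-cos(th), sin(th), 0)  # C1
  for (i in seq_len(n_residues - 1L)) {
    Ni <- coords[3 * i - 2, ]; CAi <- coords[3 * i - 1, ]; Ci <- coords[3 * i, ]
    Nn <- .place_atom(Ni, CAi, Ci, b_CN, a_CaCN, psi[i])          # psi(i)
    CAn <- .place_atom(CAi, Ci, Nn, b_NCa, a_CNCa, 180)           # omega trans
    Cn <- .place_atom(Ci, Nn, CAn, b_CaC, a_NCaC, phi[i + 1L])    # phi(i+1)
    coords[3 * i + 1, ] <- Nn
    coords[3 * i + 2, ] <- CAn
    coords[3 * i + 3, ] <- Cn
  }
  atoms <- data.frame(
    elety = rep(c("N", "CA", "C"), n_residues),
    resid = "GLY",
    chain = chain,
    resno = rep(seq_len(n_residues), each = 3L),
    insert = "",
    elesy = rep(c("N", "C", "C"), n_residues),
    stringsAsFactors = FALSE)
  xyz <- array(0, dim = c(1L, nrow(atoms), 3L))
  xyz[1, , ] <- coords
  frame_ensemble(atoms, xyz)
}

# random rotation matrix from three uniforms (axis-angle, angle <= max_deg)
.rand_rotation <- function(max_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Generate a coordinate ensemble with planted per-residue fluctuations
#'
#' Builds an ideal extended backbone scaffold and, per frame, displaces every
#' atom of residue `i` independently by isotropic Gaussian noise with the
#' residue's standard deviation `sigma[i]` (per axis, Angstrom). Optionally a
#' random global rigid-body motion (rotation up to 15 degrees plus
#' translation up to 1 Angstrom) is applied per frame to verify that the
#' alignment step removes it. Ground truth for each residue's Calpha:
#' `MSF = 3 sigma^2`, `B = (8 pi^2 / 3) * 3 sigma^2`.
#'
#' @param sigma numeric vector of per-residue fluctuation standard deviations
#'   (Angstrom, one per residue, `>= 0`).
#' @param M number of frames.
#' @param seed RNG seed.
#' @param rigid_jitter add global rigid-body motion per frame (default FALSE).
#' @param chain chain identifier.
#' @return list with `ensemble` (`FrameEnsemble`), `truth` (data.frame:
#'   `residue`, `msf`, `bfactor`) and `anchors` (keys of zero-sigma
#'   residues, a rigid core suitable as alignment selection).
#' @export
gen_coordinate_ensemble <- function(sigma, M, seed = 1L, rigid_jitter = FALSE,
                                    chain = "A") {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (M < 1L) stop("need M >= 1 frames")
  set.seed(seed)
  nres <- length(sigma)
  scaffold <- gen_backbone_scaffold(nres, chain = chain)
  base <- scaffold$xyz[1, , ]
  natoms <- nrow(base)
  atom_sigma <- rep(sigma, each = 3L)   # N, CA, C share the residue sigma
  xyz <- array(0, dim = c(M, natoms, 3L))
  for (f in seq_len(M)) {
    disp <- matrix(stats::rnorm(natoms * 3L, sd = atom_sigma), natoms, 3L)
    fr <- base + disp
    if (rigid_jitter) {
      Rm <- .rand_rotation(15)
      tr <- stats::runif(3, -1, 1)
      ctr <- colMeans(base)
      fr <- sweep(sweep(fr, 2L, ctr) %*% t(Rm), 2L, ctr + tr, `+`)
    }
    xyz[f, , ] <- fr
  }
  ens <- frame_ensemble(scaffold$atoms, xyz)
  keys <- residue_keys(ens)
  truth <- data.frame(residue = keys, msf = 3 * sigma^2,
                      bfactor = (8 * pi^2 / 3) * 3 * sigma^2,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(ensemble = ens, truth = truth, anchors = keys[sigma == 0])
}

# ---- interface ensembles ----------------------------------------------------

#' Generate a toy protease-peptide complex with planted contacts and H-bonds
#'
#' A hexapeptide (chain `P`, residues 1..6 occupying positions P6..P1) lies
#' along the x-axis; for each pocket one protease residue (chain `E`) is
#' placed with a contact atom 3.2 Angstrom from the peptide residue (inside
#' the 3.5 Angstrom pocket cutoff) and a backbone carbonyl oxygen that
#' accepts a hydrogen bond from the peptide backbone N-H. Per frame and
#' pocket, the bond is present (N...O = 2.9 Angstrom, collinear) with
#' probability `q[pocket]`, otherwise broken (N...O = 5.5 Angstrom). One
#' additional protease residue is placed far from the peptide as a negative
#' control.
#'
#' @param q named numeric vector of bond probabilities in `[0, 1]`, names
#'   `S6..S1` (any subset; missing pockets get q = 0).
#' @param M number of frames.
#' @param seed RNG seed.
#' @return list with `ensemble` (`FrameEnsemble`), `pockets` (planted
#'   `SubPocketDefinition`), `position_map` (P-label -> peptide residue key),
#'   `peptide_chain` and `truth` (named numeric: planted occupancy per
#'   pocket).
#' @export
gen_interface_ensemble <- function(q, M, seed = 1L) {
  plabs <- paste0("S", 6:1)
  if (!all(names(q) %in% plabs))
    stop("unknown pocket label(s): ",
         paste(setdiff(names(q), plabs), collapse = ","))
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  qq <- stats::setNames(rep(0, 6L), plabs)
  qq[names(q)] <- q
  set.seed(seed)
  atoms <- NULL
  base <- NULL
  add <- function(elety, resid, chain, resno, elesy, x, y, z) {
    atoms <<- rbind(atoms, data.frame(elety = elety, resid = resid,
                                      chain = chain, resno = resno,
                                      insert = "", elesy = elesy,
                                      stringsAsFactors = FALSE))
    base <<- rbind(base, c(x, y, z))
  }
  # peptide: residue i at x = 5i; N-H points toward the protease (+y)
  for (i in 1:6) {
    x <- 5 * i
    add("N",  "GLY", "P", i, "N", x, 0, 0)
    add("H",  "GLY", "P", i, "H", x, 1.01, 0)
    add("CA", "GLY", "P", i, "C", x + 1.45, 0, 0)
    add("C",  "GLY", "P", i, "C", x + 2.40, 0, 0)
    add("O",  "GLY", "P", i, "O", x + 2.40, -1.23, 0)
  }
  # protease: one pocket residue per peptide residue + a far negative control
  for (i in 1:6) {
    x <- 5 * i
    rn <- 100 + i
    add("CB", "SER", "E", rn, "C", x, 3.2, 0)        # contact marker
    add("O",  "SER", "E", rn, "O", x, 2.9, 0)        # planted acceptor
    add("CA", "SER", "E", rn, "C", x, 3.9, 0.8)
    add("N",  "SER", "E", rn, "N", x - 1, 3.5, 1.0)
    add("C",  "SER", "E", rn, "C", x, 4.6, 1.4)
  }
  add("CA", "ALA", "E", 300, "C", 12, 9, 0)
  add("O",  "ALA", "E", 300, "O", 13, 9, 0)
  # peptide residue i occupies position P(7-i): P6 -> P:1, ..., P1 -> P:6
  position_map <- stats::setNames(paste0("P:", 1:6), paste0("P", 6:1))
  pocket_of_pep <- stats::setNames(sub("^P", "S", names(position_map)),
                                   1:6)                      # "1" -> "S6", ...
  xyz <- array(0, dim = c(M, nrow(atoms), 3L))
  bonded <- matrix(FALSE, nrow = M, ncol = 6L,
                   dimnames = list(NULL, plabs))
  for (i in 1:6) {
    slab <- pocket_of_pep[[as.character(i)]]
    bonded[, slab] <- stats::runif(M) < qq[slab]
  }
  for (f in seq_len(M)) {
    fr <- base
    for (i in 1:6) {
      slab <- pocket_of_pep[[as.character(i)]]
      if (!bonded[f, slab]) {
        oi <- which(atoms$chain == "E" & atoms$resno == 100 + i &
                      atoms$elety == "O")
        fr[oi, 2] <- 5.5
      }
    }
    xyz[f, , ] <- fr
  }
  ens <- frame_ensemble(atoms, xyz)
  # protease residue E:(100+i) sits at peptide residue i, hence pocket S(7-i)
  pockets <- subpocket_definition(
    stats::setNames(lapply(1:6, function(i) paste0("E:", 100 + i)), plabs),
    source = "planted toy complex")
  list(ensemble = ens, pockets = pockets, position_map = position_map,
       peptide_chain = "P", truth = qq)
}

# ---- packaged scenario ------------------------------------------------------

#' A "thrombin-like" synthetic scenario with concordant specificity and
#' flexibility orderings
#'
#' Plants six sub-pockets whose substrate readout and backbone flexibility
#' increase together from S1 (rigid, specific) to S6 (flexible, unspecific):
#' positional residue distributions with strictly increasing normalized
#' entropies P1 < P2 < ... < P6, per-residue Calpha fluctuations increasing
#' S1 -> S6, torsion concentrations decreasing S1 -> S6, and a non-monotone
#' hydrogen-bond pattern (S1 strong, S6 moderate, S3 partial, S2/S4/S5
#' absent or rare). All ground truth is returned alongside the data.
#'
#' @param seed RNG seed (sub-seeds are derived per generator).
#' @param frames number of ensemble frames (default 20000).
#' @param substrates number of substrates (default 1000).
#' @return list with components `substrates` (table + truth), `dihedrals`
#'   (series + truth), `coordinates` (ensemble + truth + anchors),
#'   `interface` (complex + planted pockets + truth), `pockets`
#'   (`SubPocketDefinition` over the coordinate scaffold) and `params`.
#' @export
thrombin_like_scenario <- function(seed = 1L, frames = 20000L,
                                   substrates = 1000L) {
  plabs <- paste0("S", 1:6)
  # substrate positional distributions: P1 near-point, P2 moderate,
  # P3..P6 uniform blended with a decreasing point-mass weight
  u20 <- stats::setNames(rep(1 / 20, 20), .AA20)
  blend <- function(w) {
    p <- (1 - w) * u20
    p["R"] <- p["R"] + w
    p
  }
  dists <- list(P1 = c(R = 0.9, K = 0.1),
                P2 = c(P = 0.55, G = 0.20, A = 0.15, S = 0.10),
                P3 = blend(0.30), P4 = blend(0.22),
                P5 = blend(0.15), P6 = blend(0.07))
  dists <- dists[paste0("P", 6:1)]
  sub <- gen_substrate_table(dists, n = substrates, seed = seed,
                             source = sprintf("thrombin-like scenario seed %d",
                                              seed))
  # scaffold: residues 1..6 rigid anchors, then three residues per pocket
  sigma_pocket <- stats::setNames(c(0.15, 0.25, 0.35, 0.45, 0.55, 0.65), plabs)
  kappa_pocket <- stats::setNames(c(60, 25, 10, 6, 3, 1.2), plabs)
  sigma <- c(rep(0, 6L), rep(sigma_pocket, each = 3L))
  coords <- gen_coordinate_ensemble(sigma, M = frames, seed = seed + 1L,
                                    rigid_jitter = TRUE)
  keys <- residue_keys(coords$ensemble)
  pockets <- subpocket_definition(
    stats::setNames(lapply(seq_along(plabs), function(j)
      keys[6L + (j - 1L) * 3L + 1:3]), plabs),
    source = "thrombin-like scenario scaffold")
  specs <- list()
  for (j in seq_along(plabs)) {
    for (k in pockets$pockets[[plabs[j]]]) {
      specs[[paste("phi", k)]] <- list(mean = -57, kappa = kappa_pocket[[j]])
      specs[[paste("psi", k)]] <- list(mean = -47, kappa = kappa_pocket[[j]])
    }
  }
  dih <- gen_dihedral_ensemble(specs, M = frames, seed = seed + 2L)
  qh <- c(S1 = 0.95, S2 = 0, S3 = 0.35, S4 = 0, S5 = 0.05, S6 = 0.60)
  iface <- gen_interface_ensemble(qh, M = min(frames, 5000L), seed = seed + 3L)
  list(substrates = sub, dihedrals = dih, coordinates = coords,
       interface = iface, pockets = pockets,
       params = list(seed = seed, frames = frames, substrates = substrates,
                     sigma_pocket = sigma_pocket,
                     kappa_pocket = kappa_pocket, hbond_q = qh))
}

#' Write a synthetic scenario to disk
#'
#' Emits the substrate table (CSV), the coordinate and interface ensembles
#' (multi-model PDB), one residue-set file per pocket, and a ground-truth
#' JSON next to the data files.
#'
#' @param scenario output of [thrombin_like_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scenario$substrates$table$records,
                   file.path(dir, "substrates.csv"), row.names = FALSE)
  write_multimodel_pdb(scenario$coordinates$ensemble,
                       file.path(dir, "coordinates.pdb"))
  write_multimodel_pdb(scenario$interface$ensemble,
                       file.path(dir, "interface.pdb"))
  write_subpockets(scenario$pockets, file.path(dir, "pockets"))
  jsonlite::write_json(
    list(substrate_entropy = as.list(scenario$substrates$truth),
         dihedral_entropy = as.list(scenario$dihedrals$truth),
         bfactor = scenario$coordinates$truth,
         hbond_occupancy = as.list(scenario$interface$truth),
         params = list(seed = scenario$params$seed,
                       frames = scenario$params$frames,
                       substrates = scenario$params$substrates)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
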