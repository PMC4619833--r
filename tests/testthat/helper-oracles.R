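# Independent oracles used by the tests. These deliberately avoid the code
# paths they check (no SVD Kabsch, no rank()/cor(), no vectorized distance
# scan).

# --- quaternion-search RMSD oracle ------------------------------------------

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimal RMSD between point sets by quaternion grid search with local
# refinement (Nelder-Mead over the quaternion components)
oracle_min_rmsd <- function(P, Q, n_starts = 30L) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  obj <- function(q) {
    R <- .quat_to_rot(q)
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  starts <- rbind(c(1, 0, 0, 0),
                  matrix(stats::rnorm(4 * n_starts), ncol = 4))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  best
}

# --- midrank Spearman oracle -------------------------------------------------

# midranks by explicit counting: rank_i = #{x_j < x_i} + (#{x_j == x_i} + 1)/2
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; eq <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) eq <- eq + 1
    }
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Pearson correlation from explicit sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))
}

# --- brute-force contact scan ------------------------------------------------

# all protease residues with any atom within cutoff of any atom of the given
# peptide residue, by explicit double loop over atoms
oracle_contacts <- function(ensemble, peptide_chain, pep_key, cutoff,
                            frame = 1L) {
  akeys <- atom_residue_keys(ensemble)
  xyz <- ensemble$xyz[frame, , ]
  pep <- which(ensemble$atoms$chain == peptide_chain & akeys == pep_key)
  prot <- which(ensemble$atoms$chain != peptide_chain)
  hits <- character(0)
  for (i in prot) {
    for (j in pep) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff) { hits <- c(hits, akeys[i]); break }
    }
  }
  unique(hits)
}

# --- small geometry builders -------------------------------------------------

# a FrameEnsemble from a list of frames, each a data.frame with columns
# elety, resid, chain, resno, elesy, x, y, z (atom table from frame 1)
make_ensemble <- function(frames) {
  a1 <- frames[[1]]
  atoms <- data.frame(elety = a1$elety, resid = a1$resid, chain = a1$chain,
                      resno = a1$resno, insert = "", elesy = a1$elesy,
                      stringsAsFactors = FALSE)
  xyz <- array(0, dim = c(length(frames), nrow(a1), 3))
  for (f in seq_along(frames))
    xyz[f, , ] <- as.matrix(frames[[f]][, c("x", "y", "z")])
  frame_ensemble(atoms, xyz)
}

atom_row <- function(elety, elesy, chain, resno, x, y, z, resid = "GLY") {
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             elesy = elesy, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# concatenate block ensembles back into one coordinate array (frame-major)
abind_frames <- function(blocks) {
  m <- sum(vapply(blocks, n_frames, integer(1)))
  out <- array(0, dim = c(m, dim(blocks[[1]]$xyz)[2], 3))
  at <- 1L
  for (b in blocks) {
    out[at:(at + n_frames(b) - 1L), , ] <- b$xyz
    at <- at + n_frames(b)
  }
  out
}

RGAS <- 8.314462618
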