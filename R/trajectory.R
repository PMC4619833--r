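# Conformational-ensemble container and I/O.
#
# A FrameEnsemble stores an M x N x 3 coordinate array (Angstrom) plus an
# atom table (one row per atom: name, residue, chain, residue number,
# insertion code, element). Residue identity is always the
# (chain, number, insertion code) triple -- serine-protease numbering
# (chymotrypsinogen scheme) uses insertion codes such as 60A, so a bare
# residue number is ambiguous.

#' Construct a FrameEnsemble
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno` (integer), `insert`
#'   (insertion code, `""` if none) and `elesy` (element symbol).
#' @param xyz numeric array of dimension `c(M, N, 3)` with coordinates in
#'   Angstrom (M frames, N atoms), or an `M x 3N` matrix which is reshaped.
#' @param frame_labels optional vector of length M (e.g. time stamps).
#'
#' @return An object of class `FrameEnsemble`.
#' @export
frame_ensemble <- function(atoms, xyz, frame_labels = NULL) {
  req <- c("elety", "resid", "chain", "resno", "insert", "elesy")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.matrix(xyz)) {
    if (ncol(xyz) != 3L * nrow(atoms))
      stop("xyz matrix has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms))
    m <- nrow(xyz)
    xyz <- aperm(array(t(xyz), dim = c(3L, nrow(atoms), m)), c(3L, 2L, 1L))
  }
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != nrow(atoms) || dim(xyz)[3] != 3L)
    stop("xyz must be an M x N x 3 array matching the atom table")
  if (dim(xyz)[1] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(xyz))) stop("coordinates contain non-finite values")
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$chain  <- as.character(atoms$chain)
  if (!is.null(frame_labels) && length(frame_labels) != dim(xyz)[1])
    stop("frame_labels length must equal the number of frames")
  structure(list(atoms = atoms, xyz = xyz, frame_labels = frame_labels),
            class = "FrameEnsemble")
}

#' @export
print.FrameEnsemble <- function(x, ...) {
  cat(sprintf("FrameEnsemble: %d frame(s), %d atoms, %d residues\n",
              n_frames(x), n_atoms(x), length(residue_keys(x))))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a `FrameEnsemble`
#' @return integer count
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$xyz)[2]

#' Residue keys
#'
#' A residue key is the string `"<chain>:<resno><insert>"`, e.g. `"H:195"` or
#' `"H:60A"`. Keys identify residues everywhere in the package.
#'
#' @param ensemble a `FrameEnsemble`
#' @return `atom_residue_keys`: character vector, one key per atom;
#'   `residue_keys`: unique keys in order of first appearance.
#' @export
atom_residue_keys <- function(ensemble) {
  a <- ensemble$atoms
  paste0(a$chain, ":", a$resno, a$insert)
}

#' @rdname atom_residue_keys
#' @export
residue_keys <- function(ensemble) unique(atom_residue_keys(ensemble))

# scan a PDB file for per-MODEL atom counts (0 models = single block)
.scan_model_counts <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_at <- which(startsWith(lines, "MODEL"))
  if (length(model_at) == 0L) return(sum(is_atom))
  endmdl_at <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl_at) != length(model_at))
    stop("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(model_at), function(i)
    sum(is_atom[model_at[i]:endmdl_at[i]]), integer(1))
}

#' Read a multi-model PDB file as a FrameEnsemble
#'
#' Each MODEL becomes one frame; a file without MODEL records yields a
#' single-frame ensemble. Parsing is done with \code{bio3d::read.pdb}.
#' Alternate-location atoms other than blank/'A' are dropped with a warning;
#' a missing element column is inferred from the atom name with a warning.
#'
#' @param path path to a PDB file.
#' @return A `FrameEnsemble`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  counts <- .scan_model_counts(lines)
  if (length(counts) > 1L && length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("model %d has %d atoms but model 1 has %d atoms",
                 bad, counts[bad], counts[1]))
  }
  if (sum(counts) == 0L) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  if (!all(keep)) {
    warning(sum(!keep), " alternate-location atom(s) dropped (altLoc not ''/'A')")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx3 <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                          3L * which(keep)))
  xyz <- xyz[, idx3, drop = FALSE]
  a <- a[keep, , drop = FALSE]
  ele <- a$elesy
  if (any(is.na(ele) | ele == "")) {
    warning("element column missing for some atoms; inferred from atom names")
    guess <- sub("^[0-9]*", "", a$elety)
    guess <- substr(guess, 1L, 1L)
    ele <- ifelse(is.na(ele) | ele == "", guess, ele)
  }
  atoms <- data.frame(elety = a$elety, resid = a$resid, chain = a$chain,
                      resno = a$resno, insert = a$insert, elesy = ele,
                      stringsAsFactors = FALSE)
  frame_ensemble(atoms, xyz)
}

#' Write a FrameEnsemble as a multi-model PDB file
#'
#' Coordinates are written at PDB precision (3 decimals); round-tripping
#' through [read_multimodel_pdb()] preserves coordinates to 1e-3 Angstrom.
#'
#' @param ensemble a `FrameEnsemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  m <- n_frames(ensemble)
  xyz <- matrix(aperm(ensemble$xyz, c(3L, 2L, 1L)), nrow = m, byrow = TRUE)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elesy = a$elesy)
  invisible(path)
}

#' Select atoms with a small query grammar
#'
#' The query is a conjunction of clauses joined by `" and "`. Each clause is
#' a keyword followed by one or more values:
#' \describe{
#'   \item{`name V...`}{atom name, e.g. `name CA` or `name N CA C`}
#'   \item{`chain V...`}{chain identifier}
#'   \item{`resid V...`}{residue number with optional insertion code,
#'     e.g. `resid 60A` (chain-agnostic)}
#'   \item{`reskey V...`}{full residue key, e.g. `reskey H:60A`}
#'   \item{`element V...`}{element symbol}
#' }
#' Selection is deterministic and order-preserving (topology order). An empty
#' result is allowed but reported with a warning.
#'
#' @param ensemble a `FrameEnsemble`.
#' @param query selection string.
#' @return An `AtomSelection`: list with `indices` (integer) and
#'   `description` (the query).
#' @export
select_atoms <- function(ensemble, query) {
  a <- ensemble$atoms
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(a))
  for (ci in seq_along(clauses)) {
    tok <- strsplit(trimws(clauses[ci]), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop(sprintf("selection syntax error in clause %d ('%s'): expected 'keyword value...'",
                   ci, clauses[ci]))
    key <- tok[1]; vals <- tok[-1]
    hit <- switch(key,
      name    = a$elety %in% vals,
      chain   = a$chain %in% vals,
      resid   = paste0(a$resno, a$insert) %in% vals,
      reskey  = atom_residue_keys(ensemble) %in% vals,
      element = a$elesy %in% vals,
      stop(sprintf("selection syntax error in clause %d: unknown keyword '%s'",
                   ci, key))
    )
    keep <- keep & hit
  }
  idx <- which(keep)
  if (length(idx) == 0L) warning("selection '", query, "' matched no atoms")
  structure(list(indices = idx, description = query), class = "AtomSelection")
}

#' Build an AtomSelection from residue keys
#'
#' @param ensemble a `FrameEnsemble`.
#' @param keys character vector of residue keys (`"H:60A"` style).
#' @param name optional atom-name filter (e.g. `"CA"`); `NULL` keeps all atoms
#'   of the listed residues.
#' @return An `AtomSelection`.
#' @export
select_residues <- function(ensemble, keys, name = NULL) {
  keep <- atom_residue_keys(ensemble) %in% keys
  if (!is.null(name)) keep <- keep & ensemble$atoms$elety %in% name
  idx <- which(keep)
  if (length(idx) == 0L) warning("residue-key selection matched no atoms")
  structure(list(indices = idx,
                 description = paste0("reskey ", paste(keys, collapse = " "),
                                      if (!is.null(name)) paste0(" and name ", name) else "")),
            class = "AtomSelection")
}

#' Read / write residue-set files
#'
#' Plain text, one residue key per line (`"H:60A"`); blank lines and lines
#' starting with `#` are ignored on read.
#'
#' @param path file path.
#' @return `read_residue_set`: character vector of residue keys.
#' @export
read_residue_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (any(!grepl("^[^:]+:[0-9]+[A-Za-z]?$", x)))
    stop("malformed residue key(s) in ", path)
  x
}

#' @rdname read_residue_set
#' @param keys character vector of residue keys to write.
#' @export
write_residue_set <- function(keys, path) {
  writeLines(keys, path)
  invisible(path)
}

#' Split an ensemble into contiguous frame blocks
#'
#' Frames are divided into `k` contiguous blocks of equal size
#' `floor(M / k)`; remainder frames are appended to the last block, so the
#' concatenation of the blocks reproduces the original frame order.
#'
#' @param ensemble a `FrameEnsemble` with `M` frames.
#' @param k number of blocks, `1 <= k <= M`.
#' @return list of `k` `FrameEnsemble`s.
#' @export
split_blocks <- function(ensemble, k) {
  m <- n_frames(ensemble)
  if (k < 1L) stop("k must be >= 1")
  if (k > m) stop("cannot split ", m, " frame(s) into ", k, " blocks")
  size <- m %/% k
  starts <- (seq_len(k) - 1L) * size + 1L
  ends <- starts + size - 1L
  ends[k] <- m
  lapply(seq_len(k), function(i) subset_frames(ensemble, starts[i]:ends[i]))
}

#' Extract a subset of frames
#' @param ensemble a `FrameEnsemble`.
#' @param frames integer vector of frame indices (1-based).
#' @return A `FrameEnsemble` with the selected frames.
#' @export
subset_frames <- function(ensemble, frames) {
  frame_ensemble(ensemble$atoms,
                 ensemble$xyz[frames, , , drop = FALSE],
                 ensemble$frame_labels[frames])
}
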