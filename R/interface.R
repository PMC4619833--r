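# Protease-peptide interface analysis.
#
# Sub-pockets S6..S1 are defined from a complex structure by proximity: every
# protease residue with at least one atom (hydrogens included) within a
# cutoff (default 3.5 Angstrom) of any atom of the peptide residue occupying
# position Pn belongs to pocket Sn. Hydrogen bonds between protease and
# peptide are scored per frame with the common geometric criteria: heavy-atom
# donor-acceptor distance <= 3.0 Angstrom and a donor-hydrogen-acceptor
# deviation from linearity <= 45 degrees (i.e. D-H...A angle >= 135 deg).
# Pocket occupancy is the ensemble-average *count* of such bonds per frame
# attributed to the pocket's protease residues, so values above 1 indicate
# multiple simultaneous hydrogen bonds.

#' Hydrogen-bond criteria
#'
#' @param max_heavy_distance maximum donor--acceptor heavy-atom distance in
#'   Angstrom (default 3.0).
#' @param max_dha_deviation maximum deviation of the donor-hydrogen-acceptor
#'   angle from linearity, in degrees (default 45; i.e. the D-H...A angle must
#'   be at least 135 degrees).
#' @return An `HBondCriteria` object.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.0, max_dha_deviation = 45) {
  if (max_heavy_distance <= 0 || max_dha_deviation <= 0)
    stop("hydrogen-bond criteria must be strictly positive")
  structure(list(max_heavy_distance = max_heavy_distance,
                 max_dha_deviation = max_dha_deviation),
            class = "HBondCriteria")
}

#' Define sub-pockets from a protease-peptide complex
#'
#' Pocket `Sn` collects every protease residue having at least one atom
#' within `cutoff` of at least one atom of the peptide residue mapped to
#' `Pn`. Hydrogens participate in the distance scan. A single structure is
#' used; for an ensemble this is the first frame.
#'
#' @param complex a `FrameEnsemble` containing protease and peptide.
#' @param peptide_chain chain identifier of the peptide.
#' @param position_map named character vector: P-label -> peptide residue key,
#'   e.g. `c(P6 = "P:1", ..., P1 = "P:6")`.
#' @param cutoff contact radius in Angstrom (default 3.5).
#' @param frame frame index used for the scan (default 1).
#' @return A `SubPocketDefinition`: list with `pockets` (named list, pocket
#'   label `Sn` -> character vector of protease residue keys), `empty`
#'   (logical flags) and `source`.
#' @export
define_subpockets <- function(complex, peptide_chain, position_map,
                              cutoff = 3.5, frame = 1L) {
  stopifnot(inherits(complex, "FrameEnsemble"))
  akeys <- atom_residue_keys(complex)
  pep_atoms <- which(complex$atoms$chain == peptide_chain)
  prot_atoms <- which(complex$atoms$chain != peptide_chain)
  if (length(pep_atoms) == 0L || length(prot_atoms) == 0L)
    stop("complex must contain both peptide ('", peptide_chain,
         "') and protease atoms")
  xyz <- .frame_coords(complex, frame)
  pockets <- list()
  empty <- logical(0)
  for (plab in names(position_map)) {
    pkey <- position_map[[plab]]
    pa <- pep_atoms[akeys[pep_atoms] == pkey]
    if (length(pa) == 0L)
      stop("peptide residue ", pkey, " (", plab, ") absent from the complex")
    slab <- sub("^P", "S", plab)
    # min distance from each protease atom to any atom of this peptide residue
    d2min <- rep(Inf, length(prot_atoms))
    for (j in pa) {
      dx <- xyz[prot_atoms, 1] - xyz[j, 1]
      dy <- xyz[prot_atoms, 2] - xyz[j, 2]
      dz <- xyz[prot_atoms, 3] - xyz[j, 3]
      d2min <- pmin(d2min, dx * dx + dy * dy + dz * dz)
    }
    hit <- unique(akeys[prot_atoms[d2min <= cutoff^2]])
    if (length(hit) == 0L)
      warning("pocket ", slab, " is empty at cutoff ", cutoff, " Angstrom")
    pockets[[slab]] <- hit
    empty[slab] <- length(hit) == 0L
  }
  structure(list(pockets = pockets, empty = empty,
                 source = sprintf("distance cutoff %.2f A, frame %d", cutoff,
                                  frame)),
            class = "SubPocketDefinition")
}

#' @export
print.SubPocketDefinition <- function(x, ...) {
  cat("SubPocketDefinition (", x$source, "):\n", sep = "")
  for (p in names(x$pockets))
    cat(sprintf("  %s: %s\n", p,
                if (length(x$pockets[[p]])) paste(x$pockets[[p]], collapse = " ")
                else "<empty>"))
  invisible(x)
}

#' Construct a SubPocketDefinition directly
#' @param pockets named list: pocket label -> character vector of residue keys.
#' @param source provenance string.
#' @return A `SubPocketDefinition`.
#' @export
subpocket_definition <- function(pockets, source = "manual") {
  structure(list(pockets = pockets,
                 empty = vapply(pockets, function(p) length(p) == 0L, logical(1)),
                 source = source),
            class = "SubPocketDefinition")
}

#' Merge two sub-pocket definitions (per-pocket set union)
#'
#' Used to unify pocket definitions derived from different complex
#' structures into one common binding-site definition.
#'
#' @param a,b `SubPocketDefinition`s over the same pocket labels.
#' @return A `SubPocketDefinition` whose pockets are the per-label unions;
#'   provenance strings are concatenated.
#' @export
merge_definitions <- function(a, b) {
  stopifnot(inherits(a, "SubPocketDefinition"), inherits(b, "SubPocketDefinition"))
  if (!setequal(names(a$pockets), names(b$pockets)))
    stop("pocket label sets differ: ",
         paste(names(a$pockets), collapse = ","), " vs ",
         paste(names(b$pockets), collapse = ","))
  pockets <- lapply(stats::setNames(names(a$pockets), names(a$pockets)),
                    function(p) union(a$pockets[[p]], b$pockets[[p]]))
  subpocket_definition(pockets, source = paste(a$source, b$source, sep = " + "))
}

# donor heavy atoms (N/O with a covalently bound H, <= 1.2 A in the given
# frame) with their hydrogens; returns data.frame(d, h)
.find_donors <- function(ensemble, atoms_subset, frame = 1L) {
  a <- ensemble$atoms
  xyz <- .frame_coords(ensemble, frame)
  heavies <- atoms_subset[a$elesy[atoms_subset] %in% c("N", "O")]
  hydros <- atoms_subset[a$elesy[atoms_subset] == "H"]
  if (length(heavies) == 0L || length(hydros) == 0L)
    return(data.frame(d = integer(0), h = integer(0)))
  out_d <- integer(0); out_h <- integer(0)
  for (d in heavies) {
    dd <- sqrt(rowSums(sweep(xyz[hydros, , drop = FALSE], 2L, xyz[d, ])^2))
    bonded <- hydros[dd <= 1.2]
    if (length(bonded) > 0L) {
      out_d <- c(out_d, rep(d, length(bonded)))
      out_h <- c(out_h, bonded)
    }
  }
  data.frame(d = out_d, h = out_h)
}

#' Protease-peptide hydrogen-bond occupancy per sub-pocket
#'
#' Per frame, every protease--peptide donor/acceptor pair satisfying the
#' geometric criteria is counted (donors: N/O with a bound hydrogen,
#' inferred by an H within 1.2 Angstrom; acceptors: N/O; both directions
#' across the interface). Each bond is attributed to the pocket(s) containing
#' the protease residue involved; the pocket value is the mean count per
#' frame, so it can exceed 1 when several bonds form simultaneously.
#'
#' @param ensemble a `FrameEnsemble` of the complex including hydrogens.
#' @param pockets a `SubPocketDefinition`.
#' @param peptide_chain chain identifier of the peptide.
#' @param criteria an `HBondCriteria` (default: 3.0 Angstrom / 45 degrees).
#' @return A `PocketMetricTable` (see [pocket_metric_table()]) of mean
#'   hydrogen-bond counts per frame, with a `per_frame` attribute
#'   (pockets x frames count matrix).
#' @export
hbond_occupancy <- function(ensemble, pockets, peptide_chain,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(pockets, "SubPocketDefinition"),
            inherits(criteria, "HBondCriteria"))
  a <- ensemble$atoms
  akeys <- atom_residue_keys(ensemble)
  pep <- which(a$chain == peptide_chain)
  prot <- which(a$chain != peptide_chain)
  don_prot <- .find_donors(ensemble, prot)
  don_pep <- .find_donors(ensemble, pep)
  if (nrow(don_prot) + nrow(don_pep) == 0L)
    stop("no polar hydrogens found on either side of the interface; ",
         "is the input protonated?")
  acc_prot <- prot[a$elesy[prot] %in% c("N", "O")]
  acc_pep <- pep[a$elesy[pep] %in% c("N", "O")]
  # candidate triples (donor heavy, hydrogen, acceptor) across the interface
  triples <- rbind(
    if (nrow(don_prot) > 0L && length(acc_pep) > 0L)
      cbind(don_prot[rep(seq_len(nrow(don_prot)), each = length(acc_pep)), ],
            acc = rep(acc_pep, times = nrow(don_prot)), prot_is_donor = TRUE),
    if (nrow(don_pep) > 0L && length(acc_prot) > 0L)
      cbind(don_pep[rep(seq_len(nrow(don_pep)), each = length(acc_prot)), ],
            acc = rep(acc_prot, times = nrow(don_pep)), prot_is_donor = FALSE))
  m <- n_frames(ensemble)
  plabs <- names(pockets$pockets)
  counts <- matrix(0, nrow = length(plabs), ncol = m,
                   dimnames = list(plabs, NULL))
  if (!is.null(triples) && nrow(triples) > 0L) {
    # the protease residue owning each candidate bond
    prot_res <- ifelse(triples$prot_is_donor, akeys[triples$d],
                       akeys[triples$acc])
    dvec <- function(i, j) ensemble$xyz[, i, , drop = FALSE] -
                           ensemble$xyz[, j, , drop = FALSE]
    for (t in seq_len(nrow(triples))) {
      da <- dvec(triples$d[t], triples$acc[t]); dim(da) <- c(m, 3L)
      hd <- dvec(triples$d[t], triples$h[t]);  dim(hd) <- c(m, 3L)
      ha <- dvec(triples$acc[t], triples$h[t]); dim(ha) <- c(m, 3L)
      dist_da <- sqrt(rowSums(da^2))
      cosang <- rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
      cosang <- pmin(1, pmax(-1, cosang))
      dha <- acos(cosang) * 180 / pi          # angle at H between D and A
      bonded <- dist_da <= criteria$max_heavy_distance &
        (180 - dha) <= criteria$max_dha_deviation
      if (!any(bonded)) next
      for (p in plabs) {
        if (prot_res[t] %in% pockets$pockets[[p]])
          counts[p, ] <- counts[p, ] + as.numeric(bonded)
      }
    }
  }
  vals <- rowMeans(counts)
  out <- pocket_metric_table(stats::setNames(as.numeric(vals), plabs),
                             metric_name = "hbond_occupancy",
                             n_residues = lengths(pockets$pockets))
  attr(out, "per_frame") <- counts
  out
}

#' Construct a PocketMetricTable
#'
#' @param values named numeric vector: pocket label -> value (`NA` for a
#'   pocket without coverage).
#' @param metric_name name of the metric.
#' @param n_residues optional named integer vector of contributing residue
#'   counts.
#' @return A `PocketMetricTable` data.frame with columns `pocket`, `value`,
#'   `n_residues`, `flagged` (TRUE where no value could be computed).
#' @export
pocket_metric_table <- function(values, metric_name = "metric",
                                n_residues = NULL) {
  out <- data.frame(pocket = names(values), value = as.numeric(values),
                    n_residues = if (is.null(n_residues)) NA_integer_
                                 else as.integer(n_residues[names(values)]),
                    flagged = !is.finite(as.numeric(values)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("PocketMetricTable", "data.frame")
  out
}

#' Pocket-wise arithmetic averages of a residue-wise metric
#'
#' Each pocket value is the unweighted arithmetic mean of the metric over the
#' pocket's residues; residues belonging to several pockets contribute to
#' each of them. A pocket none of whose residues carries a value is flagged
#' (`NA`), never silently zero.
#'
#' @param metric named numeric vector: residue key -> value.
#' @param pockets a `SubPocketDefinition`.
#' @param metric_name stored metric name.
#' @return A `PocketMetricTable`.
#' @export
pocket_average <- function(metric, pockets, metric_name = "metric") {
  stopifnot(inherits(pockets, "SubPocketDefinition"))
  vals <- vapply(names(pockets$pockets), function(p) {
    keys <- intersect(pockets$pockets[[p]], names(metric))
    v <- metric[keys]
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  covered <- vapply(names(pockets$pockets), function(p)
    sum(is.finite(metric[intersect(pockets$pockets[[p]], names(metric))])),
    numeric(1))
  if (any(!is.finite(vals)))
    warning("pocket(s) without metric coverage flagged: ",
            paste(names(vals)[!is.finite(vals)], collapse = ", "))
  pocket_metric_table(vals, metric_name = metric_name, n_residues = covered)
}

#' Serialize a SubPocketDefinition
#'
#' Writes one residue-set file per pocket (`<prefix>_<pocket>.txt`, the plain
#' residue-key format of [read_residue_set()]) plus `<prefix>.json` carrying
#' the full definition with provenance.
#'
#' @param pockets a `SubPocketDefinition`.
#' @param prefix output path prefix.
#' @return The JSON path, invisibly.
#' @export
write_subpockets <- function(pockets, prefix) {
  for (p in names(pockets$pockets))
    write_residue_set(pockets$pockets[[p]], paste0(prefix, "_", p, ".txt"))
  jpath <- paste0(prefix, ".json")
  jsonlite::write_json(list(pockets = pockets$pockets, source = pockets$source),
                       jpath, auto_unbox = TRUE)
  invisible(jpath)
}
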