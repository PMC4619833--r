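# Rank correlation of specificity against flexibility, difference maps and
# block-convergence diagnostics.
#
# Pocket-level aggregates (typically n = 6 pockets, S6..S1) are compared by
# Spearman's rank correlation: rho is the Pearson correlation of the midrank
# vectors, which reduces to 1 - 6*sum(d^2)/(n(n^2-1)) in the absence of
# ties. With n = 6 the closed form gives, e.g., rho = 1 - 24/210 = 0.886 for
# a total squared rank displacement of 4.

#' Spearman rank correlation with midranks
#'
#' Pairs with a missing value in either vector are dropped (pairwise
#' deletion) and the effective `n` is reported. Ties receive midranks. If
#' either vector has zero rank variance the coefficient is undefined and
#' returned as `NA` (not 0).
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_p if `TRUE` and `n <= 8`, an exact permutation p-value
#'   (two-sided, over all `n!` rank permutations) is attached.
#' @return A `SpearmanResult`: list with `rho`, `n`, `ranks_x`, `ranks_y`
#'   and `p_value` (`NA` unless requested).
#' @export
spearman_rho <- function(x, y, exact_p = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs (have ", n, ")")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    rho <- NA_real_
  } else {
    rho <- stats::cor(rx, ry)
  }
  pv <- NA_real_
  if (exact_p && !is.na(rho)) {
    if (n > 8L) stop("exact permutation p-value limited to n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    pv <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  structure(list(rho = rho, n = n, ranks_x = rx, ranks_y = ry, p_value = pv),
            class = "SpearmanResult")
}

# all permutations of 1..n as a matrix (n! rows)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(n)
      row[k] <- n
      row[-k] <- sub[i, ]
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

#' @export
print.SpearmanResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %s (n = %d)%s\n",
              if (is.na(x$rho)) "undefined (zero rank variance)"
              else sprintf("%.4f", x$rho),
              x$n,
              if (!is.na(x$p_value)) sprintf(", exact p = %.4f", x$p_value)
              else ""))
  invisible(x)
}

#' Correlate pocket-wise specificity against flexibility metrics
#'
#' Maps the position-wise cleavage entropies onto pockets (`Pn -> Sn`) and
#' computes one Spearman correlation per supplied metric table. Pockets with
#' a missing metric value are excluded pairwise; metrics with fewer than 3
#' complete pairs are skipped with a warning.
#'
#' @param specificity a `SpecificityProfile`, or a named numeric vector of
#'   cleavage entropies keyed by pocket label (`S6`..`S1`).
#' @param metrics named list of `PocketMetricTable`s (or named numeric
#'   vectors keyed by pocket label).
#' @param exact_p passed to [spearman_rho()].
#' @return A `SpecificityFlexibilityReport`: list with `pocket_table`
#'   (pockets x metrics data.frame, cleavage entropy first) and
#'   `correlations` (named list of `SpearmanResult`).
#' @export
correlate_specificity <- function(specificity, metrics, exact_p = FALSE) {
  if (inherits(specificity, "SpecificityProfile")) {
    ent <- specificity$entropy_by_position
    names(ent) <- sub("^P", "S", names(ent))
  } else ent <- specificity
  if (is.null(names(ent))) stop("specificity must be named by pocket label")
  as_vec <- function(m) {
    if (inherits(m, "PocketMetricTable") || is.data.frame(m))
      stats::setNames(m$value, m$pocket)
    else m
  }
  pockets <- names(ent)
  tab <- data.frame(pocket = pockets, cleavage_entropy = as.numeric(ent),
                    row.names = NULL, stringsAsFactors = FALSE)
  correlations <- list()
  for (mn in names(metrics)) {
    v <- as_vec(metrics[[mn]])[pockets]
    tab[[mn]] <- as.numeric(v)
    n_ok <- sum(is.finite(v) & is.finite(ent))
    if (n_ok < 3L) {
      warning("metric '", mn, "' skipped: only ", n_ok, " complete pocket pair(s)")
      next
    }
    correlations[[mn]] <- spearman_rho(as.numeric(v), as.numeric(ent),
                                       exact_p = exact_p)
  }
  structure(list(pocket_table = tab, correlations = correlations),
            class = "SpecificityFlexibilityReport")
}

#' @export
print.SpecificityFlexibilityReport <- function(x, ...) {
  cat("Pocket-wise metric table:\n")
  print(x$pocket_table, row.names = FALSE)
  cat("\nSpearman correlations vs cleavage entropy:\n")
  for (mn in names(x$correlations)) {
    r <- x$correlations[[mn]]
    cat(sprintf("  %-22s rho = %7.4f  (n = %d)\n", mn, r$rho, r$n))
  }
  invisible(x)
}

#' Residue-wise difference map (complex minus unbound)
#'
#' Negative values mean the residue is rigidified upon binding (the metric is
#' lower in the complex than in the unbound ensemble); positive values mean
#' mobilization.
#'
#' @param complex_profile,unbound_profile named numeric vectors keyed by
#'   residue (or `BFactorProfile`s, whose `bfactor` column is used).
#' @param metric_name stored metric name.
#' @return A `DifferenceMap`: data.frame with columns `residue` and `delta`
#'   over the shared residue set.
#' @export
difference_map <- function(complex_profile, unbound_profile,
                           metric_name = "metric") {
  as_vec <- function(p) {
    if (inherits(p, "BFactorProfile")) stats::setNames(p$bfactor, p$residue)
    else p
  }
  a <- as_vec(complex_profile); b <- as_vec(unbound_profile)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L)
    stop("profiles share no residues; cannot build a difference map")
  out <- data.frame(residue = shared,
                    delta = as.numeric(a[shared]) - as.numeric(b[shared]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "metric_name") <- metric_name
  attr(out, "sign_convention") <- "negative = rigidified on binding"
  class(out) <- c("DifferenceMap", "data.frame")
  out
}

#' Block-wise convergence of a pocket metric
#'
#' Splits the ensemble into `k` contiguous blocks, recomputes a residue-wise
#' metric per block, aggregates into pocket averages and summarizes how
#' consistently each pocket pair preserves the rank order observed on the
#' full trajectory. Errors in single blocks are caught and reported without
#' aborting the remaining blocks.
#'
#' @param ensemble a `FrameEnsemble`.
#' @param k number of blocks (>= 2).
#' @param metric_fun function `FrameEnsemble -> named numeric` (residue key
#'   -> metric value), e.g. an aligned-B-factor wrapper.
#' @param pockets a `SubPocketDefinition`.
#' @return A `BlockConvergence`: list with `full_table` (PocketMetricTable on
#'   all frames), `block_tables` (list, `NULL` where a block failed),
#'   `rank_agreement` (data.frame: pocket pair, fraction of blocks preserving
#'   the full-trajectory order) and `block_errors`.
#' @export
block_convergence <- function(ensemble, k, metric_fun, pockets) {
  if (k < 2L) stop("block convergence needs k >= 2")
  full_vals <- metric_fun(ensemble)
  full_table <- pocket_average(full_vals, pockets)
  blocks <- split_blocks(ensemble, k)
  block_errors <- character(0)
  block_tables <- lapply(seq_along(blocks), function(i) {
    tryCatch(pocket_average(metric_fun(blocks[[i]]), pockets),
             error = function(e) {
               block_errors[[length(block_errors) + 1L]] <<-
                 sprintf("block %d: %s", i, conditionMessage(e))
               NULL
             })
  })
  plabs <- full_table$pocket
  fv <- stats::setNames(full_table$value, plabs)
  if (length(plabs) < 2L) {
    return(structure(list(full_table = full_table,
                          block_tables = block_tables,
                          rank_agreement = data.frame(
                            pocket_a = character(0), pocket_b = character(0),
                            fraction_preserved = numeric(0)),
                          block_errors = block_errors),
                     class = "BlockConvergence"))
  }
  pairs <- utils::combn(plabs, 2L)
  frac <- apply(pairs, 2L, function(pr) {
    ref <- sign(fv[pr[1]] - fv[pr[2]])
    oks <- vapply(block_tables, function(bt) {
      if (is.null(bt)) return(NA)
      bv <- stats::setNames(bt$value, bt$pocket)
      sign(bv[pr[1]] - bv[pr[2]]) == ref
    }, logical(1))
    mean(oks, na.rm = TRUE)
  })
  rank_agreement <- data.frame(pocket_a = pairs[1, ], pocket_b = pairs[2, ],
                               fraction_preserved = as.numeric(frac),
                               row.names = NULL, stringsAsFactors = FALSE)
  structure(list(full_table = full_table, block_tables = block_tables,
                 rank_agreement = rank_agreement, block_errors = block_errors),
            class = "BlockConvergence")
}

#' Write a SpecificityFlexibilityReport
#'
#' `<prefix>_pockets.csv` holds the pocket table; `<prefix>_correlations.json`
#' the Spearman results (rho, n, ranks).
#'
#' @param report a `SpecificityFlexibilityReport`.
#' @param prefix output path prefix.
#' @return The CSV path, invisibly.
#' @export
write_report <- function(report, prefix) {
  cpath <- paste0(prefix, "_pockets.csv")
  utils::write.csv(report$pocket_table, cpath, row.names = FALSE)
  jsonlite::write_json(
    lapply(report$correlations, function(r)
      list(rho = r$rho, n = r$n, ranks_x = r$ranks_x, ranks_y = r$ranks_y,
           p_value = r$p_value)),
    paste0(prefix, "_correlations.json"), auto_unbox = TRUE, digits = NA)
  invisible(cpath)
}
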