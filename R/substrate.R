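# Substrate tables and cleavage entropy.
#
# Specificity of a protease is quantified position by position over its known
# substrates (Schechter-Berger non-prime positions P6..P1) as the normalized
# Shannon entropy of the residue frequencies at each position: 0 means a
# single residue type is accepted (stringent readout), 1 means all twenty
# residues occur equally often (no preference). The base-20 logarithm makes
# the 0/1 anchors exact for the 20-letter amino-acid alphabet.

.default_positions <- paste0("P", 6:1)

#' Construct a SubstrateTable
#'
#' @param records data.frame with one row per cleavage site: a `substrate_id`
#'   column plus one column per position label holding one-letter residue
#'   codes (`"X"` = unknown).
#' @param positions character vector of position labels (default `P6..P1`).
#' @param source provenance string, e.g. `"MEROPS S01.217 accessed 14.6.2013"`.
#' @return An object of class `SubstrateTable`.
#' @export
substrate_table <- function(records, positions = .default_positions,
                            source = "unspecified") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  miss <- setdiff(positions, names(records))
  if (length(miss) > 0L)
    stop("records lack position column(s): ", paste(miss, collapse = ", "))
  if (!"substrate_id" %in% names(records))
    records$substrate_id <- paste0("sub", seq_len(nrow(records)))
  for (p in positions) {
    v <- toupper(as.character(records[[p]]))
    v[is.na(v) | v == ""] <- "X"
    bad <- !(v %in% c(.AA20, "X"))
    if (any(bad))
      stop("invalid residue code(s) at ", p, ": ",
           paste(unique(v[bad]), collapse = ", "))
    records[[p]] <- v
  }
  structure(list(records = records[, c("substrate_id", positions)],
                 positions = positions, source = source),
            class = "SubstrateTable")
}

#' @export
print.SubstrateTable <- function(x, ...) {
  cat(sprintf("SubstrateTable: %d substrates, positions %s\n  source: %s\n",
              nrow(x$records), paste(x$positions, collapse = " "), x$source))
  invisible(x)
}

#' Read a substrate cleavage table
#'
#' Reads a delimited text file (delimiter sniffed among comma, tab and
#' semicolon from the header line) with a header naming the position columns
#' (`P6`..`P1`). Missing cells become the unknown marker `"X"`. Rows carrying
#' residue codes outside the 20-letter alphabet (plus `"X"`) are dropped with
#' a warning. Alternatively, a single cleavage-window column of contiguous
#' residues can be expanded into positions via `window_col`/`window_offset`.
#'
#' Prime-side columns (`P1'` etc.) present in the file are ignored unless
#' explicitly requested in `positions`.
#'
#' @param path path to the table.
#' @param positions position labels to extract (default `P6..P1`).
#' @param source provenance string stored on the table (defaults to the file
#'   name).
#' @param window_col optional name of a column holding a contiguous residue
#'   string; position `P1` is character `window_offset` of that string, `P2`
#'   the one before it, and so on.
#' @param window_offset 1-based index of the P1 residue within the window
#'   string (default: last non-prime position, i.e. `length(positions)`).
#' @return A `SubstrateTable`.
#' @export
read_substrate_table <- function(path, positions = .default_positions,
                                 source = basename(path),
                                 window_col = NULL, window_offset = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (length(hdr) == 0L || !nzchar(trimws(hdr))) stop("empty substrate file: ", path)
  sep <- c("," = ",", "\t" = "\t", ";" = ";")[
    which.max(c(lengths(regmatches(hdr, gregexpr(",", hdr))),
                lengths(regmatches(hdr, gregexpr("\t", hdr))),
                lengths(regmatches(hdr, gregexpr(";", hdr)))))]
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (nrow(df) == 0L) stop("substrate file has a header but no rows: ", path)
  if (!is.null(window_col)) {
    if (!window_col %in% names(df)) stop("window column '", window_col, "' not found")
    if (is.null(window_offset)) window_offset <- length(positions)
    win <- toupper(df[[window_col]])
    for (i in seq_along(positions)) {
      # positions are ordered outermost..P1; P1 sits at window_offset
      off <- window_offset - (length(positions) - i)
      ch <- ifelse(off >= 1L & off <= nchar(win), substr(win, off, off), "X")
      df[[positions[i]]] <- ch
    }
  }
  miss <- setdiff(positions, names(df))
  if (length(miss) > 0L)
    stop("unknown position label(s): ", paste(miss, collapse = ", "))
  for (p in positions) {
    v <- toupper(trimws(df[[p]]))
    v[is.na(v) | v == "" | v == "-"] <- "X"
    df[[p]] <- v
  }
  ok <- Reduce(`&`, lapply(positions, function(p) df[[p]] %in% c(.AA20, "X")))
  if (any(!ok)) {
    warning(sum(!ok), " row(s) dropped: residue code outside the standard ",
            "alphabet/'X'")
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no parseable rows left in ", path)
  if (!"substrate_id" %in% names(df))
    df$substrate_id <- paste0("sub", seq_len(nrow(df)))
  substrate_table(df, positions, source)
}

#' Relative residue frequencies at one substrate position
#'
#' Unknown residues (`"X"`) are excluded from both numerator and denominator.
#'
#' @param table a `SubstrateTable`.
#' @param position one position label, e.g. `"P1"`.
#' @return Named numeric vector of length 20 (standard residues, alphabetical)
#'   summing to 1.
#' @export
positional_frequencies <- function(table, position) {
  stopifnot(inherits(table, "SubstrateTable"))
  if (!position %in% table$positions)
    stop("position '", position, "' not in table (",
         paste(table$positions, collapse = " "), ")")
  v <- table$records[[position]]
  v <- v[v != "X"]
  if (length(v) == 0L)
    stop("position ", position, " is uninformative: all residues unknown ('X')")
  counts <- table(factor(v, levels = .AA20))
  stats::setNames(as.numeric(counts) / length(v), .AA20)
}

#' Position-wise cleavage entropy profile
#'
#' For each position, the cleavage entropy is
#' \deqn{S = -\sum_a f_a \log_{20} f_a}
#' over residues with nonzero frequency (0 log 0 := 0), where `f_a` are the
#' relative frequencies from [positional_frequencies()]. S = 0 iff a single
#' residue type is observed; S = 1 iff all twenty residues are equally
#' frequent.
#'
#' @param table a `SubstrateTable`.
#' @param positions positions to profile (default: all positions of the table).
#' @param pseudocount optional additive pseudocount per residue type applied
#'   before normalization (default 0, i.e. no smoothing).
#' @return A `SpecificityProfile`: list with `entropy_by_position` (named
#'   numeric in `[0, 1]`), `counts_by_position` (20 x n matrix of residue
#'   counts) and `n_observed` (non-`"X"` record count per position).
#' @export
cleavage_entropy_profile <- function(table, positions = table$positions,
                                     pseudocount = 0) {
  stopifnot(inherits(table, "SubstrateTable"), pseudocount >= 0)
  counts <- sapply(positions, function(p) {
    v <- table$records[[p]]
    as.numeric(table(factor(v[v != "X"], levels = .AA20)))
  })
  rownames(counts) <- .AA20
  n_obs <- colSums(counts)
  entropy <- vapply(seq_along(positions), function(j) {
    cj <- counts[, j] + pseudocount
    if (sum(cj) == 0)
      stop("position ", positions[j], " is uninformative: all residues unknown ('X')")
    f <- cj / sum(cj)
    f <- f[f > 0]
    -sum(f * log(f)) / log(20)
  }, numeric(1))
  structure(list(entropy_by_position = stats::setNames(entropy, positions),
                 counts_by_position = counts,
                 n_observed = stats::setNames(n_obs, positions),
                 source = table$source),
            class = "SpecificityProfile")
}

#' @export
print.SpecificityProfile <- function(x, ...) {
  cat("SpecificityProfile (cleavage entropy, 0 = stringent, 1 = random):\n")
  print(round(x$entropy_by_position, 4))
  invisible(x)
}

#' Write a SpecificityProfile to CSV / JSON
#'
#' @param profile a `SpecificityProfile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specificity_csv <- function(profile, path) {
  df <- data.frame(position = names(profile$entropy_by_position),
                   entropy = as.numeric(profile$entropy_by_position),
                   n_observed = as.integer(profile$n_observed))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_specificity_csv
#' @export
write_specificity_json <- function(profile, path) {
  jsonlite::write_json(
    list(entropy_by_position = as.list(profile$entropy_by_position),
         n_observed = as.list(profile$n_observed),
         source = profile$source),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
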