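# Positional residue-frequency analysis and psi-K-x-E consensus matching.

#' Residue row order used for frequency matrices
#'
#' Alphabetical by amino-acid name (Ala...Val), the conventional order for
#' per-position composition tables; fixed so output is diffable.
#' @export
FREQUENCY_ROW_ORDER <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

offset_names <- function(flank) {
  off <- seq.int(-flank, flank)
  ifelse(off > 0, paste0("+", off), as.character(off))
}

#' Positional residue frequencies of a window dataset
#'
#' Counts how often each of the 20 residues occurs at each offset around the
#' center lysine. The `X` padding symbol is not counted, so columns near the
#' window edges may sum to less than the number of windows when some sites
#' lie near protein termini.
#'
#' @param dataset a `window_dataset`.
#' @return integer matrix, 20 residues (rows, Ala...Val order) by
#'   `2*flank+1` offsets (columns `-flank`...`+flank`), with attributes
#'   `flank` and `n` (number of windows). Class
#'   `positional_frequency_matrix`.
#' @export
positional_frequency <- function(dataset) {
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  flank <- ws_flank(dataset)
  wlen <- 2L * flank + 1L
  chars <- matrix(unlist(strsplit(dataset$peptide, "")), ncol = wlen, byrow = TRUE)
  counts <- vapply(seq_len(wlen), function(j) {
    tab <- table(factor(chars[, j], levels = FREQUENCY_ROW_ORDER))
    as.integer(tab)
  }, integer(20))
  dimnames(counts) <- list(FREQUENCY_ROW_ORDER, offset_names(flank))
  structure(counts, flank = flank, n = nrow(dataset),
            class = c("positional_frequency_matrix", "matrix"))
}

#' Consensus rule for the psi-K-x-E motif
#'
#' The SUMO consensus motif: a hydrophobic residue (psi) immediately before
#' the target lysine, any residue after it, and glutamate at offset +2. The
#' default psi set is the standard hydrophobic set
#' \{A, F, I, L, M, P, V, W\}; it is configurable because different analyses
#' draw the hydrophobicity boundary differently.
#'
#' @param psi character vector: the hydrophobic residue set.
#' @return object of class `consensus_rule`.
#' @export
consensus_rule <- function(psi = c("A", "F", "I", "L", "M", "P", "V", "W")) {
  if (!all(psi %in% FREQUENCY_ROW_ORDER)) {
    stop("psi set contains non-standard residues", call. = FALSE)
  }
  structure(list(psi = psi), class = "consensus_rule")
}

#' Does a window match the consensus motif?
#'
#' True iff the residue at offset -1 is in the psi set and the residue at
#' offset +2 is `E`. Only those two offsets matter; the center is `K` by the
#' dataset invariant and offset +1 is unconstrained.
#'
#' @param peptide a peptide string (flank >= 2), or a `window_dataset` (then
#'   a logical vector is returned).
#' @param rule a `consensus_rule`.
#' @return logical.
#' @export
matches_consensus <- function(peptide, rule = consensus_rule()) {
  if (inherits(peptide, "window_dataset")) peptide <- peptide$peptide
  flank <- (nchar(peptide[1]) - 1L) %/% 2L
  if (flank < 2L) stop("consensus matching needs flank >= 2", call. = FALSE)
  c0 <- flank + 1L
  substr(peptide, c0 - 1L, c0 - 1L) %in% rule$psi &
    substr(peptide, c0 + 2L, c0 + 2L) == "E"
}

#' Fraction of windows matching the consensus motif
#'
#' @param dataset a `window_dataset` with flank >= 2.
#' @param rule a `consensus_rule`.
#' @return real in `[0, 1]`.
#' @export
consensus_fraction <- function(dataset, rule = consensus_rule()) {
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  mean(matches_consensus(dataset, rule))
}

#' Side-by-side frequency report for modified vs unmodified windows
#'
#' @param pos_matrix,neg_matrix `positional_frequency_matrix` objects with
#'   matching flanks (e.g. from positive and negative windows).
#' @return list with `counts` (the two matrices), `relative` (per-column
#'   relative frequencies, each column normalized by its residue total), and
#'   `long` (plot-ready data.frame: residue, offset, class, count, freq).
#' @export
frequency_report <- function(pos_matrix, neg_matrix) {
  if (!identical(attr(pos_matrix, "flank"), attr(neg_matrix, "flank"))) {
    stop("frequency matrices have different flanks", call. = FALSE)
  }
  rel <- function(m) sweep(unclass(m), 2L, pmax(colSums(m), 1L), "/")
  long_of <- function(m, cls) {
    r <- rel(m)
    data.frame(
      residue = rep(rownames(m), times = ncol(m)),
      offset = rep(colnames(m), each = nrow(m)),
      class = cls,
      count = as.vector(unclass(m)),
      freq = as.vector(r),
      stringsAsFactors = FALSE
    )
  }
  list(
    counts = list(positive = pos_matrix, negative = neg_matrix),
    relative = list(positive = rel(pos_matrix), negative = rel(neg_matrix)),
    long = rbind(long_of(pos_matrix, "positive"), long_of(neg_matrix, "negative"))
  )
}

#' Write a frequency matrix as TSV
#'
#' Residue row labels, one column per offset `-flank`...`+flank`.
#' @param matrix a `positional_frequency_matrix`.
#' @param path output file.
#' @export
write_frequency_tsv <- function(matrix, path) {
  df <- data.frame(residue = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
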