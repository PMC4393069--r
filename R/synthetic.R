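# Synthetic fixture generators.
#
# These emulate the shape of curated SUMOylation data -- positive windows
# with a realistic positional residue composition, uniform-background
# negatives centered on lysine -- so every pipeline stage is testable without
# any external download. Positions are modeled independently (marginals
# only); none of this is real SUMO data.

TABLE2_MD5 <- "41141775f19f110d9bbe46043256741d"

#' Positional residue counts of the curated positive set
#'
#' Loads the packaged 20-residue x 21-offset count matrix of the 293 curated
#' modified-lysine windows (flank 10). Columns near the window edges sum to
#' less than 293 because some sites lie close to a protein terminus and the
#' overhang is padding. The file is checksummed against corruption.
#'
#' @return a `positional_frequency_matrix` with `n = 293`, flank 10.
#' @export
table2_counts <- function() {
  path <- system.file("extdata", "table2_counts.tsv", package = "sumohunt")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged positional-count data file is missing; reinstall the package",
         call. = FALSE)
  }
  if (!identical(unname(tools::md5sum(path)), TABLE2_MD5)) {
    stop("packaged positional-count data file is corrupt (checksum mismatch)",
         call. = FALSE)
  }
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  stopifnot(identical(rownames(m), FREQUENCY_ROW_ORDER), ncol(m) == 21L)
  n <- max(colSums(m))
  center <- m[, "0"]
  stopifnot(center[["K"]] == n, sum(center) == n)
  structure(m, flank = 10L, n = n,
            class = c("positional_frequency_matrix", "matrix"))
}

#' Deterministic dataset with exactly the given positional counts
#'
#' Builds `n` windows whose positional-frequency matrix equals `matrix`
#' cell-for-cell. Construction: in each column the residues are laid out in
#' fixed row order, each repeated by its count, and any deficit up to `n` is
#' filled with the padding symbol `X`; row `i` of the layout becomes peptide
#' `i`. Columns are independent by design and no randomness is involved.
#' Because padding deficits must grow towards the window edges (as they do in
#' real terminus-padded data), the `X` symbols land contiguously at the ends
#' of each peptide.
#'
#' @param matrix a `positional_frequency_matrix`; each column must sum to at
#'   most `n` and the center column must be all-`K` with count `n`.
#' @param n number of windows; defaults to the matrix's `n` attribute (or the
#'   maximum column sum).
#' @return a `window_dataset` of `n` positive windows.
#' @export
exact_marginal_dataset <- function(matrix, n = NULL) {
  if (is.null(n)) n <- attr(matrix, "n")
  if (is.null(n)) n <- max(colSums(matrix))
  cs <- colSums(matrix)
  if (any(cs > n)) {
    stop("column sum exceeds n = ", n, " at offset(s) ",
         paste(colnames(matrix)[cs > n], collapse = ", "), call. = FALSE)
  }
  flank <- (ncol(matrix) - 1L) %/% 2L
  center <- flank + 1L
  if (matrix[["K", center]] != n || cs[center] != n) {
    stop("center column must carry all ", n, " counts on K", call. = FALSE)
  }
  deficits <- n - cs
  # padding must be attachable to the window ends: deficits may not decrease
  # towards either edge
  if (is.unsorted(rev(deficits[seq_len(center)])) ||
      is.unsorted(deficits[center:ncol(matrix)])) {
    stop("column deficits must be monotone towards the window edges ",
         "(padding occurs only at termini)", call. = FALSE)
  }
  cols <- lapply(seq_len(ncol(matrix)), function(j) {
    c(rep(rownames(matrix), times = matrix[, j]), rep("X", deficits[j]))
  })
  peptides <- do.call(paste0, cols)
  window_dataset(peptides, rep("positive", n), flank = flank)
}

#' Positional sampling model from a frequency matrix
#'
#' Per-offset categorical distributions over the 20 residues, with the center
#' degenerate at `K`. Padding deficits are ignored: probabilities are the
#' observed residue counts normalized per column.
#'
#' @param matrix a `positional_frequency_matrix`.
#' @return matrix of column-stochastic probabilities (20 x window length),
#'   class `positional_model`.
#' @export
positional_model <- function(matrix) {
  probs <- sweep(unclass(matrix), 2L, colSums(matrix), "/")
  structure(probs, flank = attr(matrix, "flank"),
            class = c("positional_model", "matrix"))
}

#' Sample positive windows from a positional model
#'
#' Residues are drawn position-independently from the model's per-offset
#' distributions (windows share no joint structure beyond the marginals).
#'
#' @param model a `positional_model`.
#' @param n number of windows.
#' @param seed RNG seed; same seed, same dataset.
#' @return a `window_dataset` of `n` positive windows.
#' @export
sample_positives <- function(model, n, seed) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  wlen <- ncol(model)
  cols <- lapply(seq_len(wlen), function(j) {
    sample(rownames(model), n, replace = TRUE, prob = model[, j])
  })
  window_dataset(do.call(paste0, cols), rep("positive", n),
                 flank = (wlen - 1L) %/% 2L)
}

#' Sample uniform-background negative windows
#'
#' Center `K`; flanking residues i.i.d. uniform over the 20 standard
#' residues.
#'
#' @param n number of windows.
#' @param seed RNG seed.
#' @param flank flank size (default 10).
#' @return a `window_dataset` of `n` negative windows.
#' @export
sample_negatives <- function(n, seed, flank = 10L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  wlen <- 2L * flank + 1L
  cols <- lapply(seq_len(wlen), function(j) {
    if (j == flank + 1L) rep("K", n)
    else sample(FREQUENCY_ROW_ORDER, n, replace = TRUE)
  })
  window_dataset(do.call(paste0, cols), rep("negative", n), flank = flank)
}

#' End-to-end synthetic benchmark
#'
#' Positives sampled from the packaged positional-count model, negatives
#' uniform, encoded with the packaged sixteen-scale property table. The
#' motif signal (e.g. glutamate at +2 in 224/293 positives vs 1/20
#' background) makes the classes learnably separable.
#'
#' @param n_pos,n_neg class sizes (default 293 each, the curated composition).
#' @param seed master seed; positive and negative draws use derived streams.
#' @param flank flank of the encoded dataset (default 3; windows are sampled
#'   at flank 10 and trimmed).
#' @param table property table (default the packaged one).
#' @return list with `windows` (flank-10 `window_dataset`, positives first)
#'   and `encoded` (an `encoded_dataset` at `flank`), plus `seed`.
#' @export
make_benchmark <- function(n_pos = 293L, n_neg = 293L, seed = 1L, flank = 3L,
                           table = load_paper_table()) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  model <- positional_model(table2_counts())
  pos <- sample_positives(model, n_pos, sub_seeds[1])
  neg <- sample_negatives(n_neg, sub_seeds[2], flank = 10L)
  windows <- window_dataset(c(pos$peptide, neg$peptide),
                            c(pos$label, neg$label), flank = 10L)
  list(windows = windows,
       encoded = encode_dataset(shrink_windows(windows, flank), table),
       seed = as.integer(seed))
}

#' Simulate a synthetic proteome with annotated lysines
#'
#' Generates random protein sequences containing a fixed total number of
#' lysines, a fixed subset of which are annotated as modified; the rest are
#' unmodified by assumption. Useful for exercising dataset curation at
#' realistic scale without real sequence data.
#'
#' @param n_proteins number of proteins.
#' @param n_lysines total lysine count across the proteome.
#' @param n_modified number of lysines annotated as modified.
#' @param seed RNG seed.
#' @param mean_length approximate protein length.
#' @return list with `sequences` (named character vector) and `sites`
#'   (data.frame of the modified annotations: accession, position, status).
#' @export
simulate_proteome <- function(n_proteins = 181L, n_lysines = 7639L,
                              n_modified = 293L, seed = 1L,
                              mean_length = 400L) {
  if (n_modified > n_lysines) stop("n_modified exceeds n_lysines", call. = FALSE)
  set.seed(seed)
  non_k <- setdiff(FREQUENCY_ROW_ORDER, "K")
  # distribute lysines over proteins (each gets at least one)
  k_per <- rep(n_lysines %/% n_proteins, n_proteins)
  extra <- sample.int(n_proteins, n_lysines %% n_proteins)
  k_per[extra] <- k_per[extra] + 1L
  sequences <- character(n_proteins)
  names(sequences) <- sprintf("SYN%04d", seq_len(n_proteins))
  all_k <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    len <- max(k_per[i] + 10L, stats::rpois(1L, mean_length))
    chars <- sample(non_k, len, replace = TRUE)
    kpos <- sort(sample.int(len, k_per[i]))
    chars[kpos] <- "K"
    sequences[i] <- paste(chars, collapse = "")
    all_k[[i]] <- data.frame(accession = names(sequences)[i], position = kpos,
                             stringsAsFactors = FALSE)
  }
  lysines <- do.call(rbind, all_k)
  mod_rows <- sort(sample.int(nrow(lysines), n_modified))
  sites <- lysines[mod_rows, , drop = FALSE]
  sites$status <- "modified"
  rownames(sites) <- NULL
  list(sequences = sequences, sites = sites)
}
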