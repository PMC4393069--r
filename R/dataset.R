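# Dataset curation: sequences + site annotations -> labeled peptide windows.
#
# Site positions are 1-based in all external files and function arguments;
# any internal offsets are 0-based and never exposed.

STANDARD_RESIDUES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Read protein sequences from a FASTA file
#'
#' Non-standard residue codes (B, Z, U, O, and anything else outside the 20
#' standard letters) are mapped to the padding/unknown symbol `X` with a
#' warning, so downstream encoding stays total.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, seqonly = FALSE),
    error = function(e) stop("failed to parse FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], character(1)))
  names(out) <- vapply(seqs, function(s) attr(s, "name"), character(1))
  cleaned <- gsub(sprintf("[^%sX]", paste(STANDARD_RESIDUES, collapse = "")), "X", out)
  if (sum(cleaned != out) > 0) {
    warning(sum(cleaned != out), " sequence(s) contained non-standard residues; mapped to 'X'",
            call. = FALSE)
  }
  cleaned
}

#' Read site annotations from tab-separated text
#'
#' Each record is `accession<TAB>position<TAB>status` with 1-based positions
#' and status `modified` or `unmodified`.
#'
#' @param path,text path to a TSV file, or (alternatively) its text content.
#' @return data.frame with columns `accession`, `position`, `status`.
#' @export
read_sites <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(accession = character(0), position = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) stop("site record at line ", i, " has fewer than 3 fields", call. = FALSE)
    pos <- suppressWarnings(as.integer(p[2]))
    if (is.na(pos) || pos < 1L) {
      stop("non-integer or non-positive position at line ", i, ": '", p[2], "'", call. = FALSE)
    }
    if (!p[3] %in% c("modified", "unmodified")) {
      stop("unknown status '", p[3], "' at line ", i,
           " (expected 'modified' or 'unmodified')", call. = FALSE)
    }
  }
  data.frame(
    accession = vapply(parts, `[`, character(1), 1),
    position = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    status = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
}

#' Annotate every lysine in a sequence
#'
#' Every `K` yields exactly one annotation: positive if its position is in
#' `modified_positions`, negative otherwise. Lysines not reported as modified
#' are assumed unmodified. A position reported both modified and unmodified
#' upstream of this call must be resolved to modified (see [resolve_sites()]).
#'
#' @param sequence residue string.
#' @param modified_positions integer vector of 1-based modified positions.
#' @param accession protein identifier recorded in the annotations.
#' @return data.frame of annotations (`accession`, `position`, `status`).
#' @export
label_lysines <- function(sequence, modified_positions = integer(0), accession = "protein") {
  chars <- strsplit(sequence, "")[[1]]
  kpos <- which(chars == "K")
  modified_positions <- unique(as.integer(modified_positions))
  bad <- setdiff(modified_positions, kpos)
  if (length(bad) > 0L) {
    stop("modified position(s) ", paste(bad, collapse = ", "), " in '", accession,
         "' do not index a lysine", call. = FALSE)
  }
  data.frame(
    accession = rep(accession, length(kpos)),
    position = kpos,
    status = ifelse(kpos %in% modified_positions, "modified", "unmodified"),
    stringsAsFactors = FALSE
  )
}

#' Resolve conflicting site reports
#'
#' A site reported both modified and unmodified is considered modified.
#' @param sites data.frame as from [read_sites()].
#' @return deduplicated data.frame, one row per (accession, position).
#' @export
resolve_sites <- function(sites) {
  key <- paste(sites$accession, sites$position, sep = "\r")
  status <- tapply(sites$status, key, function(s) if ("modified" %in% s) "modified" else "unmodified")
  first <- !duplicated(key)
  out <- sites[first, , drop = FALSE]
  out$status <- unname(status[paste(out$accession, out$position, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Extract a lysine-centered peptide window
#'
#' Returns the (2*flank+1)-mer centered at `position`, padded with `X` where
#' the window overhangs either terminus (sites near protein ends stay usable).
#'
#' @param sequence residue string.
#' @param position 1-based index of the center lysine.
#' @param flank number of residues on each side.
#' @return Peptide string of length `2*flank+1`.
#' @export
extract_window <- function(sequence, position, flank) {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position ", position, " outside sequence of length ", n, call. = FALSE)
  }
  if (substr(sequence, position, position) != "K") {
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', not 'K'", call. = FALSE)
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(lo, 1L), min(hi, n))
  paste0(
    strrep("X", max(0L, 1L - lo)),
    core,
    strrep("X", max(0L, hi - n))
  )
}

#' Construct a window dataset
#'
#' A `window_dataset` is a data.frame of lysine-centered peptides with class
#' labels and provenance, all sharing one flank size.
#'
#' @param peptide character vector of peptides, each of length `2*flank+1`
#'   with `K` at the center (`X` padding allowed at the ends).
#' @param label `"positive"` or `"negative"` per peptide.
#' @param accession,position provenance of each window.
#' @param flank shared flank size; inferred from the peptides if omitted.
#' @return data.frame of class `window_dataset` with attribute `flank`.
#' @export
window_dataset <- function(peptide, label,
                           accession = rep(NA_character_, length(peptide)),
                           position = rep(NA_integer_, length(peptide)),
                           flank = NULL) {
  if (length(peptide) == 0L) stop("empty window dataset", call. = FALSE)
  if (is.null(flank)) flank <- (nchar(peptide[1]) - 1L) %/% 2L
  wlen <- 2L * flank + 1L
  if (!all(nchar(peptide) == wlen)) {
    stop("all peptides must have length ", wlen, " (2*flank+1)", call. = FALSE)
  }
  centers <- substr(peptide, flank + 1L, flank + 1L)
  if (!all(centers == "K")) {
    stop("every window must be centered on 'K'; offending window(s): ",
         paste(utils::head(which(centers != "K"), 3), collapse = ", "), call. = FALSE)
  }
  if (!all(label %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  structure(
    data.frame(peptide = peptide, label = label, accession = accession,
               position = position, stringsAsFactors = FALSE),
    flank = as.integer(flank),
    class = c("window_dataset", "data.frame")
  )
}

#' Flank size of a window dataset
#' @param dataset a `window_dataset`.
#' @export
ws_flank <- function(dataset) {
  f <- attr(dataset, "flank")
  if (is.null(f)) f <- (nchar(dataset$peptide[1]) - 1L) %/% 2L
  as.integer(f)
}

#' Build labeled windows from sequences and site annotations
#'
#' Runs conflict resolution, per-protein lysine labeling (annotated lysines
#' keep their reported status; in `assume_unmodified` mode every unannotated
#' lysine becomes a negative), and window extraction with terminus padding.
#'
#' @param sequences named character vector of protein sequences.
#' @param sites data.frame from [read_sites()]; only `modified` rows are
#'   required when `assume_unmodified = TRUE`.
#' @param flank window flank size.
#' @param assume_unmodified if TRUE, every lysine not reported modified is a
#'   negative instance.
#' @return a `window_dataset`.
#' @export
build_windows <- function(sequences, sites, flank = 10L, assume_unmodified = TRUE) {
  sites <- resolve_sites(sites)
  unknown <- setdiff(unique(sites$accession), names(sequences))
  if (length(unknown) > 0L) {
    stop("site annotations reference unknown accession(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  pieces <- lapply(names(sequences), function(acc) {
    seq <- sequences[[acc]]
    mod <- sites$position[sites$accession == acc & sites$status == "modified"]
    if (assume_unmodified) {
      ann <- label_lysines(seq, mod, accession = acc)
    } else {
      ann <- sites[sites$accession == acc, , drop = FALSE]
      for (p in ann$position) {
        if (substr(seq, p, p) != "K") {
          stop("annotated position ", p, " in '", acc, "' is not a lysine", call. = FALSE)
        }
      }
    }
    if (nrow(ann) == 0L) return(NULL)
    data.frame(
      peptide = vapply(ann$position, function(p) extract_window(seq, p, flank), character(1)),
      label = ifelse(ann$status == "modified", "positive", "negative"),
      accession = acc, position = ann$position, stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, pieces)
  if (is.null(all) || nrow(all) == 0L) stop("no lysine windows found", call. = FALSE)
  window_dataset(all$peptide, all$label, all$accession, all$position, flank = flank)
}

#' Remove exact-duplicate peptides
#'
#' Identical peptide strings collapse to one window. If duplicates conflict in
#' label the retained window is positive (a site reported both modified and
#' unmodified counts as modified); provenance of the first occurrence is kept
#' and input order is otherwise preserved. Idempotent.
#'
#' @param dataset a `window_dataset`.
#' @return deduplicated `window_dataset`.
#' @export
deduplicate <- function(dataset) {
  pep <- dataset$peptide
  any_pos <- tapply(dataset$label == "positive", pep, any)
  keep <- !duplicated(pep)
  out <- dataset[keep, , drop = FALSE]
  out$label <- ifelse(unname(any_pos[out$peptide]), "positive", "negative")
  rownames(out) <- NULL
  window_dataset(out$peptide, out$label, out$accession, out$position,
                 flank = ws_flank(dataset))
}

#' Balance classes by down-sampling negatives
#'
#' Keeps all positives and a seeded uniform sample (without replacement) of
#' negatives of equal count, preserving input order within each class.
#'
#' @param dataset a `window_dataset`.
#' @param seed integer seed for the negative subsample; recorded in the
#'   `balance_seed` attribute of the result.
#' @return balanced `window_dataset`.
#' @export
balance <- function(dataset, seed) {
  pos_idx <- which(dataset$label == "positive")
  neg_idx <- which(dataset$label == "negative")
  if (length(neg_idx) < length(pos_idx)) {
    stop("cannot balance: ", length(neg_idx), " negatives < ",
         length(pos_idx), " positives", call. = FALSE)
  }
  set.seed(seed)
  take <- sort(sample(neg_idx, length(pos_idx)))
  idx <- sort(c(pos_idx, take))
  out <- window_dataset(dataset$peptide[idx], dataset$label[idx],
                        dataset$accession[idx], dataset$position[idx],
                        flank = ws_flank(dataset))
  attr(out, "balance_seed") <- as.integer(seed)
  out
}

#' Trim windows to a narrower flank
#'
#' The same sites at a narrower window are substrings of the wide windows, so
#' a flank-10 dataset can be reused at flank 5 or 3 without re-extraction.
#'
#' @param dataset a `window_dataset`.
#' @param flank target flank, at most the current flank.
#' @return `window_dataset` at the new flank.
#' @export
shrink_windows <- function(dataset, flank) {
  f0 <- ws_flank(dataset)
  if (flank > f0) stop("target flank ", flank, " exceeds current flank ", f0, call. = FALSE)
  if (flank == f0) return(dataset)
  lo <- f0 + 1L - flank
  hi <- f0 + 1L + flank
  window_dataset(substr(dataset$peptide, lo, hi), dataset$label,
                 dataset$accession, dataset$position, flank = flank)
}

#' Write a window dataset as TSV
#' @param dataset a `window_dataset`.
#' @param path output file; header `peptide label accession position`.
#' @export
write_windows_tsv <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a window dataset from TSV written by [write_windows_tsv()]
#' @param path input file.
#' @export
read_windows_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character", "integer"))
  window_dataset(df$peptide, df$label, df$accession, df$position)
}
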