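# Window -> feature-vector encoding and WEKA-compatible export.
#
# Ordering is position-major: for offsets -flank..+flank in sequence order,
# the 16 property values in table order. Feature names record this layout
# ("pos-3:PRAM900101", ...) so any consumer can verify it.

feature_names_for <- function(table, flank) {
  offsets <- seq.int(-flank, flank)
  tags <- ifelse(offsets > 0, paste0("pos+", offsets), paste0("pos", offsets))
  as.vector(vapply(tags, function(t) paste0(t, ":", names(table)), character(length(table))))
}

# 20 residues + X -> per-scale value lookup matrix, rows = scales, cols = residues
encoding_matrix <- function(table) {
  m <- vapply(table, function(s) s$coefficients, numeric(20))  # 20 x nscale
  m <- t(m)                                                    # nscale x 20
  colnames(m) <- AAINDEX_RESIDUE_ORDER
  cbind(m, X = rowMeans(m))
}

#' Encode one peptide window as a feature vector
#'
#' Each of the `2*flank+1` positions contributes the 16 property coefficients
#' of its residue (in table order), giving `16*(2*flank+1)` dimensions:
#' 112, 176 and 336 for windows 7, 11 and 21. The `X` padding symbol encodes
#' as the per-scale mean. Raw coefficients are used; no standardization.
#'
#' @param peptide peptide string (center `K`, `X` padding allowed).
#' @param table a `property_table`.
#' @return named numeric vector of length `length(table) * nchar(peptide)`.
#' @export
encode_window <- function(peptide, table) {
  chars <- strsplit(peptide, "")[[1]]
  em <- encoding_matrix(table)
  bad <- setdiff(chars, colnames(em))
  if (length(bad) > 0L) {
    stop("cannot encode residue(s) outside the alphabet: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  v <- as.vector(em[, chars, drop = FALSE])
  names(v) <- feature_names_for(table, (length(chars) - 1L) %/% 2L)
  v
}

#' Encode a window dataset
#'
#' @param dataset a `window_dataset`.
#' @param table a `property_table`.
#' @param standardize if TRUE, each feature column is centered and scaled to
#'   unit variance after encoding (off by default; raw coefficients are the
#'   reference behaviour).
#' @return object of class `encoded_dataset`: list with `x` (numeric matrix,
#'   one row per window), `label`, `feature_names`, `flank`, `provenance`.
#' @export
encode_dataset <- function(dataset, table, standardize = FALSE) {
  if (nrow(dataset) == 0L) stop("cannot encode an empty dataset", call. = FALSE)
  flank <- ws_flank(dataset)
  em <- encoding_matrix(table)
  chars <- strsplit(dataset$peptide, "")
  bad <- setdiff(unique(unlist(chars)), colnames(em))
  if (length(bad) > 0L) {
    stop("cannot encode residue(s) outside the alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- t(vapply(chars, function(ch) as.vector(em[, ch, drop = FALSE]),
                numeric(length(table) * (2L * flank + 1L))))
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant columns stay zero
    x <- x[, , drop = FALSE]
    attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  }
  colnames(x) <- feature_names_for(table, flank)
  structure(
    list(x = x, label = dataset$label, feature_names = colnames(x),
         flank = flank,
         provenance = data.frame(accession = dataset$accession,
                                 position = dataset$position,
                                 stringsAsFactors = FALSE)),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("encoded_dataset: %d instances x %d features (flank %d); %d positive / %d negative\n",
              nrow(x$x), ncol(x$x), x$flank, sum(x$label == "positive"),
              sum(x$label == "negative")))
  invisible(x)
}

#' Subset an encoded dataset by row index
#' @param data an `encoded_dataset`.
#' @param idx integer row indices.
#' @export
subset_encoded <- function(data, idx) {
  structure(
    list(x = data$x[idx, , drop = FALSE], label = data$label[idx],
         feature_names = data$feature_names, flank = data$flank,
         provenance = data$provenance[idx, , drop = FALSE]),
    class = "encoded_dataset"
  )
}

#' Write an encoded dataset as ARFF (WEKA dialect)
#'
#' One numeric attribute per feature plus a final nominal `class` attribute
#' with values `{positive,negative}`. Values are written with full precision
#' so the file round-trips through standard ARFF readers.
#'
#' @param data an `encoded_dataset`.
#' @param path output file.
#' @param relation_name ARFF relation name; empty defaults to `"sumohunt"`.
#' @export
write_arff <- function(data, path, relation_name = "sumohunt") {
  if (!nzchar(relation_name)) relation_name <- "sumohunt"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@RELATION ", relation_name), con)
  writeLines(paste0("@ATTRIBUTE '", data$feature_names, "' NUMERIC"), con)
  writeLines("@ATTRIBUTE class {positive,negative}", con)
  writeLines("@DATA", con)
  rows <- apply(data$x, 1L, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                                              collapse = ","))
  writeLines(paste0(rows, ",", data$label), con)
  invisible(path)
}

#' Write an encoded dataset as CSV
#'
#' Header is the feature names plus `class`; optional provenance columns
#' (`accession`, `position`) can be prepended.
#'
#' @param data an `encoded_dataset`.
#' @param path output file.
#' @param provenance include provenance columns (default FALSE).
#' @export
write_encoded_csv <- function(data, path, provenance = FALSE) {
  df <- as.data.frame(data$x)
  names(df) <- data$feature_names
  df$class <- data$label
  if (provenance) df <- cbind(data$provenance, df)
  utils::write.csv(df, path, row.names = FALSE, quote = provenance)
  invisible(path)
}

#' Read an encoded dataset back from CSV written by [write_encoded_csv()]
#' @param path input CSV (without provenance columns).
#' @export
read_encoded_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- df$class
  df$class <- NULL
  x <- as.matrix(df)
  flank <- (ncol(x) / 16L - 1L) %/% 2L
  structure(
    list(x = x, label = lab, feature_names = colnames(x), flank = flank,
         provenance = data.frame(accession = rep(NA_character_, nrow(x)),
                                 position = rep(NA_integer_, nrow(x)))),
    class = "encoded_dataset"
  )
}
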