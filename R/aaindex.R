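# Physicochemical property scales (AAIndex) used to encode peptide windows.

#' Canonical AAIndex residue order
#'
#' The order in which the 20 coefficients of an AAIndex1 `I` record are laid
#' out: first row A R N D C Q E G H I, second row L K M F P S T W Y V.
#' @keywords internal
AAINDEX_RESIDUE_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Accessions of the sixteen property scales used for encoding
#'
#' Hydrophobicity, polarity, bulkiness, hydropathy, accessible surface area,
#' tripeptide surface area, buried-residue percentage, entropy of formation,
#' side-chain volume, side-chain stability contribution, buriability,
#' hydrophilicity, molecular weight, transfer free energy to surface, steric
#' parameter and isoelectric point -- properties bearing on how a target
#' lysine and its neighbourhood are presented to an incoming SUMO moiety.
#' @export
SUMOHUNT_ACCESSIONS <- c(
  "PRAM900101", "GRAR740102", "ZIMJ680102", "KYTJ820101",
  "RADA880106", "CHOC760101", "JANJ780102", "HUTJ700103",
  "KRIW790103", "TAKK010101", "ZHOH040103", "HOPT810101",
  "FASG760101", "BULH740101", "CHAM810101", "ZIMJ680104"
)

new_property_scale <- function(accession, description, coefficients) {
  stopifnot(is.character(accession), length(accession) == 1L)
  if (!identical(sort(names(coefficients)), sort(AAINDEX_RESIDUE_ORDER))) {
    stop("property scale '", accession, "' must have exactly the 20 standard residue coefficients",
         call. = FALSE)
  }
  if (!all(is.finite(coefficients))) {
    stop("property scale '", accession, "' has non-finite coefficients", call. = FALSE)
  }
  structure(
    list(accession = accession, description = description,
         coefficients = coefficients[AAINDEX_RESIDUE_ORDER]),
    class = "property_scale"
  )
}

#' Construct a property table from a list of scales
#'
#' @param scales list of property scales as returned by [parse_aaindex1()].
#' @return An object of class `property_table`: an ordered list of scales with
#'   unique accessions. Feature encoding depends on this order, so it is fixed
#'   at construction.
#' @export
property_table <- function(scales) {
  acc <- vapply(scales, function(s) s$accession, character(1))
  if (anyDuplicated(acc)) stop("duplicate accessions in property table", call. = FALSE)
  structure(scales, names = acc, class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("property_table with", length(x), "scales:\n")
  for (s in x) cat(" ", s$accession, "-", s$description, "\n")
  invisible(x)
}

#' Parse AAIndex1 flat-file text into property scales
#'
#' Understands the `H` (accession), `D` (description) and `I` (coefficient)
#' records of the AAIndex1 format. The `I` record carries 20 values over two
#' lines in the canonical A/L, R/K, N/M, D/F, C/P, Q/S, E/T, G/W, H/Y, I/V
#' layout. Entries are terminated by `//`.
#'
#' @param text character vector: lines of AAIndex1 content, or a single string
#'   containing newlines.
#' @return list of `property_scale` objects, one per entry.
#' @export
parse_aaindex1 <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  scales <- list()
  acc <- NULL; desc <- ""; values <- numeric(0); in_i <- FALSE
  flush_entry <- function() {
    if (is.null(acc)) return(invisible(NULL))
    if (length(values) != 20L) {
      stop("malformed AAIndex1 entry '", acc, "': expected 20 coefficients, got ",
           length(values), call. = FALSE)
    }
    names(values) <- AAINDEX_RESIDUE_ORDER
    scales[[length(scales) + 1L]] <<- new_property_scale(acc, desc, values)
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 1L)
    if (tag == "H") {
      acc <- trimws(substr(ln, 2L, nchar(ln)))
      if (!nzchar(acc)) stop("AAIndex1 entry with empty accession", call. = FALSE)
      desc <- ""; values <- numeric(0); in_i <- FALSE
    } else if (tag == "D") {
      desc <- trimws(substr(ln, 2L, nchar(ln))); in_i <- FALSE
    } else if (tag == "I") {
      in_i <- TRUE
    } else if (startsWith(ln, "//")) {
      flush_entry()
      acc <- NULL; in_i <- FALSE
    } else if (in_i && grepl("^\\s", ln)) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (any(tok == "NA")) {
        stop("AAIndex1 entry '", acc, "' contains NA coefficients and cannot be used",
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(tok))
      if (anyNA(num)) {
        stop("malformed AAIndex1 entry '", acc, "': non-numeric coefficient line", call. = FALSE)
      }
      values <- c(values, num)
    } else {
      in_i <- FALSE
    }
  }
  if (!is.null(acc)) {
    stop("malformed AAIndex1 input: unterminated entry '", acc, "'", call. = FALSE)
  }
  scales
}

#' Load the packaged table of sixteen property scales
#'
#' Reads the vendored AAIndex1 flat file shipped with the package and returns
#' the sixteen scales in their fixed encoding order (PRAM900101 first,
#' ZIMJ680104 last).
#'
#' @return A `property_table` of length 16.
#' @export
load_paper_table <- function() {
  path <- system.file("extdata", "aaindex_table1.txt", package = "sumohunt")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged AAIndex data file is missing; reinstall the package", call. = FALSE)
  }
  scales <- parse_aaindex1(readLines(path))
  tab <- property_table(scales)
  if (length(tab) != 16L || !identical(names(tab), SUMOHUNT_ACCESSIONS)) {
    stop("packaged AAIndex data file is corrupt: accession set or order is wrong",
         call. = FALSE)
  }
  tab
}

#' Look up a property coefficient for a residue
#'
#' The padding symbol `X` (used where a window overhangs a sequence terminus)
#' encodes as the unweighted mean of the scale's 20 coefficients, preserving
#' fixed dimensionality without biasing towards any particular residue.
#'
#' @param table a `property_table`.
#' @param scale_index 1-based index into the table.
#' @param residue single one-letter residue code, or `"X"`.
#' @return The scalar coefficient.
#' @export
residue_value <- function(table, scale_index, residue) {
  if (scale_index < 1L || scale_index > length(table)) {
    stop("scale_index out of range [1, ", length(table), "]", call. = FALSE)
  }
  co <- table[[scale_index]]$coefficients
  if (residue == "X") return(mean(co))
  v <- co[residue]
  if (is.na(v)) {
    stop("unknown residue '", residue, "' (not one of the 20 standard codes or 'X')",
         call. = FALSE)
  }
  unname(v)
}

#' Serialize a property table to AAIndex1 flat-file text
#'
#' Inverse of [parse_aaindex1()] up to numeric formatting; round-trips
#' coefficient values exactly (written with full precision).
#' @param table a `property_table`.
#' @return character scalar of AAIndex1 text.
#' @export
serialize_aaindex1 <- function(table) {
  entry <- function(s) {
    v <- s$coefficients
    paste0(
      "H ", s$accession, "\n",
      "D ", s$description, "\n",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V\n",
      "    ", paste(format(v[1:10], digits = 17, trim = TRUE), collapse = " "), "\n",
      "    ", paste(format(v[11:20], digits = 17, trim = TRUE), collapse = " "), "\n",
      "//"
    )
  }
  paste(vapply(table, entry, character(1)), collapse = "\n")
}

#' Export a property table as JSON (for provenance records)
#'
#' @param table a `property_table`.
#' @return JSON string with accession, description and named coefficients per
#'   scale, in table order.
#' @export
property_table_json <- function(table) {
  jsonlite::toJSON(
    lapply(unname(table), function(s) {
      list(accession = s$accession, description = s$description,
           coefficients = as.list(s$coefficients))
    }),
    auto_unbox = TRUE, digits = NA
  )
}
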