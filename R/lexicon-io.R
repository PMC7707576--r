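#' Read cognate-coded wordlists
#'
#' Parses an ABVD-style delimited text export (one row per word form,
#' with its language, semantic unit, cognate-set id and loan flag) into a
#' [CognateMatrix-class].  The delimiter (comma or tab) is auto-detected
#' from the header line; a header is required.  Duplicate rows collapse
#' under the set semantics of the matrix.
#'
#' @param source path to a UTF-8 CSV/TSV file, or a connection.
#' @param schema named character vector mapping the canonical field names
#'   `language`, `concept`, `form`, `cognate_set`, `loan` to the column
#'   names used in the file.  Defaults to the identity mapping.
#' @param quiet suppress the row/language/concept count message.
#' @return A [CognateMatrix-class] whose `attested` flag is `TRUE`
#'   exactly for the (language, concept) cells with at least one row.
#' @export
readWordlists <- function(source, schema = NULL, quiet = FALSE) {
  canonical <- c("language", "concept", "form", "cognate_set", "loan")
  if (is.null(schema)) schema <- stats::setNames(canonical, canonical)
  if (!all(canonical %in% names(schema)))
    stop("schema must map all of: ", paste(canonical, collapse = ", "))
  raw <- .readDelimAuto(source)
  missing_cols <- setdiff(unname(schema[canonical]), names(raw))
  if (length(missing_cols))
    stop("wordlist is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  e <- data.frame(language = as.character(raw[[schema[["language"]]]]),
                  concept = as.character(raw[[schema[["concept"]]]]),
                  cognate_set = as.character(raw[[schema[["cognate_set"]]]]),
                  form = as.character(raw[[schema[["form"]]]]),
                  loan = .parseLoan(raw[[schema[["loan"]]]]),
                  stringsAsFactors = FALSE)
  m <- CognateMatrix(e)
  if (!quiet)
    message("read ", nrow(raw), " rows: ", length(m@languages),
            " languages, ", length(m@concepts), " concepts")
  m
}

.readDelimAuto <- function(source) {
  if (is.character(source)) {
    header <- readLines(source, n = 1L, encoding = "UTF-8")
    if (!length(header)) stop("empty wordlist file: ", source)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0)
      "\t" else ","
    utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", encoding = "UTF-8",
                      check.names = FALSE, comment.char = "")
  } else {
    utils::read.csv(source, colClasses = "character", check.names = FALSE)
  }
}

.parseLoan <- function(v) {
  if (is.logical(v)) return(ifelse(is.na(v), FALSE, v))
  v <- tolower(trimws(as.character(v)))
  out <- v %in% c("true", "t", "1", "yes", "y", "l")
  out
}

#' Write a CognateMatrix as a canonical wordlist file
#'
#' Emits the entry table in the same five-column dialect that
#' [readWordlists()] accepts, so read -> write -> read round-trips.
#' Cells that are attested but hold no entries (possible after
#' [filterLoans()]) have no row representation and are not preserved;
#' write before filtering when the attestation distinction matters.
#'
#' @param x A [CognateMatrix-class].
#' @param path output file path.
#' @param sep field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
writeWordlists <- function(x, path, sep = ",") {
  stopifnot(is(x, "CognateMatrix"))
  e <- x@entries
  e$loan <- ifelse(e$loan, "TRUE", "FALSE")
  utils::write.table(e, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove loan-flagged entries
#'
#' Identified loan words are excluded from rate counting so that shared
#' cognates reflect inheritance, not borrowing.  The attestation flag is
#' untouched: a cell whose only entries were loans stays attested (the
#' concept was collected for that language) but becomes empty, and is
#' therefore still eligible for counting.
#'
#' @param x A [CognateMatrix-class].
#' @param quiet suppress the removed-entry count message.
#' @return A [CognateMatrix-class] without loan entries.
#' @export
filterLoans <- function(x, quiet = FALSE) {
  stopifnot(is(x, "CognateMatrix"))
  keep <- !x@entries$loan
  if (!quiet && any(!keep))
    message("removed ", sum(!keep), " loan-flagged entries")
  e <- x@entries[keep, , drop = FALSE]
  rownames(e) <- NULL
  new("CognateMatrix", entries = e, languages = x@languages,
      concepts = x@concepts, attested = x@attested)
}

#' Restrict a CognateMatrix to a set of languages
#'
#' Used to carve an analysis sample out of a larger family background
#' (for example, keeping the full family for background cognate lookups
#' while restricting statistics to sampled languages).  Concepts are
#' unchanged.
#'
#' @param x A [CognateMatrix-class].
#' @param keep character vector of language ids to keep
#'   (must all be present in `x`).
#' @return A [CognateMatrix-class] over exactly `keep`.
#' @export
restrictToLanguages <- function(x, keep) {
  stopifnot(is(x, "CognateMatrix"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, x@languages)
  if (length(unknown))
    stop("unknown language id(s): ", paste(unknown, collapse = ", "))
  e <- x@entries[x@entries$language %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  att <- x@attested[match(keep, x@languages), , drop = FALSE]
  new("CognateMatrix", entries = e, languages = keep,
      concepts = x@concepts, attested = att)
}
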