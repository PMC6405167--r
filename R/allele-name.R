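#' Recognised HLA loci
#'
#' The classical class I and class II loci handled by the package, plus the
#' secondary DR-beta loci that exist only on some DR haplotypes.
#'
#' @format Character vector of locus symbols.
#' @export
HLA_LOCI <- c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5", "DQB1", "DPB1")

CLASS_I_LOCI <- c("A", "B", "C")
CLASS_II_LOCI <- c("DRB1", "DRB3", "DRB4", "DRB5", "DQB1", "DPB1")

#' Parse a WHO-nomenclature HLA allele name
#'
#' Decomposes an allele label such as `"DRB1*04:01"` into its locus and
#' colon-separated numeric fields.  A bare field list (`"04:01"`) is accepted
#' when `locus` is supplied by the caller.  Names with more than `max_fields`
#' fields (e.g. `"DRB1*04:01:01G"`) are truncated to the working resolution;
#' an expression suffix letter (N, L, S, C, A, Q) attached to a *retained*
#' field is preserved.
#'
#' @param text Allele label, with or without the `LOCUS*` prefix.
#' @param locus Locus symbol used when `text` carries no prefix.
#' @param max_fields Number of fields kept (default 2, protein-level
#'   resolution; all downstream analyses work at two-field resolution).
#' @return An object of class `hla_allele`: a list with elements `locus`,
#'   `fields` (character vector of zero-padded numeric fields) and `suffix`
#'   (single letter or `NA`).
#' @seealso [format_allele_name()]
#' @examples
#' parse_allele_name("DRB1*04:01")
#' parse_allele_name("02:01", locus = "A")
#' @export
parse_allele_name <- function(text, locus = NULL, max_fields = 2L) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "") stop("empty allele name", call. = FALSE)
  if (grepl("*", text, fixed = TRUE)) {
    parts <- strsplit(text, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("malformed allele name (multiple '*'): '", text, "'", call. = FALSE)
    }
    locus <- parts[[1L]]
    body <- parts[[2L]]
  } else {
    if (is.null(locus)) {
      stop("allele name '", text, "' has no locus prefix and no locus was supplied",
           call. = FALSE)
    }
    body <- text
  }
  if (!locus %in% HLA_LOCI) {
    stop("unknown HLA locus: '", locus, "'", call. = FALSE)
  }
  fields <- strsplit(body, ":", fixed = TRUE)[[1L]]
  if (length(fields) == 0L || any(fields == "")) {
    stop("malformed field list in allele name: '", text, "'", call. = FALSE)
  }
  suffix <- NA_character_
  last <- fields[[length(fields)]]
  m <- regmatches(last, regexec("^([0-9]+)([A-Z])$", last))[[1L]]
  if (length(m) == 3L) {
    fields[[length(fields)]] <- m[[2L]]
    suffix <- m[[3L]]
  }
  bad <- fields[!grepl("^[0-9]+$", fields)]
  if (length(bad) > 0L) {
    stop("non-numeric allele field '", bad[[1L]], "' in '", text, "'", call. = FALSE)
  }
  if (length(fields) > max_fields) {
    fields <- fields[seq_len(max_fields)]
    suffix <- NA_character_  # suffix belonged to a dropped field
  }
  structure(list(locus = locus, fields = fields, suffix = suffix),
            class = "hla_allele")
}

#' Format an HLA allele name
#'
#' Inverse of [parse_allele_name()]: rebuilds the WHO-nomenclature string.
#'
#' @param allele An `hla_allele` object.
#' @param with_locus Include the `LOCUS*` prefix (default `TRUE`).
#' @return Character scalar.
#' @export
format_allele_name <- function(allele, with_locus = TRUE) {
  stopifnot(inherits(allele, "hla_allele"))
  body <- paste(allele$fields, collapse = ":")
  if (!is.na(allele$suffix)) body <- paste0(body, allele$suffix)
  if (with_locus) paste0(allele$locus, "*", body) else body
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(format_allele_name(x), "\n")
  invisible(x)
}

# Canonical two-field cell value used inside cohort tables: no locus prefix,
# truncated to two fields, suffix (if any) kept.
normalize_call <- function(text, locus) {
  format_allele_name(parse_allele_name(text, locus = locus), with_locus = FALSE)
}
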