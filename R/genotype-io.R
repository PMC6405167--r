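#' Construct a case-control HLA cohort
#'
#' A cohort is a flat table with one row per subject: `subject_id`, `group`
#' (`"case"` or `"control"`) and two columns per locus (`A_1`, `A_2`, ...)
#' holding two-field allele calls without the locus prefix.  A missing
#' genotype at a locus is a pair of `NA` cells; a homozygote repeats the
#' allele in both cells.
#'
#' @param genotypes Data frame in the layout above.  Allele cells are assumed
#'   already normalised (see [read_genotypes()], which normalises on load).
#' @return An object of class `hla_cohort`.
#' @export
hla_cohort <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  need <- c("subject_id", "group")
  if (!all(need %in% names(genotypes))) {
    stop("cohort table must have columns 'subject_id' and 'group'", call. = FALSE)
  }
  genotypes$subject_id <- as.character(genotypes$subject_id)
  genotypes$group <- tolower(as.character(genotypes$group))
  if (anyDuplicated(genotypes$subject_id)) {
    dup <- unique(genotypes$subject_id[duplicated(genotypes$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(genotypes$group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  loci <- cohort_loci_from_names(names(genotypes))
  for (loc in loci) {
    a1 <- genotypes[[paste0(loc, "_1")]]
    a2 <- genotypes[[paste0(loc, "_2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop("locus ", loc, ": exactly one of the two allele cells is blank at row(s) ",
           paste(which(half), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(genotypes = genotypes, loci = loci), class = "hla_cohort")
}

cohort_loci_from_names <- function(nm) {
  cand <- sub("_1$", "", grep("_1$", nm, value = TRUE))
  cand <- cand[paste0(cand, "_2") %in% nm]
  bad <- setdiff(cand, HLA_LOCI)
  if (length(bad) > 0L) {
    stop("unknown locus column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cand[order(match(cand, HLA_LOCI))]
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat(sprintf("hla_cohort: %d cases, %d controls; loci: %s\n",
              n_cases(x), n_controls(x), paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Cohort group sizes
#'
#' @param cohort An `hla_cohort`.
#' @return Integer count of case (resp. control) subjects.
#' @export
n_cases <- function(cohort) sum(cohort$genotypes$group == "case")

#' @rdname n_cases
#' @export
n_controls <- function(cohort) sum(cohort$genotypes$group == "control")

#' Read a genotype table
#'
#' Reads a delimited genotype file with header
#' `subject_id,group,A_1,A_2,...` (any subset of the recognised loci).
#' Blank cells are missing; an allele cell may carry the locus prefix
#' (`DRB1*04:01`) or not (`04:01`) and is normalised to two-field resolution
#' on load (higher-resolution calls are truncated).
#'
#' @param path Path to a CSV (or other single-character-delimited) file.
#' @param sep Field separator, default `","`.
#' @return An [hla_cohort()].
#' @export
read_genotypes <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), strip.white = TRUE)
  loci <- cohort_loci_from_names(names(raw))
  for (loc in loci) {
    for (col in paste0(loc, c("_1", "_2"))) {
      v <- raw[[col]]
      ok <- !is.na(v)
      raw[[col]][ok] <- vapply(v[ok], normalize_call, character(1L), locus = loc)
    }
  }
  hla_cohort(raw)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]; a write/read cycle reproduces the cohort
#' exactly.
#'
#' @param cohort An `hla_cohort`.
#' @param path Output path.
#' @param sep Field separator, default `","`.
#' @export
write_genotypes <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "hla_cohort"))
  utils::write.table(cohort$genotypes, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

CATALOG_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "-", "*")

#' Construct an aligned allele protein catalog
#'
#' Holds, per locus, the aligned mature-protein residues of each allele as a
#' character matrix (alleles x positions) whose column names are 1-based
#' mature-protein coordinates.  `'*'` marks an unknown residue; unknown
#' residues never match a motif and never generate one.
#'
#' @param sequences Named list: one element per locus, itself a list with
#'   `start` (integer, first aligned position) and `seqs` (named character
#'   vector, allele name -> aligned sequence).  Within a locus all sequences
#'   must have equal length.  A `'-'` in any sequence after the first is
#'   resolved at load to the residue of the first (reference) allele at that
#'   column.
#' @return An object of class `hla_catalog`: named list of per-locus residue
#'   matrices with attribute `start`.
#' @export
hla_catalog <- function(sequences) {
  stopifnot(is.list(sequences), length(names(sequences)) == length(sequences))
  bad <- setdiff(names(sequences), HLA_LOCI)
  if (length(bad) > 0L) stop("unknown locus: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(names(sequences), function(loc) {
    el <- sequences[[loc]]
    seqs <- el$seqs
    start <- as.integer(el$start %||% 1L)
    if (start < 1L) stop("locus ", loc, ": start_position must be >= 1", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("locus ", loc, ": aligned sequences have unequal lengths", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
    bad_chr <- setdiff(unique(as.vector(mat)), CATALOG_ALPHABET)
    if (length(bad_chr) > 0L) {
      stop("locus ", loc, ": residue(s) outside alphabet: ",
           paste(bad_chr, collapse = " "), call. = FALSE)
    }
    # '-' = identical to the reference (first) allele at that column
    ref <- mat[1L, ]
    if (any(ref == "-")) {
      stop("locus ", loc, ": reference (first) allele may not contain '-'", call. = FALSE)
    }
    gap <- mat == "-"
    if (any(gap)) mat[gap] <- ref[col(mat)[gap]]
    colnames(mat) <- as.character(seq(start, length.out = ncol(mat)))
    attr(mat, "start") <- start
    mat
  })
  names(out) <- names(sequences)
  structure(out, class = "hla_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hla_catalog <- function(x, ...) {
  for (loc in names(x)) {
    cat(sprintf("%s: %d alleles, positions %s-%s\n", loc, nrow(x[[loc]]),
                colnames(x[[loc]])[1L], colnames(x[[loc]])[ncol(x[[loc]])]))
  }
  invisible(x)
}

#' Read an allele protein catalog
#'
#' Reads a TSV with columns `locus`, `allele`, `start_position`, `sequence`
#' (one row per allele; aligned residues, alphabet = 20 amino-acid letters,
#' `'-'` for identity with the locus reference, `'*'` for unknown).
#'
#' @param path Path to the TSV file.
#' @return An [hla_catalog()].
#' @export
read_catalog <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  need <- c("locus", "allele", "start_position", "sequence")
  if (!all(need %in% names(raw))) {
    stop("catalog file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  seqs <- lapply(split(raw, factor(raw$locus, levels = unique(raw$locus))),
                 function(d) {
    start <- unique(as.integer(d$start_position))
    if (length(start) != 1L) {
      stop("locus ", d$locus[[1L]], ": inconsistent start_position", call. = FALSE)
    }
    s <- d$sequence
    names(s) <- vapply(d$allele, normalize_call, character(1L),
                       locus = d$locus[[1L]])
    list(start = start, seqs = s)
  })
  hla_catalog(seqs)
}

#' Write an allele protein catalog
#'
#' Sequences are written fully resolved (no `'-'` placeholders), so a
#' write/read cycle reproduces the catalog exactly.
#'
#' @param catalog An `hla_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "hla_catalog"))
  rows <- do.call(rbind, lapply(names(catalog), function(loc) {
    mat <- catalog[[loc]]
    data.frame(locus = loc, allele = rownames(mat),
               start_position = attr(mat, "start"),
               sequence = apply(mat, 1L, paste, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count carriers of each allele at a locus
#'
#' A subject is a carrier of an allele if at least one of its two calls at
#' the locus equals that allele; a homozygote counts once.  Denominators are
#' the per-group numbers of subjects with a non-missing genotype at this
#' locus (per-locus denominators, matching typing dropout).
#'
#' @param cohort An `hla_cohort`.
#' @param locus Locus symbol.
#' @return Data frame with one row per allele observed in either group:
#'   `locus`, `allele`, `case_carriers`, `case_total`, `control_carriers`,
#'   `control_total`, sorted by allele name.  Empty (0-row) if the locus was
#'   never typed.
#' @export
carrier_counts <- function(cohort, locus) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (nrow(cohort$genotypes) == 0L) stop("empty cohort", call. = FALSE)
  empty <- data.frame(locus = character(), allele = character(),
                      case_carriers = integer(), case_total = integer(),
                      control_carriers = integer(), control_total = integer(),
                      stringsAsFactors = FALSE)
  if (!locus %in% cohort$loci) return(empty)
  g <- cohort$genotypes
  a1 <- g[[paste0(locus, "_1")]]
  a2 <- g[[paste0(locus, "_2")]]
  typed <- !is.na(a1)
  if (!any(typed)) return(empty)
  a1 <- a1[typed]; a2 <- a2[typed]
  is_case <- g$group[typed] == "case"
  alleles <- sort(unique(c(a1, a2)))
  carrier <- vapply(alleles, function(al) a1 == al | a2 == al,
                    logical(length(a1)))
  carrier <- matrix(carrier, ncol = length(alleles))
  data.frame(locus = locus, allele = alleles,
             case_carriers = as.integer(colSums(carrier[is_case, , drop = FALSE])),
             case_total = sum(is_case),
             control_carriers = as.integer(colSums(carrier[!is_case, , drop = FALSE])),
             control_total = sum(!is_case),
             stringsAsFactors = FALSE, row.names = NULL)
}
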