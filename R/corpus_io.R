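#' @title Corpus input/output
#' @description Read and write a barcode corpus stored as a FASTA file plus
#'   a tab-separated metadata table. The metadata dialect is fixed:
#'   UTF-8, header row, columns `accession`, `release_date`, `lineage`,
#'   `country`, `journal`, `study_id`. Dates are ISO 8601 (`YYYY-MM-DD`);
#'   the deposition year is always derived from the date, never stored.
#'   Missing country/journal/study_id are empty fields in the TSV and `NA`
#'   in R.
#' @name corpus_io
NULL

CORPUS_META_COLS <- c("accession", "release_date", "lineage",
                      "country", "journal", "study_id")

IUPAC_REGEX <- "^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$"

#' Read a corpus from FASTA + metadata TSV
#'
#' FASTA ids (up to the first whitespace) and the metadata `accession`
#' column must be in bijection. Records are returned in metadata row
#' order. Any missing or duplicate accession, unparseable release date or
#' non-IUPAC nucleotide symbol is a hard error naming the offending
#' accession; records without a release date are rejected because the
#' temporal audit is meaningless without one.
#'
#' @param fasta_path Path to the FASTA file.
#' @param metadata_path Path to the metadata TSV (see [corpus_io]).
#' @param placeholders Lineage placeholder tokens, see [parse_lineage()].
#' @return A `data.frame` with columns `accession`, `sequence`,
#'   `release_date` (`Date`), the seven rank columns of [RANKS] (`NA` =
#'   unidentified), `country`, `journal`, `study_id` and derived `year`.
#' @export
read_corpus <- function(fasta_path, metadata_path,
                        placeholders = default_placeholders()) {
  # readDNAStringSet silently drops invalid letters; escalate to an error
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(fasta_path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("unknown nucleotide symbol(s) in FASTA file ", fasta_path)
      }
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     colClasses = "character", na.strings = NULL,
                     quote = "", check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(CORPUS_META_COLS, names(meta))
  if (length(missing_cols)) {
    stop("metadata TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  acc <- meta$accession
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in metadata: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  only_meta <- setdiff(acc, ids)
  only_fa <- setdiff(ids, acc)
  if (length(only_meta) || length(only_fa)) {
    stop("FASTA/metadata accession mismatch.",
         if (length(only_meta)) paste0(" Missing from FASTA: ",
                                       paste(only_meta, collapse = ", "), "."),
         if (length(only_fa)) paste0(" Missing from metadata: ",
                                     paste(only_fa, collapse = ", "), "."))
  }
  seq_chr <- as.character(seqs)[match(acc, ids)]
  bad_nt <- !grepl(IUPAC_REGEX, seq_chr)
  if (any(bad_nt)) {
    stop("non-IUPAC nucleotide symbols (or empty sequence) in: ",
         paste(acc[bad_nt], collapse = ", "))
  }
  dates <- parse_iso_date(meta$release_date, acc)
  lin <- do.call(rbind, lapply(meta$lineage, parse_lineage,
                               placeholders = placeholders))
  records <- data.frame(
    accession = acc,
    sequence = toupper(seq_chr),
    release_date = dates,
    lin,
    country = empty_to_na(meta$country),
    journal = empty_to_na(meta$journal),
    study_id = empty_to_na(meta$study_id),
    year = as.integer(format(dates, "%Y")),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  records
}

parse_iso_date <- function(x, acc) {
  x <- trimws(x)
  bad_form <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  d[!bad_form] <- as.Date(x[!bad_form], format = "%Y-%m-%d")
  bad <- bad_form | is.na(d)
  if (any(bad)) {
    stop("unparseable or missing release_date for: ",
         paste(paste0(acc[bad], " (", x[bad], ")"), collapse = ", "))
  }
  d
}

empty_to_na <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  x
}

#' Write a corpus to FASTA + metadata TSV
#'
#' Inverse of [read_corpus()]: `read_corpus()` followed by
#' `write_corpus()` reproduces the metadata TSV byte-identically (modulo
#' line endings).
#'
#' @param records Corpus `data.frame` as returned by [read_corpus()].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `records`.
#' @export
write_corpus <- function(records, fasta_path, metadata_path) {
  validate_corpus(records)
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- records$accession
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  meta <- data.frame(
    accession = records$accession,
    release_date = format(records$release_date, "%Y-%m-%d"),
    lineage = format_lineage(records),
    country = records$country,
    journal = records$journal,
    study_id = records$study_id,
    stringsAsFactors = FALSE
  )
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(records)
}

#' Validate corpus invariants
#'
#' Checks accession uniqueness, the IUPAC alphabet, date validity and the
#' presence of all rank columns. Called by [write_corpus()] and the
#' pipeline entry points; fails with an informative error.
#'
#' @param records Corpus `data.frame`.
#' @return Invisibly `TRUE`.
#' @export
validate_corpus <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("accession", "sequence", "release_date", RANKS)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("corpus lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$accession)) {
    stop("duplicate accessions: ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "))
  }
  bad_nt <- !grepl(IUPAC_REGEX, records$sequence)
  if (any(bad_nt)) {
    stop("non-IUPAC sequences for: ",
         paste(records$accession[bad_nt], collapse = ", "))
  }
  if (!inherits(records$release_date, "Date") ||
      anyNA(records$release_date)) {
    stop("release_date must be a Date vector without NAs")
  }
  invisible(TRUE)
}
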