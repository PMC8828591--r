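#' Normalize a journal name for matching
#'
#' Case-folds, collapses whitespace, maps `&` to `and` and strips other
#' punctuation, so that e.g. `"Studies  in Mycology"` and
#' `"studies in mycology."` compare equal. How INSDC REFERENCE-field
#' journal strings map onto a curated journal list is a convention, not
#' something the data dictates; this normalization is that convention.
#'
#' @param x Character vector of journal names.
#' @return Normalized character vector.
#' @export
normalize_journal <- function(x) {
  x <- tolower(x)
  x <- gsub("&", " and ", x, fixed = TRUE)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x
}

#' Read a journal list file
#'
#' One journal name per line; `#` starts a comment; blank lines ignored.
#' Names are normalized with [normalize_journal()] before storage.
#'
#' @param path Path to the list file.
#' @return Object of class `journal_list` (a normalized character vector).
#' @export
read_journal_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  journal_list(lines)
}

#' Construct a journal list from names
#'
#' @param names Character vector of journal names.
#' @return Object of class `journal_list`.
#' @export
journal_list <- function(names) {
  structure(unique(normalize_journal(names)), class = "journal_list")
}

#' Path to the bundled synthetic mycology-journal fixture
#'
#' A clearly synthetic placeholder standing in for a curated list of
#' mycological journals (the real curated list is not redistributed).
#' 29 invented names, for tests and the corpus generator.
#'
#' @return File path within the installed package.
#' @export
synthetic_journal_fixture <- function() {
  system.file("extdata", "journals_synthetic.txt", package = "darktaxa",
              mustWork = TRUE)
}

#' Is a journal mycological?
#'
#' Membership of the normalized name in the journal list. Records without
#' a journal (direct submissions, unpublished studies) are scored
#' non-mycological.
#'
#' @param journal Character vector of journal names (`NA` = absent).
#' @param jl A `journal_list`.
#' @return Logical vector.
#' @export
is_mycology_journal <- function(journal, jl) {
  stopifnot(inherits(jl, "journal_list"))
  out <- normalize_journal(ifelse(is.na(journal), "", journal)) %in%
    unclass(jl)
  out & !is.na(journal)
}

#' Mycologist fractions
#'
#' Journal-based scoring of depositors: the fraction of close-match false
#' negatives (`FN_CLOSE` queries) whose study was published in a
#' mycological journal, and the fraction of fully identified records
#' (carrying a complete binomial, see [is_fully_identified()]) from
#' mycological journals.
#'
#' @param results Per-query audit table (needs `accession`,
#'   `classification`), e.g. from [audit_corpus()].
#' @param records Corpus `data.frame`.
#' @param jl A `journal_list`.
#' @return List with `fn_close_myc_fraction`, `n_fn_close`,
#'   `fully_identified_myc_fraction`, `n_fully_identified`. Fractions are
#'   `NA` when their denominator is zero.
#' @export
mycologist_fractions <- function(results, records, jl) {
  fn_acc <- results$accession[results$classification == "FN_CLOSE"]
  fn_j <- records$journal[match(fn_acc, records$accession)]
  full <- is_fully_identified(records)
  full_j <- records$journal[full]
  frac <- function(j) if (length(j)) mean(is_mycology_journal(j, jl)) else NA_real_
  list(
    fn_close_myc_fraction = frac(fn_j),
    n_fn_close = length(fn_j),
    fully_identified_myc_fraction = frac(full_j),
    n_fully_identified = length(full_j)
  )
}

#' Country-of-collection comparison
#'
#' For records with a known country of collection (and, by default, an
#' associated publication, approximated by journal presence), computes
#' each country's share among the sequences annotated to at least the
#' phylum level and its share among the kingdom-level sequences. The
#' table is ranked by the phylum-level share, keeping the top `top_n`
#' countries, ties broken alphabetically.
#'
#' @param records Corpus `data.frame`.
#' @param top_n Number of countries to keep (default 15).
#' @param publication_associated Restrict to records with a journal
#'   (default `TRUE`).
#' @return `data.frame` with `country`, `phylum_prop`, `kingdom_prop`,
#'   `phylum_n`, `kingdom_n`, in decreasing `phylum_prop` order, with
#'   group totals attached as attributes `n_phylum_total` /
#'   `n_kingdom_total`.
#' @export
country_comparison <- function(records, top_n = 15L,
                               publication_associated = TRUE) {
  keep <- !is.na(records$country)
  if (publication_associated) keep <- keep & !is.na(records$journal)
  sub <- records[keep, , drop = FALSE]
  if (!nrow(sub)) {
    out <- data.frame(country = character(0), phylum_prop = numeric(0),
                      kingdom_prop = numeric(0), phylum_n = integer(0),
                      kingdom_n = integer(0))
    attr(out, "n_phylum_total") <- 0L
    attr(out, "n_kingdom_total") <- 0L
    return(out)
  }
  depth <- annotation_depth(sub)
  is_kingdom <- depth == "kingdom"
  tab <- function(mask) table(factor(sub$country[mask],
                                     levels = sort(unique(sub$country))))
  n_ph <- tab(!is_kingdom)
  n_kg <- tab(is_kingdom)
  phylum_prop <- if (sum(n_ph) > 0) as.numeric(n_ph) / sum(n_ph) else
    rep(0, length(n_ph))
  kingdom_prop <- if (sum(n_kg) > 0) as.numeric(n_kg) / sum(n_kg) else
    rep(0, length(n_kg))
  out <- data.frame(country = names(n_ph),
                    phylum_prop = phylum_prop,
                    kingdom_prop = kingdom_prop,
                    phylum_n = as.integer(n_ph),
                    kingdom_n = as.integer(n_kg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$phylum_prop, out$country), , drop = FALSE]
  out <- head(out, top_n)
  rownames(out) <- NULL
  attr(out, "n_phylum_total") <- sum(!is_kingdom)
  attr(out, "n_kingdom_total") <- sum(is_kingdom)
  out
}

#' Yearly false-negative trend
#'
#' Per deposition year, the fraction of that year's kingdom-level queries
#' classified `FN_CLOSE` and `FN_REASONABLE`. Years without queries get
#' `NA` fractions.
#'
#' @param results Per-query audit table (`accession`, `classification`).
#' @param records Corpus `data.frame`.
#' @param years Inclusive integer range of years (default 2001-2020).
#' @return `data.frame` with `year`, `n_queries`, `fn_close_frac`,
#'   `fn_reasonable_frac`.
#' @export
yearly_fn_trend <- function(results, records, years = 2001:2020) {
  yr <- records$year[match(results$accession, records$accession)]
  out <- data.frame(year = years, n_queries = 0L,
                    fn_close_frac = NA_real_,
                    fn_reasonable_frac = NA_real_)
  for (k in seq_along(years)) {
    sel <- which(yr == years[k])
    out$n_queries[k] <- length(sel)
    if (length(sel)) {
      cls <- results$classification[sel]
      out$fn_close_frac[k] <- mean(cls == "FN_CLOSE")
      out$fn_reasonable_frac[k] <- mean(cls == "FN_REASONABLE")
    }
  }
  out
}
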