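#' Taxonomic ranks, shallowest to deepest
#'
#' The seven Linnean ranks used throughout the package, ordered from
#' kingdom (shallowest) to species (deepest).
#'
#' @format Character vector of length 7.
#' @export
RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Index of a rank in the kingdom-to-species order
#'
#' @param rank Character vector of rank names (subset of [RANKS]).
#' @return Integer vector of positions (kingdom = 1, species = 7).
#' @export
rank_index <- function(rank) {
  i <- match(rank, RANKS)
  if (anyNA(i)) {
    stop("unknown rank(s): ", paste(rank[is.na(i)], collapse = ", "))
  }
  i
}

#' Default placeholder tokens treated as "unidentified"
#'
#' Lineage fields equal to one of these tokens (case-insensitive, after
#' whitespace trimming) carry no taxonomic information and are parsed as
#' unidentified slots.
#'
#' @return Character vector of placeholder tokens.
#' @export
default_placeholders <- function() {
  c("", "unidentified", "sp.", "incertae sedis")
}

#' Parse a semicolon-delimited seven-rank lineage
#'
#' Splits a string of the form
#' `"Fungi;Basidiomycota;Agaricomycetes;Agaricales;Amanitaceae;Amanita;Amanita muscaria"`
#' into a named lineage vector. Empty fields and placeholder tokens become
#' `NA` (unidentified). Gaps are allowed: a rank may be unidentified while a
#' deeper rank carries a name.
#'
#' @param text Single string with exactly 7 semicolon-separated fields,
#'   kingdom first.
#' @param placeholders Tokens treated as unidentified
#'   (default [default_placeholders()]).
#' @return Named character vector of length 7 (names = [RANKS]); `NA` marks
#'   an unidentified slot.
#' @examples
#' parse_lineage("Fungi;;;;;;")
#' parse_lineage("Fungi;Ascomycota;;;;;")
#' @export
parse_lineage <- function(text, placeholders = default_placeholders()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  n_sep <- lengths(regmatches(text, gregexpr(";", text, fixed = TRUE)))
  if (n_sep != 6L) {
    stop("lineage must have exactly 7 semicolon-separated fields, got ",
         n_sep + 1L, ": ", text)
  }
  fields <- strsplit(text, ";", fixed = TRUE)[[1L]]
  fields <- c(fields, rep("", 7L - length(fields)))  # trailing empties
  fields <- trimws(fields)
  unid <- tolower(fields) %in% tolower(placeholders)
  fields[unid] <- NA_character_
  names(fields) <- RANKS
  fields
}

#' Format a lineage back to its semicolon-delimited form
#'
#' Inverse of [parse_lineage()]: unidentified slots become empty fields.
#'
#' @param lineage Named character vector of length 7 (or a 7-column matrix,
#'   one row per lineage).
#' @return Character vector of semicolon-delimited lineage strings.
#' @export
format_lineage <- function(lineage) {
  m <- as_lineage_matrix(lineage)
  m[is.na(m)] <- ""
  apply(m, 1L, paste, collapse = ";")
}

# Coerce a single lineage vector, a list of them, or an n x 7 matrix /
# data.frame with rank columns into an n x 7 character matrix.
as_lineage_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 7L)
    colnames(x) <- RANKS
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(all(RANKS %in% names(x)))
    return(as.matrix(x[, RANKS, drop = FALSE]))
  }
  if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(l) {
      stopifnot(length(l) == 7L)
      as.character(l)
    }))
    colnames(m) <- RANKS
    return(m)
  }
  stopifnot(is.character(x), length(x) == 7L)
  matrix(x, nrow = 1L, dimnames = list(NULL, RANKS))
}

#' Deepest identified rank of a lineage
#'
#' A lineage identified only at the kingdom slot is "kingdom-level"; gaps do
#' not matter, only the deepest identified slot counts.
#'
#' @param lineage A lineage vector, list of lineages, or n x 7 matrix.
#' @return Ordered factor over [RANKS], one element per lineage.
#' @export
annotation_depth <- function(lineage) {
  m <- as_lineage_matrix(lineage)
  if (any(is.na(m[, "kingdom"]))) {
    stop("kingdom slot unidentified: record not attributable to a kingdom")
  }
  idx <- apply(!is.na(m), 1L, function(r) max(which(r)))
  factor(RANKS[idx], levels = RANKS, ordered = TRUE)
}

#' Is a lineage carrying a full (non-provisional) species name?
#'
#' `TRUE` iff the species slot is identified and the name does not look
#' provisional (by default: ends in " sp." or contains "uncultured",
#' case-insensitively).
#'
#' @param lineage A lineage vector, list of lineages, or n x 7 matrix.
#' @param provisional_patterns Case-insensitive regular expressions marking
#'   provisional epithets.
#' @return Logical vector, one element per lineage.
#' @export
is_fully_identified <- function(lineage,
                                provisional_patterns = c(" sp\\.$",
                                                         "uncultured")) {
  m <- as_lineage_matrix(lineage)
  sp <- m[, "species"]
  ok <- !is.na(sp)
  for (pat in provisional_patterns) {
    ok <- ok & !grepl(pat, ifelse(is.na(sp), "", sp), ignore.case = TRUE)
  }
  unname(ok)
}

#' Worked-example lineages
#'
#' Two classic agaric lineages (the fly agaric *Amanita muscaria* and the
#' chanterelle *Cantharellus cibarius*) that share the class Agaricomycetes
#' but diverge at the order level. They are used throughout the
#' documentation and tests of the consensus algorithm: together they
#' resolve to a class-level consensus with a conflict flagged at the order
#' rank.
#'
#' @return Named list with elements `amanita_muscaria` and
#'   `cantharellus_cibarius`, each a 7-slot lineage vector.
#' @examples
#' ex <- worked_example_lineages()
#' resolve_consensus(rbind(ex$amanita_muscaria, ex$cantharellus_cibarius))
#' @export
worked_example_lineages <- function() {
  list(
    amanita_muscaria = parse_lineage(
      "Fungi;Basidiomycota;Agaricomycetes;Agaricales;Amanitaceae;Amanita;Amanita muscaria"),
    cantharellus_cibarius = parse_lineage(
      "Fungi;Basidiomycota;Agaricomycetes;Cantharellales;Cantharellaceae;Cantharellus;Cantharellus cibarius")
  )
}
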