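#' Conflict-aware consensus lineage
#'
#' Assigns the most resolved lineage compatible with every member
#' annotation, ignoring low-resolution (unidentified) slots as long as
#' they are not contradictory. Walking from kingdom to species, each rank
#' collects the distinct identified names among the members: none leaves
#' the rank unidentified (deeper ranks may still be assigned across the
#' gap); exactly one assigns that name; two or more is a conflict - the
#' consensus is unidentified from that rank downwards and the rank is
#' reported as `conflict_rank`.
#'
#' A set of five *Amanita muscaria* annotations plus one "Basidiomycota
#' sp." therefore resolves to the full *Amanita muscaria* lineage, whereas
#' *Amanita muscaria* together with *Cantharellus cibarius* (same class,
#' different orders) resolves to the class Agaricomycetes with a conflict
#' at the order rank.
#'
#' Name comparison is exact string equality after whitespace
#' normalization and case-folding; no synonym resolution is attempted.
#' When members spell an agreeing name differently, the lexicographically
#' smallest spelling is reported, keeping the result invariant under
#' permutations of the input.
#'
#' @param lineages A lineage vector, list of lineage vectors, or n x 7
#'   matrix / data.frame with rank columns (one row per member).
#' @return Object of class `consensus_result`: list with `lineage`
#'   (named character(7), `NA` = unidentified) and `conflict_rank`
#'   (rank name, or `NA` when no conflict).
#' @examples
#' ex <- worked_example_lineages()
#' resolve_consensus(rbind(ex$amanita_muscaria, ex$cantharellus_cibarius))
#' @export
resolve_consensus <- function(lineages) {
  m <- as_lineage_matrix(lineages)
  if (nrow(m) == 0L) stop("resolve_consensus: empty input")
  out <- setNames(rep(NA_character_, 7L), RANKS)
  conflict <- NA_character_
  for (r in RANKS) {
    names_r <- m[, r]
    names_r <- names_r[!is.na(names_r)]
    if (!length(names_r)) next
    norm <- normalize_name(names_r)
    uniq <- unique(norm)
    if (length(uniq) == 1L) {
      out[r] <- sort(unique(names_r), method = "radix")[1L]
    } else {
      conflict <- r
      break
    }
  }
  structure(list(lineage = out, conflict_rank = conflict),
            class = "consensus_result")
}

normalize_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Is there an annotation conflict at a given rank?
#'
#' `TRUE` iff at least two distinct identified names occur at rank `r`
#' among the lineages; unidentified slots are never contradictory.
#'
#' @param lineages See [resolve_consensus()].
#' @param r Rank name (one of [RANKS]).
#' @return Logical scalar.
#' @export
has_conflict_at <- function(lineages, r) {
  stopifnot(r %in% RANKS)
  m <- as_lineage_matrix(lineages)
  names_r <- m[, r]
  names_r <- names_r[!is.na(names_r)]
  length(unique(normalize_name(names_r))) >= 2L
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus lineage:", format_lineage(x$lineage), "\n")
  cat("Conflict rank:    ",
      if (is.na(x$conflict_rank)) "none" else x$conflict_rank, "\n")
  invisible(x)
}
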