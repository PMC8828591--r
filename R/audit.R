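#' Availability policy
#'
#' A reference sequence is considered available to a query iff it was
#' released at least `lag_days` calendar days before the query (default
#' 7, leaving the depositor room for a final pre-release check of their
#' annotations). Time of day is ignored; the comparison is on calendar
#' dates.
#'
#' @param lag_days Non-negative integer number of days.
#' @return Object of class `availability_policy`.
#' @export
availability_policy <- function(lag_days = 7L) {
  stopifnot(length(lag_days) == 1L, !is.na(lag_days), lag_days >= 0)
  structure(list(lag_days = as.integer(lag_days)),
            class = "availability_policy")
}

#' Which records were available before a query?
#'
#' @param records Corpus `data.frame`.
#' @param q Accession of the query record.
#' @param policy An [availability_policy()].
#' @return Character vector of available accessions (never includes the
#'   query itself).
#' @export
available_before <- function(records, q, policy = availability_policy()) {
  qi <- match(q, records$accession)
  if (is.na(qi)) stop("query accession not in corpus: ", q)
  diff <- as.integer(records$release_date[qi] - records$release_date)
  records$accession[diff >= policy$lag_days &
                      records$accession != q]
}

# Precomputed per-corpus context shared by classify_query/audit_corpus.
audit_context <- function(records, clusters) {
  depth <- annotation_depth(records)
  lin <- as_lineage_matrix(records)
  ord <- match(records$accession, clusters$accession)
  if (anyNA(ord)) stop("clusters do not cover the corpus")
  list(
    acc = records$accession,
    date = records$release_date,
    depth_i = as.integer(depth),           # 1 = kingdom ... 7 = species
    identified = !is.na(lin),              # n x 7 logical
    sh_id = clusters$sh_id[ord],
    cc_id = clusters$compound_id[ord]
  )
}

classify_one <- function(ctx, qi, lag) {
  avail <- as.integer(ctx$date[qi] - ctx$date) >= lag
  avail[qi] <- FALSE
  sh_mem <- which(ctx$sh_id == ctx$sh_id[qi] & avail)
  cc_mem <- which(ctx$cc_id == ctx$cc_id[qi] & avail)
  close_hit <- any(ctx$depth_i[sh_mem] > 1L)
  reasonable_hit <- any(ctx$depth_i[cc_mem] > 1L)
  classification <- if (close_hit) "FN_CLOSE" else
    if (reasonable_hit) "FN_REASONABLE" else "TP"
  rank_avail <- function(mem) {
    if (length(mem)) apply(ctx$identified[mem, , drop = FALSE], 2L, any)
    else setNames(rep(FALSE, 7L), RANKS)
  }
  hit_props <- function(mem) {
    if (length(mem)) {
      vapply(1:7, function(r) mean(ctx$depth_i[mem] >= r), numeric(1))
    } else rep(NA_real_, 7L)
  }
  list(
    accession = ctx$acc[qi],
    classification = classification,
    n_available_sh = length(sh_mem),
    n_available_cc = length(cc_mem),
    rank_available_close = rank_avail(sh_mem),
    rank_available_reasonable = rank_avail(cc_mem),
    hitlist_close_props = setNames(hit_props(sh_mem), RANKS),
    hitlist_reasonable_props = setNames(hit_props(cc_mem), RANKS)
  )
}

#' Classify one kingdom-level query
#'
#' Replays the deposition history for a single kingdom-level sequence:
#' `FN_CLOSE` if some available co-member of its species hypothesis is
#' annotated beyond the kingdom (a close, top-of-the-hit-list match was
#' there to copy from); otherwise `FN_REASONABLE` if some available
#' member of its compound cluster is; otherwise `TP` - a genuinely
#' unidentifiable dark-taxon candidate at its deposition date.
#'
#' Per-rank availability flags record whether some available co-member
#' carries an identified name at exactly that rank; hit-list proportions
#' give the fraction of available co-members annotated at least to each
#' rank (`NA` when no co-member was available). The query itself never
#' counts.
#'
#' @param records Corpus `data.frame`.
#' @param clusters A `cluster_set` from [cluster_corpus()].
#' @param q Accession of a kingdom-level record.
#' @param policy An [availability_policy()].
#' @return List with `accession`, `classification`, `n_available_sh`,
#'   `n_available_cc`, per-rank logical vectors `rank_available_close` /
#'   `rank_available_reasonable` and numeric vectors
#'   `hitlist_close_props` / `hitlist_reasonable_props`.
#' @export
classify_query <- function(records, clusters, q,
                           policy = availability_policy()) {
  ctx <- audit_context(records, clusters)
  qi <- match(q, ctx$acc)
  if (is.na(qi)) stop("query accession not in corpus: ", q)
  if (ctx$depth_i[qi] != 1L) {
    stop("query ", q, " is not kingdom-level (depth = ",
         RANKS[ctx$depth_i[qi]], ")")
  }
  classify_one(ctx, qi, policy$lag_days)
}

#' Audit a corpus: classify every kingdom-level sequence
#'
#' Runs [classify_query()] for every kingdom-level record and aggregates
#' the summary report: classification counts and fractions, per-rank
#' name-availability fractions over all queries (close and
#' close-or-reasonable scenarios), mean hit-list composition per rank
#' (over queries with a non-empty hit list), the median available
#' species-hypothesis size and mean available compound-cluster size at
#' deposition time (excluding and including the query itself), and
#' phylum-level annotation conflict rates over SHs and compound clusters.
#'
#' @param records Corpus `data.frame`.
#' @param clusters A `cluster_set`.
#' @param policy An [availability_policy()].
#' @return List with `report` (class `audit_report`) and `results`, a
#'   per-query `data.frame` with the classification, per-rank flags
#'   (`avail_close_*`, `avail_reasonable_*`), hit-list proportions
#'   (`hit_close_*`, `hit_reasonable_*`) and availability counts.
#' @export
audit_corpus <- function(records, clusters, policy = availability_policy()) {
  validate_corpus(records)
  ctx <- audit_context(records, clusters)
  queries <- which(ctx$depth_i == 1L)
  rows <- lapply(queries, classify_one, ctx = ctx, lag = policy$lag_days)
  results <- audit_results_frame(rows)
  report <- audit_report(results, records, clusters)
  list(report = report, results = results)
}

audit_results_frame <- function(rows) {
  if (!length(rows)) {
    cols <- c("accession", "classification", "n_available_sh",
              "n_available_cc",
              paste0("avail_close_", RANKS),
              paste0("avail_reasonable_", RANKS),
              paste0("hit_close_", RANKS),
              paste0("hit_reasonable_", RANKS))
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    df$accession <- character(0)
    df$classification <- character(0)
    return(df)
  }
  df <- data.frame(
    accession = vapply(rows, `[[`, character(1), "accession"),
    classification = vapply(rows, `[[`, character(1), "classification"),
    n_available_sh = vapply(rows, `[[`, integer(1), "n_available_sh"),
    n_available_cc = vapply(rows, `[[`, integer(1), "n_available_cc"),
    stringsAsFactors = FALSE
  )
  grab <- function(field) {
    t(vapply(rows, function(r) as.numeric(r[[field]]), numeric(7)))
  }
  ac <- grab("rank_available_close") > 0
  ar <- grab("rank_available_reasonable") > 0
  hc <- grab("hitlist_close_props")
  hr <- grab("hitlist_reasonable_props")
  colnames(ac) <- paste0("avail_close_", RANKS)
  colnames(ar) <- paste0("avail_reasonable_", RANKS)
  colnames(hc) <- paste0("hit_close_", RANKS)
  colnames(hr) <- paste0("hit_reasonable_", RANKS)
  cbind(df, ac, ar, hc, hr)
}

audit_report <- function(results, records, clusters) {
  n_q <- nrow(results)
  counts <- c(TP = sum(results$classification == "TP"),
              FN_CLOSE = sum(results$classification == "FN_CLOSE"),
              FN_REASONABLE = sum(results$classification == "FN_REASONABLE"))
  fractions <- if (n_q > 0) counts / n_q else
    setNames(rep(NA_real_, 3L), names(counts))
  col_mean <- function(prefix, mask = rep(TRUE, n_q)) {
    cols <- paste0(prefix, RANKS)
    if (n_q == 0 || !any(mask)) {
      return(setNames(rep(NA_real_, 7L), RANKS))
    }
    setNames(colMeans(results[mask, cols, drop = FALSE]), RANKS)
  }
  has_sh <- results$n_available_sh >= 1L
  has_cc <- results$n_available_cc >= 1L
  lin <- as_lineage_matrix(records)
  ord <- match(clusters$accession, records$accession)
  conflict_rate <- function(group) {
    grps <- split(ord, group)
    mean(vapply(grps, function(ix) {
      has_conflict_at(lin[ix, , drop = FALSE], "phylum")
    }, logical(1)))
  }
  structure(list(
    n_queries = n_q,
    counts = counts,
    fractions = fractions,
    fn_any_fraction = if (n_q > 0)
      unname(fractions["FN_CLOSE"] + fractions["FN_REASONABLE"])
    else NA_real_,
    rank_availability_close = col_mean("avail_close_"),
    rank_availability_reasonable = col_mean("avail_reasonable_"),
    hitlist_mean_close = col_mean("hit_close_", has_sh),
    hitlist_mean_reasonable = col_mean("hit_reasonable_", has_cc),
    median_sh_size_excl = if (any(has_sh))
      median(results$n_available_sh[has_sh]) else NA_real_,
    median_sh_size_incl = if (any(has_sh))
      median(results$n_available_sh[has_sh] + 1L) else NA_real_,
    mean_cc_size_excl = if (any(has_cc))
      mean(results$n_available_cc[has_cc]) else NA_real_,
    mean_cc_size_incl = if (any(has_cc))
      mean(results$n_available_cc[has_cc] + 1L) else NA_real_,
    conflict_rate_sh_phylum = conflict_rate(clusters$sh_id),
    conflict_rate_cc_phylum = conflict_rate(clusters$compound_id)
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", 100 * v))
  cat("Annotation-gap audit report\n")
  cat("  kingdom-level queries:", x$n_queries, "\n")
  if (x$n_queries > 0) {
    cat(sprintf("  FN_CLOSE      %6d (%s)\n",
                x$counts["FN_CLOSE"], pct(x$fractions["FN_CLOSE"])))
    cat(sprintf("  FN_REASONABLE %6d (%s)\n",
                x$counts["FN_REASONABLE"], pct(x$fractions["FN_REASONABLE"])))
    cat(sprintf("  TP            %6d (%s)\n",
                x$counts["TP"], pct(x$fractions["TP"])))
    cat("  false negatives overall:", pct(x$fn_any_fraction), "\n")
    cat("  name availability (close), phylum..species:",
        paste(pct(x$rank_availability_close[-1]), collapse = " "), "\n")
    cat("  name availability (close+reasonable):",
        paste(pct(x$rank_availability_reasonable[-1]), collapse = " "), "\n")
    cat("  median SH size at deposition (excl/incl query):",
        x$median_sh_size_excl, "/", x$median_sh_size_incl, "\n")
    cat("  mean compound-cluster size (excl/incl query):",
        round(x$mean_cc_size_excl, 1), "/",
        round(x$mean_cc_size_incl, 1), "\n")
  } else {
    cat("  no kingdom-level queries in the corpus\n")
  }
  cat(sprintf("  phylum conflict rate: %.2f%% of SHs, %.2f%% of compound clusters\n",
              100 * x$conflict_rate_sh_phylum,
              100 * x$conflict_rate_cc_phylum))
  invisible(x)
}

#' Write the per-query audit table to TSV
#'
#' @param results Per-query `data.frame` from [audit_corpus()].
#' @param path Output path.
#' @return Invisibly `results`.
#' @export
write_audit_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(results)
}
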