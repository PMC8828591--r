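#' Clustering configuration
#'
#' Thresholds and alignment scoring for the two-level cluster structure:
#' compound clusters at >= 80% global identity, sub-partitioned into
#' single-linkage species hypotheses (SHs) at a distance threshold from
#' the ladder 0.0%-3.0% in steps of 0.5% (default 3.0%).
#'
#' Identity is computed from the optimal global alignment under the
#' configured scoring (match +1, mismatch -1, -2 per gap column) as the
#' fraction of identical columns after trimming terminal-gap columns, so
#' length differences between query and reference do not depress identity.
#' Ambiguity codes never count as identical columns.
#'
#' @param compound_identity_threshold Minimum identity to join a compound
#'   cluster (fraction, default 0.80).
#' @param sh_distance_threshold Single-linkage distance threshold for SHs
#'   (fraction, default 0.030).
#' @param match,mismatch,gap Alignment scoring parameters.
#' @param ladder_mode When `TRUE` (default), `sh_distance_threshold` must
#'   lie on the 0.000-0.030 (step 0.005) ladder.
#' @return Object of class `clustering_config`.
#' @export
clustering_config <- function(compound_identity_threshold = 0.80,
                              sh_distance_threshold = 0.030,
                              match = 1, mismatch = -1, gap = -2,
                              ladder_mode = TRUE) {
  stopifnot(compound_identity_threshold > 0,
            compound_identity_threshold < 1,
            sh_distance_threshold >= 0,
            sh_distance_threshold <= 1 - compound_identity_threshold + 1e-12)
  if (ladder_mode) {
    ladder <- sh_ladder()
    if (min(abs(ladder - sh_distance_threshold)) > 1e-9) {
      stop("sh_distance_threshold must lie on the ladder ",
           paste(format(ladder), collapse = ", "),
           " (set ladder_mode = FALSE to lift this)")
    }
  }
  structure(list(compound_identity_threshold = compound_identity_threshold,
                 sh_distance_threshold = sh_distance_threshold,
                 match = match, mismatch = mismatch, gap = gap,
                 ladder_mode = ladder_mode),
            class = "clustering_config")
}

#' The SH distance-threshold ladder: 0.0% to 3.0% in steps of 0.5%
#' @return Numeric vector of the seven ladder thresholds.
#' @export
sh_ladder <- function() seq(0, 0.030, by = 0.005)

#' Pairwise global sequence identity
#'
#' Identity between two IUPAC DNA strings under the optimal global
#' alignment with the configured scoring; see [clustering_config()] for
#' the exact definition. Ties among optimal alignments are resolved by a
#' fixed deterministic traceback preference (match/mismatch, then gap in
#' `a`, then gap in `b`).
#'
#' @param a,b Non-empty DNA strings.
#' @param cfg A [clustering_config()].
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' global_identity("ACGTACGTAC", "ACGTACGTAT")  # 0.9
#' @export
global_identity <- function(a, b, cfg = clustering_config()) {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  cpp_global_identity(a, b, cfg$match, cfg$mismatch, cfg$gap)
}

# Unique k-mer sets used by the optional prefilter. Pairs sharing no k-mer
# are assumed to be far below any clustering threshold and skip the
# alignment; this is a pure optimization and must not change results on
# corpora with the divergence guards in place.
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy centroid compound clustering
#'
#' USEARCH-style greedy clustering at the compound identity threshold:
#' records are processed in order of decreasing sequence length (ties by
#' ascending accession); each record joins the first existing centroid
#' with identity at or above the threshold, otherwise it founds a new
#' centroid. Fully deterministic.
#'
#' @param records Corpus `data.frame` (needs `accession`, `sequence`).
#' @param cfg A [clustering_config()].
#' @param prefilter Use the shared-k-mer prefilter to skip hopeless
#'   alignments (default `FALSE`).
#' @param kmer Prefilter k-mer size.
#' @return Named list of character vectors: compound cluster id ->
#'   member accessions (each cluster's centroid first).
#' @export
build_compound_clusters <- function(records, cfg = clustering_config(),
                                    prefilter = FALSE, kmer = 12L) {
  ord <- order(-nchar(records$sequence), records$accession)
  acc <- records$accession[ord]
  seqs <- records$sequence[ord]
  n <- length(acc)
  ksets <- if (prefilter) lapply(seqs, kmer_set, k = kmer) else NULL
  centroid_idx <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(centroid_idx)) {
      j <- centroid_idx[ci]
      if (prefilter && !any(ksets[[i]] %in% ksets[[j]])) next
      idy <- cpp_global_identity(seqs[i], seqs[j],
                                 cfg$match, cfg$mismatch, cfg$gap)
      if (idy >= cfg$compound_identity_threshold - 1e-9) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, i)
      hit <- length(centroid_idx)
    }
    assign[i] <- hit
  }
  ids <- sprintf("CC%04d", seq_along(centroid_idx))
  out <- split(acc, factor(ids[assign], levels = ids))
  # centroid first, then joining order (= processing order) is preserved
  lapply(out, as.character)
}

#' Single-linkage species hypotheses within one compound cluster
#'
#' Partitions the members of a compound cluster into the connected
#' components of the graph with an edge between two members whenever
#' their alignment distance (1 - identity) is at or below the SH
#' threshold. Single linkage: transitive chains merge even when some
#' member pairs exceed the threshold.
#'
#' @param records Corpus `data.frame`.
#' @param members Accessions of one compound cluster.
#' @param cfg A [clustering_config()].
#' @param prefilter,kmer See [build_compound_clusters()].
#' @return List of character vectors (the SHs), ordered by their smallest
#'   member accession; members sorted by accession.
#' @export
build_species_hypotheses <- function(records, members,
                                     cfg = clustering_config(),
                                     prefilter = FALSE, kmer = 12L) {
  idx <- match(members, records$accession)
  if (anyNA(idx)) stop("members absent from corpus: ",
                       paste(members[is.na(idx)], collapse = ", "))
  acc <- sort(records$accession[idx])
  seqs <- records$sequence[match(acc, records$accession)]
  n <- length(acc)
  if (n == 0L) return(list())
  ksets <- if (prefilter) lapply(seqs, kmer_set, k = kmer) else NULL
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  thr <- cfg$sh_distance_threshold + 1e-9
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      if (find(i) == find(j)) next  # already linked; edge cannot change components
      if (prefilter && !any(ksets[[i]] %in% ksets[[j]])) next
      idy <- cpp_global_identity(seqs[i], seqs[j],
                                 cfg$match, cfg$mismatch, cfg$gap)
      if (1 - idy <= thr) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(acc, roots)
  comps <- comps[order(vapply(comps, min, character(1)))]
  unname(comps)
}

#' Cluster a corpus into compound clusters and species hypotheses
#'
#' Runs [build_compound_clusters()] then [build_species_hypotheses()]
#' within each compound cluster, and validates the partition invariants.
#'
#' @inheritParams build_compound_clusters
#' @return A `cluster_set`: `data.frame` with columns `accession`,
#'   `compound_id`, `sh_id` (SH ids are nested, e.g. `CC0001.SH01`), in
#'   corpus record order, with the configuration attached as attribute
#'   `config`.
#' @export
cluster_corpus <- function(records, cfg = clustering_config(),
                           prefilter = FALSE, kmer = 12L) {
  ccs <- build_compound_clusters(records, cfg, prefilter, kmer)
  rows <- lapply(names(ccs), function(cc_id) {
    shs <- build_species_hypotheses(records, ccs[[cc_id]], cfg,
                                    prefilter, kmer)
    do.call(rbind, lapply(seq_along(shs), function(k) {
      data.frame(accession = shs[[k]],
                 compound_id = cc_id,
                 sh_id = sprintf("%s.SH%02d", cc_id, k),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[match(records$accession, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("cluster_set", "data.frame")
  validate_cluster_set(out, records)
  out
}

#' Validate cluster-set invariants
#'
#' Compound clusters must partition the corpus and every SH must sit
#' inside exactly one compound cluster.
#'
#' @param clusters A `cluster_set` from [cluster_corpus()].
#' @param records The corpus it was built from.
#' @return Invisibly `TRUE`; hard error on violation.
#' @export
validate_cluster_set <- function(clusters, records) {
  stopifnot(is.data.frame(clusters),
            all(c("accession", "compound_id", "sh_id") %in% names(clusters)))
  if (!setequal(clusters$accession, records$accession) ||
      anyDuplicated(clusters$accession)) {
    stop("compound clusters do not partition the corpus")
  }
  cc_of_sh <- tapply(clusters$compound_id, clusters$sh_id,
                     function(x) length(unique(x)))
  if (any(cc_of_sh != 1L)) {
    stop("an SH spans more than one compound cluster")
  }
  invisible(TRUE)
}

#' Write cluster assignments (and per-SH consensus) to TSV
#'
#' Columns: `accession`, `compound_id`, `sh_id`, plus `sh_consensus`
#' (the semicolon-formatted consensus lineage of the record's SH) when
#' `records` is supplied.
#'
#' @param clusters A `cluster_set`.
#' @param path Output TSV path.
#' @param records Optional corpus `data.frame` for the consensus column.
#' @return Invisibly the written `data.frame`.
#' @export
write_clusters <- function(clusters, path, records = NULL) {
  out <- as.data.frame(clusters)[, c("accession", "compound_id", "sh_id")]
  if (!is.null(records)) {
    lin <- as_lineage_matrix(records[match(out$accession,
                                           records$accession), ])
    cons <- vapply(split(seq_len(nrow(out)), out$sh_id), function(ix) {
      format_lineage(resolve_consensus(lin[ix, , drop = FALSE])$lineage)
    }, character(1))
    out$sh_consensus <- cons[out$sh_id]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(out)
}
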