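# Independent oracles and fixture builders. These deliberately do NOT share
# code with the package internals they check: the identity oracle is a
# plain-R full-matrix dynamic program, the component oracle uses igraph,
# and the audit oracle scans all record pairs directly.

BASES <- c("A", "C", "G", "T")

# Full-matrix Needleman-Wunsch in plain R, same scoring and the same
# deterministic tie preference (diagonal, then gap in `a`, then gap in
# `b`), returning identity over the terminal-gap-trimmed alignment.
r_identity_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  m <- length(A)
  n <- length(B)
  S <- matrix(0, m + 1, n + 1)
  P <- matrix("", m + 1, n + 1)
  S[1, ] <- gap * (0:n)
  S[, 1] <- gap * (0:m)
  if (n > 0) P[1, 2:(n + 1)] <- "L"
  if (m > 0) P[2:(m + 1), 1] <- "U"
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      eq <- A[i] == B[j] && A[i] %in% BASES
      d <- S[i, j] + if (eq) match else mismatch
      l <- S[i + 1, j] + gap  # gap in a, consumes B[j]
      u <- S[i, j + 1] + gap  # gap in b, consumes A[i]
      best <- d
      p <- "D"
      if (l > best) { best <- l; p <- "L" }
      if (u > best) { best <- u; p <- "U" }
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- p
    }
  }
  i <- m; j <- n
  colA <- character(0); colB <- character(0)
  while (i > 0 || j > 0) {
    p <- if (i == 0) "L" else if (j == 0) "U" else P[i + 1, j + 1]
    if (p == "D") {
      colA <- c(A[i], colA); colB <- c(B[j], colB); i <- i - 1; j <- j - 1
    } else if (p == "L") {
      colA <- c("-", colA); colB <- c(B[j], colB); j <- j - 1
    } else {
      colA <- c(A[i], colA); colB <- c("-", colB); i <- i - 1
    }
  }
  gapcol <- colA == "-" | colB == "-"
  lo <- 1L
  while (lo <= length(gapcol) && gapcol[lo]) lo <- lo + 1L
  hi <- length(gapcol)
  while (hi >= lo && gapcol[hi]) hi <- hi - 1L
  if (hi < lo) return(0)
  idx <- lo:hi
  mean(colA[idx] == colB[idx] & colA[idx] %in% BASES)
}

# Transitive-closure (connected components) oracle over a full distance
# matrix, via igraph.
igraph_components_oracle <- function(acc, distmat, threshold) {
  adj <- distmat <= threshold + 1e-9
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(acc, comp))
}

# Brute-force audit oracle: classifies every kingdom-level record by
# scanning all pairs with direct identity computation and the date rule,
# bypassing the cluster structure entirely.
brute_force_audit_oracle <- function(records, lag = 7,
                                     close_identity = 0.97,
                                     reasonable_identity = 0.80) {
  depth <- as.integer(annotation_depth(records))
  n <- nrow(records)
  queries <- which(depth == 1L)
  cls <- vapply(queries, function(qi) {
    close <- FALSE
    reasonable <- FALSE
    for (ri in seq_len(n)) {
      if (ri == qi) next
      if (as.integer(records$release_date[qi] - records$release_date[ri]) < lag) next
      if (depth[ri] <= 1L) next
      idy <- global_identity(records$sequence[qi], records$sequence[ri])
      if (idy >= close_identity) close <- TRUE
      else if (idy >= reasonable_identity) reasonable <- TRUE
      if (close) break
    }
    if (close) "FN_CLOSE" else if (reasonable) "FN_REASONABLE" else "TP"
  }, character(1))
  data.frame(accession = records$accession[queries], classification = cls,
             stringsAsFactors = FALSE)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  denom <- (b + cc) / 2 - expected
  if (denom == 0) return(1)
  (a - expected) / denom
}

# ---- fixture builders -------------------------------------------------

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Substitute `k` distinct positions (capped at the sequence length).
mutate_at <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), min(k, length(x)))
  for (p in pos) x[p] <- sample(setdiff(BASES, x[p]), 1)
  paste(x, collapse = "")
}

# Hand-built corpus from parallel vectors; lineages as semicolon strings.
mk_corpus <- function(accession, sequence, release_date, lineage,
                      country = NA_character_, journal = NA_character_,
                      study_id = NA_character_) {
  lin <- do.call(rbind, lapply(lineage, parse_lineage))
  dates <- as.Date(release_date)
  data.frame(accession = accession, sequence = sequence,
             release_date = dates, lin,
             country = rep_len(country, length(accession)),
             journal = rep_len(journal, length(accession)),
             study_id = rep_len(study_id, length(accession)),
             year = as.integer(format(dates, "%Y")),
             stringsAsFactors = FALSE)
}

# Hand-built cluster assignment table (for audit-logic tests that do not
# care about sequence content).
mk_clusters <- function(accession, compound_id, sh_id) {
  data.frame(accession = accession, compound_id = compound_id,
             sh_id = sh_id, stringsAsFactors = FALSE)
}

full_distmat <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- 1 - global_identity(seqs[i], seqs[j])
    }
  }
  d
}
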