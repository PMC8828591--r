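test_that("global identity matches hand-checkable cases", {
  twenty <- paste(rep("ACGT", 5), collapse = "")
  expect_equal(global_identity(twenty, twenty), 1.0)
  # one substitution, ungapped alignment optimal (gap cost > mismatch)
  expect_equal(global_identity("ACGTACGTAC", "ACGTACGTAT"), 0.9)
  # terminal-gap columns are excluded from the denominator
  expect_equal(global_identity("ACGTACGTAC", "CGTACGTAC"), 1.0)
  # ambiguity codes never count as identical columns
  expect_equal(global_identity("ACGN", "ACGN"), 0.75)
  expect_error(global_identity("", "ACGT"))
})

test_that("identity is symmetric, self-identical and in [0, 1]", {
  set.seed(101)
  for (rep in 1:10) {
    a <- rand_seq(sample(5:60, 1))
    b <- rand_seq(sample(5:60, 1))
    ab <- global_identity(a, b)
    expect_identical(ab, global_identity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 1)
    expect_equal(global_identity(a, a), 1.0)
  }
})

test_that("identity agrees with the plain-R dynamic-programming oracle", {
  set.seed(202)
  for (rep in 1:30) {
    a <- rand_seq(sample(3:50, 1))
    b <- if (runif(1) < 0.5) rand_seq(sample(3:50, 1)) else
      mutate_at(a, sample(0:4, 1))
    expect_equal(global_identity(a, b), r_identity_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("greedy centroid clustering handles degenerate inputs", {
  seqs <- rep(paste(rep("ACGT", 25), collapse = ""), 5)
  rec <- mk_corpus(sprintf("A%d", 1:5), seqs,
                   rep("2010-01-01", 5), rep("Fungi;;;;;;", 5))
  cc <- build_compound_clusters(rec)
  expect_length(cc, 1L)
  expect_setequal(cc[[1]], rec$accession)

  single <- rec[1, , drop = FALSE]
  expect_length(build_compound_clusters(single), 1L)
})

test_that("compound clusters recover two planted families", {
  set.seed(303)
  anc1 <- rand_seq(300)
  anc2 <- rand_seq(300)
  seqs <- c(vapply(1:6, function(i) mutate_at(anc1, 8), character(1)),
            vapply(1:6, function(i) mutate_at(anc2, 8), character(1)))
  rec <- mk_corpus(sprintf("S%02d", 1:12), seqs, rep("2010-01-01", 12),
                   rep("Fungi;;;;;;", 12))
  # brute-force identity matrix confirms the planted separation
  d <- full_distmat(rec$sequence)
  intra <- c(d[1:6, 1:6][upper.tri(d[1:6, 1:6])],
             d[7:12, 7:12][upper.tri(d[7:12, 7:12])])
  inter <- d[1:6, 7:12]
  expect_true(all(1 - intra >= 0.90))
  expect_true(all(1 - inter <= 0.60))

  cc <- build_compound_clusters(rec)
  expect_length(cc, 2L)
  truth <- rep(1:2, each = 6)
  memb <- setNames(rep(names(cc), lengths(cc)), unlist(cc))
  expect_equal(adjusted_rand_index(truth, memb[rec$accession]), 1)
})

test_that("species hypotheses are single-linkage transitive closures", {
  # d(a,b) = 0.02, d(b,c) = 0.02, d(a,c) = 0.04: one SH despite a-c > 3%
  set.seed(404)
  b <- rand_seq(100)
  x <- strsplit(b, "")[[1]]
  flip <- function(x, pos) {
    for (p in pos) x[p] <- setdiff(BASES, x[p])[1]
    paste(x, collapse = "")
  }
  a <- flip(x, 1:2)
  cst <- flip(x, 3:4)
  rec <- mk_corpus(c("a", "b", "cst"), c(a, b, cst),
                   rep("2010-01-01", 3), rep("Fungi;;;;;;", 3))
  d <- full_distmat(rec$sequence)
  expect_equal(d[1, 2], 0.02)
  expect_equal(d[1, 3], 0.04)
  shs <- build_species_hypotheses(rec, rec$accession)
  expect_length(shs, 1L)
  expect_setequal(shs[[1]], rec$accession)

  # all pairwise distances above the threshold: all singletons
  far <- mk_corpus(c("x", "y", "z"),
                   c(rand_seq(100), rand_seq(100), rand_seq(100)),
                   rep("2010-01-01", 3), rep("Fungi;;;;;;", 3))
  expect_length(build_species_hypotheses(far, far$accession), 3L)
})

test_that("species hypotheses equal the igraph components oracle", {
  skip_if_not_installed("igraph")
  set.seed(505)
  anc <- rand_seq(200)
  seqs <- vapply(1:20, function(i) mutate_at(anc, sample(0:12, 1)),
                 character(1))
  rec <- mk_corpus(sprintf("M%02d", 1:20), seqs, rep("2010-01-01", 20),
                   rep("Fungi;;;;;;", 20))
  d <- full_distmat(rec$sequence)
  want <- igraph_components_oracle(rec$accession, d, 0.03)
  got <- build_species_hypotheses(rec, rec$accession)
  norm <- function(p) unname(lapply(p, sort)[order(vapply(p, min, character(1)))])
  expect_equal(norm(got), norm(want))
})

test_that("raising the SH threshold only coarsens partitions", {
  set.seed(606)
  anc <- rand_seq(200)
  seqs <- vapply(1:15, function(i) mutate_at(anc, sample(0:10, 1)),
                 character(1))
  rec <- mk_corpus(sprintf("L%02d", 1:15), seqs, rep("2010-01-01", 15),
                   rep("Fungi;;;;;;", 15))
  prev <- NULL
  for (t in sh_ladder()) {
    cfg <- clustering_config(sh_distance_threshold = t)
    part <- build_species_hypotheses(rec, rec$accession, cfg)
    if (!is.null(prev)) {
      for (cl in prev) {
        holders <- vapply(part, function(p) all(cl %in% p), logical(1))
        expect_equal(sum(holders), 1L)  # each finer SH sits inside one coarser SH
      }
    }
    prev <- part
  }
})

test_that("cluster_corpus nests SHs in compound clusters and validates", {
  set.seed(707)
  sim <- simulate_corpus(sim_config(seed = 707, n_families = 3))
  cs <- cluster_corpus(sim$records)
  expect_s3_class(cs, "cluster_set")
  expect_true(validate_cluster_set(cs, sim$records))
  expect_true(all(startsWith(cs$sh_id, cs$compound_id)))
  expect_setequal(cs$accession, sim$records$accession)
})

test_that("the k-mer prefilter does not change clustering results", {
  sim <- simulate_corpus(sim_config(seed = 808, n_families = 4))
  plain <- cluster_corpus(sim$records)
  fast <- cluster_corpus(sim$records, prefilter = TRUE)
  expect_identical(as.data.frame(plain), as.data.frame(fast))
})
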