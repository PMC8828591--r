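seq20 <- function() paste(rep("ACGT", 5), collapse = "")

test_that("availability uses the at-least-seven-days calendar rule", {
  rec <- mk_corpus(c("Q", "R7", "R6", "SAME"),
                   rep(seq20(), 4),
                   c("2010-01-10", "2010-01-03", "2010-01-04", "2010-01-10"),
                   rep("Fungi;;;;;;", 4))
  avail <- available_before(rec, "Q")
  expect_true("R7" %in% avail)    # exactly 7 days satisfies "at least seven"
  expect_false("R6" %in% avail)   # 6 days is too recent
  expect_false("SAME" %in% avail)
  expect_false("Q" %in% avail)    # the query never counts for itself

  # lag 0 admits same-day records (but still never the query)
  avail0 <- available_before(rec, "Q", availability_policy(0))
  expect_setequal(avail0, c("R7", "R6", "SAME"))

  # availability is monotone in the lag: larger lags give subsets
  prev <- avail0
  for (lag in c(3, 7, 30, 400)) {
    cur <- available_before(rec, "Q", availability_policy(lag))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("classify_query covers the close/reasonable/true-positive trichotomy", {
  rec <- mk_corpus(
    accession = c("Q1", "G1", "Q2", "P1", "Q3", "K1", "N1"),
    sequence = rep(seq20(), 7),
    release_date = c("2010-06-01", "2009-01-01",  # Q1 + genus-level SH mate
                     "2010-06-01", "2009-01-01",  # Q2 + phylum-level CC mate
                     "2010-06-01", "2009-01-01", "2010-05-30"),
    lineage = c(
      "Fungi;;;;;;",
      "Fungi;Basidiomycota;Agaricomycetes;Agaricales;Amanitaceae;Amanita;",
      "Fungi;;;;;;",
      "Fungi;Basidiomycota;;;;;",
      "Fungi;;;;;;",
      "Fungi;;;;;;",                               # available but kingdom-only
      "Fungi;Ascomycota;Sordariomycetes;;;;"))     # too recent (2 days)
  cl <- mk_clusters(
    rec$accession,
    compound_id = c("CC1", "CC1", "CC2", "CC2", "CC3", "CC3", "CC3"),
    sh_id = c("CC1.SH1", "CC1.SH1", "CC2.SH1", "CC2.SH2",
              "CC3.SH1", "CC3.SH1", "CC3.SH1"))

  r1 <- classify_query(rec, cl, "Q1")
  expect_equal(r1$classification, "FN_CLOSE")
  expect_equal(unname(r1$rank_available_close[RANKS]),
               c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(r1$hitlist_close_props["genus"]), 1)

  r2 <- classify_query(rec, cl, "Q2")
  expect_equal(r2$classification, "FN_REASONABLE")
  expect_equal(r2$n_available_sh, 0L)
  expect_true(is.na(r2$hitlist_close_props[["phylum"]]))
  expect_equal(unname(r2$hitlist_reasonable_props[["phylum"]]), 1)

  # co-members are kingdom-only or too recent: a true positive
  r3 <- classify_query(rec, cl, "Q3")
  expect_equal(r3$classification, "TP")
  expect_equal(r3$n_available_sh, 1L)  # K1 is available, just uninformative

  expect_error(classify_query(rec, cl, "G1"), "not kingdom-level")
})

test_that("audit_corpus aggregates a constructed one-of-each fixture", {
  rec <- mk_corpus(
    accession = c("Q1", "A1", "Q2", "A2", "Q3", "A3",
                  "F1", "F2", "F3", "F4"),
    sequence = rep(seq20(), 10),
    release_date = c("2010-06-01", "2009-01-01",
                     "2010-06-01", "2009-01-01",
                     "2010-06-01", "2010-05-31",
                     "2008-01-01", "2009-01-01", "2010-01-01", "2011-01-01"),
    lineage = c(
      "Fungi;;;;;;",
      "Fungi;Basidiomycota;Agaricomycetes;Agaricales;Amanitaceae;Amanita;Amanita muscaria",
      "Fungi;;;;;;",
      "Fungi;Basidiomycota;Agaricomycetes;;;;",
      "Fungi;;;;;;",
      "Fungi;Ascomycota;;;;;",
      rep("Fungi;Ascomycota;Sordariomycetes;Hypocreales;Nectriaceae;Fusarium;Fusarium oxysporum", 4)))
  cl <- mk_clusters(
    rec$accession,
    compound_id = c("CC1", "CC1", "CC2", "CC2", "CC3", "CC3",
                    "CC4", "CC4", "CC4", "CC4"),
    sh_id = c("CC1.SH1", "CC1.SH1",            # Q1: close match
              "CC2.SH1", "CC2.SH2",            # Q2: reasonable match only
              "CC3.SH1", "CC3.SH1",            # Q3: mate too recent -> TP
              rep("CC4.SH1", 4)))
  aud <- audit_corpus(rec, cl)
  expect_equal(aud$report$n_queries, 3L)
  expect_equal(unname(aud$report$fractions),
               c(1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(aud$report$fractions), 1, tolerance = 1e-12)
  expect_equal(aud$report$fn_any_fraction, 2 / 3, tolerance = 1e-12)
  # close FN fraction can never exceed the cumulative FN fraction
  expect_lte(aud$report$fractions[["FN_CLOSE"]], aud$report$fn_any_fraction)
  # no phylum conflicts planted anywhere
  expect_equal(aud$report$conflict_rate_sh_phylum, 0)
  expect_equal(aud$report$conflict_rate_cc_phylum, 0)

  # hit-list proportions are antitone in rank depth for gap-free lineages
  hc <- as.numeric(aud$results[1, paste0("hit_close_", RANKS)])
  expect_true(all(diff(hc) <= 1e-12))
})

test_that("corpora without queries or without annotations are handled", {
  rec <- mk_corpus(c("A", "B"), rep(seq20(), 2),
                   c("2010-01-01", "2011-01-01"),
                   rep("Fungi;Ascomycota;;;;;", 2))
  cl <- mk_clusters(rec$accession, rep("CC1", 2), rep("CC1.SH1", 2))
  aud <- audit_corpus(rec, cl)
  expect_equal(aud$report$n_queries, 0L)
  expect_true(all(is.na(aud$report$fractions)))
  expect_equal(nrow(aud$results), 0L)

  # zero annotated records: every query is a true positive
  rec2 <- mk_corpus(c("A", "B", "C"), rep(seq20(), 3),
                    c("2010-01-01", "2011-01-01", "2012-01-01"),
                    rep("Fungi;;;;;;", 3))
  cl2 <- mk_clusters(rec2$accession, rep("CC1", 3), rep("CC1.SH1", 3))
  aud2 <- audit_corpus(rec2, cl2)
  expect_equal(unname(aud2$report$counts["TP"]), 3L)
})

test_that("phylum conflict rates count conflicted groups", {
  rec <- mk_corpus(
    c("A", "B", "C", "D"), rep(seq20(), 4),
    rep("2010-01-01", 4),
    c("Fungi;Ascomycota;;;;;", "Fungi;Basidiomycota;;;;;",
      "Fungi;Ascomycota;;;;;", "Fungi;Ascomycota;;;;;"))
  cl <- mk_clusters(rec$accession,
                    compound_id = c("CC1", "CC1", "CC2", "CC2"),
                    sh_id = c("CC1.SH1", "CC1.SH2", "CC2.SH1", "CC2.SH1"))
  aud <- audit_corpus(rec, cl)
  expect_equal(aud$report$conflict_rate_cc_phylum, 0.5)  # CC1 conflicted
  expect_equal(aud$report$conflict_rate_sh_phylum, 0)    # no SH mixes phyla
})

test_that("pipeline classifications equal the brute-force pairwise oracle", {
  sim <- simulate_corpus(sim_config(seed = 909, n_families = 4,
                                    genera_per_family = 2,
                                    species_per_genus = 2,
                                    seqs_per_species = 3, seq_length = 400))
  expect_equal(nrow(sim$records), 48L)
  cl <- cluster_corpus(sim$records)
  aud <- audit_corpus(sim$records, cl)
  want <- brute_force_audit_oracle(sim$records)
  got <- aud$results[match(want$accession, aud$results$accession), ]
  expect_equal(got$classification, want$classification)
})
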