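---
title: "Auditing the annotation gap in barcode corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the annotation gap in barcode corpora: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darktaxa)
```

## The question the package answers

Environmental sequencing deposits large numbers of fungal ITS barcode
sequences annotated no deeper than the kingdom ("uncultured fungus",
"fungal sp."). Some of these are genuinely unidentifiable — dark-taxon
candidates from unexplored lineages. Many others had a well-annotated,
nearly identical relative sitting in the public databases at the moment
they were deposited, and the low-resolution name reflects depositor
behaviour rather than missing reference data. darktaxa separates the two
cases by replaying deposition history over a clustered corpus.

A kingdom-level *query* is classified as:

* `FN_CLOSE` — some member of its own species hypothesis (SH) was
  *available* (released at least 7 days earlier) and annotated beyond the
  kingdom. A depositor running a similarity search would have seen the name
  among the top hits.
* `FN_REASONABLE` — no such close match, but an available member of its
  compound cluster (≥ 80% identity) was annotated beyond the kingdom: the
  name was further down the hit list.
* `TP` — neither existed; the sequence was a defensible dark-taxon
  candidate at its deposition date.

The 7-day lag models the gap between submission and release during which
the depositor could still have double-checked annotations; availability is
computed on calendar dates, time of day ignored. The query itself never
counts towards its own availability or hit-list statistics.

## Sequence identity and clustering

The corpus is clustered in two levels, standing in for the
production-database practice of 80%-similarity "compound clusters"
sub-clustered into species hypotheses by single linkage at thresholds
0.0%–3.0% in 0.5% steps:

* **Identity kernel.** Pairwise identity is taken from the optimal global
  (Needleman–Wunsch) alignment under match +1, mismatch −1, −2 per gap
  column, as *identical columns / alignment columns after trimming
  terminal-gap columns*. Excluding terminal-gap columns (a semi-global
  flavour) stops length differences between query and reference from
  depressing identity; internal gap columns count against it. IUPAC
  ambiguity codes never count as identical (conservative). The external
  clustering tool the scheme emulates does not publish an exact identity
  definition, so this one is a stated convention, chosen to be simple,
  symmetric and reproducible — not a claim of bit-for-bit equivalence.
* **Determinism.** Ties among optimal alignments are broken by a fixed
  traceback preference (match/mismatch, then gap in the first sequence,
  then gap in the second), evaluated per cell, so reported identities are
  unique. Threshold comparisons use a 1e-9 epsilon so that rational
  identities landing exactly on a threshold (e.g. 97/100 at 3.0%) are not
  misclassified by floating-point representation.
* **Compound clusters** are built greedily: records sorted by decreasing
  length (ties by accession) join the first centroid with identity ≥ 0.80,
  else found a new one. No re-centroiding, no abundance weighting — the
  simplest deterministic greedy-centroid scheme.
* **Species hypotheses** are the connected components of the
  ≤-threshold-distance graph within a compound cluster (single linkage):
  transitive chains merge even when individual pairs exceed the threshold.
  Raising the threshold along the ladder can only coarsen the partition,
  and every SH is nested in exactly one compound cluster; both properties
  are asserted in the tests.
* An optional shared-k-mer prefilter (default off, k = 12) skips alignments
  between pairs sharing no k-mer. It is a pure optimization: the test suite
  asserts it does not change clustering output.

The alignment kernel is compiled (Rcpp). Internally scores are integers;
non-integral scoring configurations are rescaled by an exact common
denominator up to 1000 (else by 10^6), which is exact for any realistic
scoring.

## Consensus taxonomy

Each SH is assigned the most resolved lineage compatible with all member
annotations. Per rank from kingdom to species: no identified names leaves
the rank unidentified (deeper ranks may still be assigned across the gap);
one distinct name is adopted; two or more distinct names stop the walk,
flagging that rank as the conflict rank. Low-resolution annotations are
thereby ignored exactly as long as they are not contradictory. Name
comparison is exact string equality after case-folding and whitespace
collapsing — synonym resolution and backbone reconciliation are assumed to
have happened upstream. When agreeing members spell a name differently the
lexicographically smallest spelling (C-locale) is reported, keeping the
result permutation-invariant. Ranks are treated independently: a conflict
is reported at the shallowest conflicting rank regardless of whether the
conflicting names form internally consistent parent chains.

## Report statistics

Over all kingdom-level queries the report aggregates classification counts
and fractions (these sum to 1 by construction), per-rank name-availability
fractions, mean hit-list composition, cluster sizes and conflict rates.
Points where the underlying bookkeeping was genuinely open, and the
conventions adopted:

* *Per-rank availability* requires an identified name at exactly that rank
  in some available co-member; it is never inferred from a deeper rank.
  Fractions are computed over **all** queries (queries with nothing
  available count as all-false), not only over false negatives.
* *Hit-list composition* (fraction of available co-members annotated at
  least to each rank) is undefined for an empty hit list; such queries are
  excluded from the means but retained in the availability fractions.
* *Cluster size at deposition* counts available co-members. Whether the
  query itself belongs in that count is ambiguous, so both readings are
  reported (`median_sh_size_excl`/`_incl`, `mean_cc_size_excl`/`_incl`);
  "non-singleton" means at least one available co-member.
* *Conflict rates* are the fractions of SHs and of compound clusters whose
  members carry ≥ 2 distinct phylum names, over all clusters in the corpus.

## Metadata analyses

A depositor is scored a "mycologist" iff the record's journal matches a
configurable journal list after normalization (case-folding, whitespace
collapsing, `&` → `and`, punctuation stripped); records without a journal
(direct submissions) are non-mycological. How free-text journal fields map
onto a curated list is a convention — the normalization above is this
package's. The bundled 29-name list is **synthetic** (placeholder names);
real analyses must supply a curated list. The country comparison restricts
to records with a known country and, by default, an associated publication
(approximated by journal presence, the only publication signal in the
metadata schema), then ranks countries by their share among phylum-or-
deeper-annotated records. The yearly trend reports per-year `FN_CLOSE` and
`FN_REASONABLE` fractions among that year's queries, `NA` for empty years.

## The synthetic world

`simulate_corpus()` emulates the audited corpus at desk scale: a balanced
taxonomy (defaults: 84 families × 2 genera × 2 species × 3 records = 1008
records), 550-base sequences, dates uniform over 2001-01-01 to 2020-11-01,
a 12% kingdom-level masking rate and a planted classification mix of
73% / 17% / 10% (`FN_CLOSE`/`FN_REASONABLE`/`TP`) — the masking rate and
mix mirror the magnitudes reported for the real public-database corpus
that motivated the method.

**Divergence model.** The divergence knobs are *tip-to-tip pairwise*
targets: members of two species in one genus differ at ≈ `d_species`
(default 0.10) of their sites, members of two genera in one family at
≈ `d_genus` (0.15); family ancestors are independent random sequences
(pairwise identity ≈ 0.5 after alignment). Branch substitution rates are
derived from these targets (genus branch = (d_genus − d_species)/2, species
branch = (d_species − 2·d_intra)/2). An ancestor-branch-rate reading of the
same knobs would put cross-genus pairs near 75% identity and make planted
families unrecoverable at the 80% compound threshold, contradicting the
package's own recoverability guarantee — hence the pairwise reading.
Construction-time guards enforce the recoverable regime
(`d_intra` < 0.03, `d_genus` < 0.20, `d_family` > 0.20,
2·`d_intra` < `d_species` < `d_genus`). With the defaults the planted
margins are ≈ 4.7 standard deviations for the SH level and ≈ 3.7 for the
compound level at 550 bases, so exact recovery on seeded runs is expected
but not a mathematical certainty at unusual seeds.

**Structural masking.** The class mix is planted constructively, not hoped
for statistically:

* whole *dark families* are fully masked — every record is a `TP` query
  (granularity: one family = `m` queries, so tiny corpora may receive no
  TP stratum);
* in *reasonable families*, the species holding the family's earliest
  record stays fully annotated while whole sampled other species are
  masked (granularity: one species = `seqs_per_species` queries);
* in the remaining *close families*, each species' earliest record is an
  annotated anchor and a sampled subset of later records is masked.

Masked queries dated less than `lag_days` after their anchor are moved to
exactly `lag_days` after it, so anchors always qualify under the
availability policy (a negligible, documented distortion of date
uniformity). Because the strata are whole families/species, planted
fractions hit the targets up to this granularity: the default 1008-record
world realizes (0.727, 0.174, 0.099). The spec-style notion of "tuning
`p_kingdom_mask` to the mix" conflates two controls; here the masking
*rate* (0.12) and the masking *structure* (class mix) are separate knobs.

Non-query records are truncated to a depth drawn from
`depth_mask_distribution` (default mass 0.05/0.08/0.10/0.12/0.25/0.40 over
phylum…species, a skew towards well-annotated records). Journals are drawn
per record (mycological with `p_myc` = 0.22, another named journal with
0.58, else absent); countries from an 18-country geometrically decaying
weight vector with 8% missing. Five RNG streams (topology, sequences,
dates, masking, metadata) are derived from the master seed so changing one
knob perturbs only its own stream.

**What the generator does not emulate.** No indels (the substitution-only
model keeps identity arithmetic predictable; an indel-free world slightly
flatters the aligner), no chimeras or sequencing error, no length
variation, no uneven taxon sampling or deposition bursts, no synonymy or
backbone churn, and dark taxa appear as whole masked families rather than
as phylogenetically novel sequence. A green oracle-equivalence test
therefore establishes that the pipeline machinery is faithful on corpora
satisfying the divergence guards — not that the stand-in clustering
reproduces any particular production database on real data.

**Worked-example fixtures.** Two classical lineages
(`worked_example_lineages()`: the fly agaric and the chanterelle) are
reserved as documentation/test fixtures for the consensus algorithm rather
than injected into generated corpora, whose names stay uniformly
synthetic.

## Validation strategy

Every consequential path is checked against an independent route:

* the compiled identity kernel against a plain-R full-matrix DP oracle
  with the same tie conventions;
* single-linkage SHs against igraph connected components on brute-force
  distance matrices;
* pipeline classifications against `oracle_classify()` (true memberships
  and dates only) and against a brute-force pair-scanning oracle that
  bypasses clustering entirely (0.97/0.80 identity thresholds);
* planted parameters (masking rate, class mix, mycologist rate) against
  their recovered estimates at 3-standard-error or ±0.03 tolerances;
* end-to-end byte determinism of the CLI outputs under a fixed seed.

## Other design choices

* The CLI config file format is JSON rather than YAML: no YAML parser is
  part of the package's dependency footprint, and jsonlite is already
  required for the report output.
* Records without a parseable ISO release date are rejected at read time —
  the audit is meaningless without dates, and failing fast beats silently
  dropping rows.
* Placeholder lineage tokens (`unidentified`, `sp.`, `incertae sedis`,
  empty) parse to unidentified slots; a name like `"Fusarium sp."` in the
  species slot parses as identified but is excluded from "fully
  identified" by the provisional-name patterns (trailing `" sp."` or
  `uncultured`).
* The audit's `report.json` serializes named vectors as JSON objects keyed
  by rank/class name, `NA` as `null`.

## Known limitations

* All-pairs alignment makes clustering quadratic per compound cluster;
  the package targets desk-scale corpora (10^3–10^4 sequences), not the
  full public databases.
* The greedy centroid scheme is order-dependent by design (deterministic,
  but a different stand-in than any specific production pipeline).
* Journal-based mycologist scoring inherits every caveat of its crude
  definition; the package only mechanizes it.
* With very small corpora the masking plant's family/species granularity
  can leave a class stratum empty; the realized mix is always recorded in
  the ground truth's `planted_fractions` attribute.
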