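#' Synthetic corpus configuration
#'
#' Describes a planted world for testing the audit pipeline end to end: a
#' balanced taxonomy (`n_families` families x `genera_per_family` genera x
#' `species_per_genus` species x `seqs_per_species` records), a
#' substitution-only sequence model whose divergences are *tip-to-tip
#' pairwise* targets (members of two species in one genus differ at about
#' `d_species` of their sites, members of two genera in one family at
#' about `d_genus`; family ancestors are independent random sequences, so
#' cross-family divergence is far beyond `d_family`), release dates over
#' `date_range`, and a masking policy that hides the lineage of a
#' controlled subset of records down to the kingdom.
#'
#' Masking is structural so that the planted classification mix is
#' realized by construction rather than hoped for:
#' \itemize{
#'   \item a whole "dark" family is masked for every ~`m` true positives
#'     wanted (`m` = records per family): none of its members ever has an
#'     annotated relative, at any date;
#'   \item in "reasonable" families one anchor species (the one holding
#'     the family's earliest record) stays fully annotated while whole
#'     other species are masked: their members have only family-level
#'     (compound-cluster) matches;
#'   \item in the remaining "close" families the earliest record of each
#'     species is kept as an annotated anchor and a sampled subset of the
#'     later records is masked: each such query has a same-species
#'     annotated match.
#' }
#' Masked queries dated less than `lag_days` after their anchor are moved
#' to exactly `lag_days` after it, so anchors always qualify under the
#' availability policy. The defaults (84 families of 12 records, masking
#' rate 0.12, class mix 73/17/10) realize the planted fractions at the
#' granularity this construction allows.
#'
#' @param seed Integer master seed; all five RNG streams (topology,
#'   sequences, dates, masking, metadata) are derived from it.
#' @param n_families,genera_per_family,species_per_genus,seqs_per_species
#'   Taxonomy shape (counts).
#' @param seq_length Sequence length in bases (default 550, a typical
#'   full-length ITS amplicon).
#' @param d_intra Per-site substitution probability of a record relative
#'   to its species ancestor (default 0.005; within-species pairs then
#'   sit near 99% identity, safely above the 97% close-match threshold).
#' @param d_species Pairwise divergence between species in a genus
#'   (default 0.10).
#' @param d_genus Pairwise divergence between genera in a family
#'   (default 0.15; family members thus stay above 80% identity).
#' @param d_family Guard value for cross-family divergence (default
#'   0.45); construction-time check requires `d_family > 0.20` so planted
#'   compound clusters are recoverable.
#' @param date_range Length-2 `Date` vector (default 2001-01-01 to
#'   2020-11-01, the span of the audited era).
#' @param p_kingdom_mask Fraction of records masked to kingdom-only
#'   (default 0.12).
#' @param class_mix Target mix of planted classes among masked records,
#'   named `FN_CLOSE`, `FN_REASONABLE`, `TP` (default .73/.17/.10).
#' @param depth_mask_distribution Distribution over the truncation depth
#'   of annotated (non-masked) records, named by the ranks phylum to
#'   species.
#' @param p_myc Probability an individual record's journal is drawn from
#'   the mycology list (default 0.22).
#' @param p_journal_other Probability of a named non-mycological journal
#'   (remaining mass = no journal, i.e. direct submission).
#' @param countries Named numeric vector of country sampling weights.
#' @param p_country_missing Probability the country is absent.
#' @param lag_days Availability lag used for anchor date guarantees.
#' @param mycology_journals Character vector of mycological journal names
#'   (default: the bundled synthetic fixture).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 84L,
                       genera_per_family = 2L,
                       species_per_genus = 2L,
                       seqs_per_species = 3L,
                       seq_length = 550L,
                       d_intra = 0.005,
                       d_species = 0.10,
                       d_genus = 0.15,
                       d_family = 0.45,
                       date_range = as.Date(c("2001-01-01", "2020-11-01")),
                       p_kingdom_mask = 0.12,
                       class_mix = c(FN_CLOSE = 0.73, FN_REASONABLE = 0.17,
                                     TP = 0.10),
                       depth_mask_distribution = c(phylum = 0.05,
                                                   class = 0.08,
                                                   order = 0.10,
                                                   family = 0.12,
                                                   genus = 0.25,
                                                   species = 0.40),
                       p_myc = 0.22,
                       p_journal_other = 0.58,
                       countries = default_country_weights(),
                       p_country_missing = 0.08,
                       lag_days = 7L,
                       mycology_journals = NULL) {
  probs <- c(d_intra = d_intra, d_species = d_species, d_genus = d_genus,
             d_family = d_family, p_kingdom_mask = p_kingdom_mask,
             p_myc = p_myc, p_journal_other = p_journal_other,
             p_country_missing = p_country_missing, class_mix,
             depth_mask_distribution)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  # divergence guards: planted clusters must be recoverable
  if (d_intra >= 1 - 0.97) {
    stop("sim_config: d_intra must be < 0.03 so within-species pairs stay ",
         "above the 97% close-match identity")
  }
  if (d_family <= 1 - 0.80) {
    stop("sim_config: d_family must be > 0.20 so families separate at the ",
         "80% compound threshold")
  }
  if (d_genus >= 0.20) {
    stop("sim_config: d_genus must be < 0.20 so family members stay above ",
         "80% identity")
  }
  if (d_species <= 2 * d_intra || d_genus <= d_species) {
    stop("sim_config: need 2*d_intra < d_species < d_genus")
  }
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            seqs_per_species >= 1, seq_length >= 1,
            length(date_range) == 2L, inherits(date_range, "Date"),
            date_range[1] <= date_range[2],
            abs(sum(class_mix) - 1) < 1e-9,
            all(c("FN_CLOSE", "FN_REASONABLE", "TP") %in% names(class_mix)),
            abs(sum(depth_mask_distribution) - 1) < 1e-9,
            all(names(depth_mask_distribution) %in% RANKS[-1]),
            p_myc + p_journal_other <= 1, lag_days >= 0)
  if (is.null(mycology_journals)) {
    mycology_journals <- readLines(synthetic_journal_fixture(),
                                   encoding = "UTF-8", warn = FALSE)
    mycology_journals <- trimws(sub("#.*$", "", mycology_journals))
    mycology_journals <- mycology_journals[nzchar(mycology_journals)]
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 seqs_per_species = as.integer(seqs_per_species),
                 seq_length = as.integer(seq_length),
                 d_intra = d_intra, d_species = d_species,
                 d_genus = d_genus, d_family = d_family,
                 date_range = date_range,
                 p_kingdom_mask = p_kingdom_mask, class_mix = class_mix,
                 depth_mask_distribution = depth_mask_distribution,
                 p_myc = p_myc, p_journal_other = p_journal_other,
                 countries = countries,
                 p_country_missing = p_country_missing,
                 lag_days = as.integer(lag_days),
                 mycology_journals = mycology_journals),
            class = "sim_config")
}

#' Default country sampling weights for the generator
#'
#' Eighteen countries with geometrically decaying weights - a caricature
#' of the skew of real collection metadata, not an estimate of it.
#'
#' @return Named numeric vector of weights (not normalized).
#' @export
default_country_weights <- function() {
  countries <- c("USA", "China", "Sweden", "Germany", "Canada", "Estonia",
                 "Spain", "Finland", "Norway", "Thailand", "Brazil",
                 "Japan", "Australia", "India", "France", "Italy",
                 "Mexico", "South Africa")
  setNames(0.85 ^ (seq_along(countries) - 1), countries)
}

# Derived sub-seed for a named stream; kept below 2^31.
stream_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1000003) %% 2147483647
}

mutate_seq <- function(x, rate) {
  # x: character vector of bases; substitution-only, uniform over the
  # three alternative bases
  n <- length(x)
  nm <- rbinom(1L, n, rate)
  if (nm == 0L) return(x)
  pos <- sample.int(n, nm)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    x[p] <- sample(setdiff(bases, x[p]), 1L)
  }
  x
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Builds the lineage tree, ancestor and member sequences, release dates,
#' the structural masking plant (see [sim_config()]) and journal/country
#' metadata. Fully deterministic given `cfg$seed`; the five concerns
#' (topology, sequences, dates, masking, metadata) draw from separate
#' RNG streams so changing one knob perturbs only its own stream.
#'
#' @param cfg A [sim_config()].
#' @return List with `records` (a corpus `data.frame` as from
#'   [read_corpus()], lineages already masked) and `truth`, a
#'   `data.frame` with the true lineage (`true_*` columns), `species_id`,
#'   `compound_id` (= planted family) and `planted_class` (`NA` for
#'   unmasked records), with the realized planted class fractions in
#'   attribute `planted_fractions` and `cfg` in attribute `config`.
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  FF <- cfg$n_families; G <- cfg$genera_per_family
  S <- cfg$species_per_genus; K <- cfg$seqs_per_species
  m <- G * S * K              # records per family
  N <- FF * m
  idx <- expand.grid(k = seq_len(K), s = seq_len(S), g = seq_len(G),
                     f = seq_len(FF))[, c("f", "g", "s", "k")]
  acc <- sprintf("SYN%06d", seq_len(N))

  # --- topology / names -----------------------------------------------
  fam_name <- sprintf("Familia%03d", idx$f)
  ord_name <- sprintf("Ordo%03d", (idx$f - 1L) %/% 2L + 1L)
  cls_name <- sprintf("Classis%02d", (idx$f - 1L) %/% 4L + 1L)
  phy_name <- sprintf("Phylum%02d", (idx$f - 1L) %/% 8L + 1L)
  gen_name <- sprintf("Genus%03d_%d", idx$f, idx$g)
  spc_name <- sprintf("%s epithet%d", gen_name, idx$s)
  true_lin <- cbind(kingdom = rep("Fungi", N), phylum = phy_name,
                    class = cls_name, order = ord_name, family = fam_name,
                    genus = gen_name, species = spc_name)
  species_id <- sprintf("SP%03d_%d_%d", idx$f, idx$g, idx$s)
  compound_id <- sprintf("FAM%03d", idx$f)

  # --- sequences -------------------------------------------------------
  set.seed(stream_seed(cfg$seed, 2L))
  g_rate <- max(0, (cfg$d_genus - cfg$d_species) / 2)
  s_rate <- max(0, (cfg$d_species - 2 * cfg$d_intra) / 2)
  bases <- c("A", "C", "G", "T")
  seqs <- character(N)
  row <- 1L
  for (f in seq_len(FF)) {
    fam_anc <- sample(bases, cfg$seq_length, replace = TRUE)
    for (g in seq_len(G)) {
      gen_anc <- mutate_seq(fam_anc, g_rate)
      for (s in seq_len(S)) {
        spc_anc <- mutate_seq(gen_anc, s_rate)
        for (k in seq_len(K)) {
          seqs[row] <- paste(mutate_seq(spc_anc, cfg$d_intra),
                             collapse = "")
          row <- row + 1L
        }
      }
    }
  }

  # --- dates -----------------------------------------------------------
  set.seed(stream_seed(cfg$seed, 3L))
  ndays <- as.integer(cfg$date_range[2] - cfg$date_range[1]) + 1L
  dates <- cfg$date_range[1] + sample.int(ndays, N, replace = TRUE) - 1L

  # --- masking plant ---------------------------------------------------
  set.seed(stream_seed(cfg$seed, 4L))
  plant <- plant_masking(cfg, idx, dates, m)
  dates <- plant$dates
  masked <- plant$masked
  planted_class <- plant$planted_class

  # annotated records: truncate the true lineage to a sampled depth
  obs_lin <- true_lin
  depth_names <- names(cfg$depth_mask_distribution)
  ann <- which(!masked)
  if (length(ann)) {
    depths <- sample(depth_names, length(ann), replace = TRUE,
                     prob = cfg$depth_mask_distribution)
    for (i in seq_along(ann)) {
      di <- rank_index(depths[i])
      if (di < 7L) obs_lin[ann[i], (di + 1L):7L] <- NA_character_
    }
  }
  obs_lin[masked, 2:7] <- NA_character_

  # --- metadata --------------------------------------------------------
  set.seed(stream_seed(cfg$seed, 5L))
  u <- runif(N)
  n_other <- 40L
  other_journals <- sprintf("Synthetic Journal of Environmental Biology %02d",
                            seq_len(n_other))
  journal <- rep(NA_character_, N)
  myc_pick <- u < cfg$p_myc
  oth_pick <- !myc_pick & u < cfg$p_myc + cfg$p_journal_other
  journal[myc_pick] <- sample(cfg$mycology_journals, sum(myc_pick),
                              replace = TRUE)
  journal[oth_pick] <- sample(other_journals, sum(oth_pick), replace = TRUE)
  country <- sample(names(cfg$countries), N, replace = TRUE,
                    prob = cfg$countries)
  country[runif(N) < cfg$p_country_missing] <- NA_character_
  n_studies <- max(1L, round(N / 13))
  study_id <- sprintf("STUDY%04d", sample.int(n_studies, N, replace = TRUE))

  records <- data.frame(accession = acc, sequence = seqs,
                        release_date = dates, obs_lin,
                        country = country, journal = journal,
                        study_id = study_id,
                        year = as.integer(format(dates, "%Y")),
                        stringsAsFactors = FALSE)
  truth_lin <- true_lin
  colnames(truth_lin) <- paste0("true_", RANKS)
  truth <- data.frame(accession = acc, truth_lin,
                      species_id = species_id, compound_id = compound_id,
                      planted_class = planted_class,
                      stringsAsFactors = FALSE)
  n_q <- sum(masked)
  pf <- if (n_q > 0) {
    c(FN_CLOSE = sum(planted_class == "FN_CLOSE", na.rm = TRUE),
      FN_REASONABLE = sum(planted_class == "FN_REASONABLE", na.rm = TRUE),
      TP = sum(planted_class == "TP", na.rm = TRUE)) / n_q
  } else c(FN_CLOSE = NA_real_, FN_REASONABLE = NA_real_, TP = NA_real_)
  attr(truth, "planted_fractions") <- pf
  attr(truth, "config") <- cfg
  list(records = records, truth = truth)
}

# The structural masking plant. Returns the masked flag, the planted
# class per record (NA when unmasked) and the (possibly shifted) dates.
plant_masking <- function(cfg, idx, dates, m) {
  FF <- cfg$n_families
  K <- cfg$seqs_per_species
  spc <- cfg$genera_per_family * cfg$species_per_genus
  N <- nrow(idx)
  n_q <- round(cfg$p_kingdom_mask * N)
  n_tp_t <- round(cfg$class_mix[["TP"]] * n_q)
  n_dark <- round(n_tp_t / m)
  n_re_t <- round(cfg$class_mix[["FN_REASONABLE"]] * n_q)
  n_re_species <- round(n_re_t / K)
  n_cl <- n_q - n_dark * m - n_re_species * K
  while (n_cl < 0 && n_re_species > 0) {
    n_re_species <- n_re_species - 1L
    n_cl <- n_q - n_dark * m - n_re_species * K
  }
  n_re_fams <- if (spc > 1L) ceiling(n_re_species / (spc - 1L)) else 0L
  if (spc == 1L && n_re_species > 0) {
    stop("cannot plant FN_REASONABLE queries with a single species per family")
  }
  if (n_dark + n_re_fams >= FF && (n_re_species > 0 || n_dark > 0)) {
    stop("corpus too small for the requested class mix: needs more families")
  }

  fam_of <- idx$f
  spe_of <- paste(idx$f, idx$g, idx$s)
  masked <- logical(N)
  planted <- rep(NA_character_, N)

  fams <- sample.int(FF)  # random stratum assignment
  dark_fams <- if (n_dark > 0) fams[seq_len(n_dark)] else integer(0)
  re_fams <- if (n_re_fams > 0) fams[n_dark + seq_len(n_re_fams)] else integer(0)
  close_fams <- setdiff(fams, c(dark_fams, re_fams))

  # dark families: everything masked, every record a TP query
  dk <- fam_of %in% dark_fams
  masked[dk] <- TRUE
  planted[dk] <- "TP"

  # reasonable families: anchor species (holds the family-earliest
  # record) stays annotated; whole sampled other species are masked
  left <- n_re_species
  for (f in re_fams) {
    rows <- which(fam_of == f)
    anchor_row <- rows[which.min(dates[rows])]
    anchor_sp <- spe_of[anchor_row]
    other_sp <- setdiff(unique(spe_of[rows]), anchor_sp)
    take <- min(left, length(other_sp))
    if (take == 0L) break
    sel_sp <- sample(other_sp, take)
    sel <- rows[spe_of[rows] %in% sel_sp]
    masked[sel] <- TRUE
    planted[sel] <- "FN_REASONABLE"
    # guarantee the anchor qualifies under the lag for every query
    shift <- sel[as.integer(dates[sel] - dates[anchor_row]) < cfg$lag_days]
    dates[shift] <- dates[anchor_row] + cfg$lag_days
    left <- left - take
  }

  # close families: per-species earliest record is the annotated anchor;
  # a sampled subset of the remaining records is masked
  pool <- integer(0)
  anchor_of <- integer(N)  # row index of the species anchor
  for (f in close_fams) {
    rows <- which(fam_of == f)
    for (sp in unique(spe_of[rows])) {
      srows <- rows[spe_of[rows] == sp]
      a <- srows[which.min(dates[srows])]
      rest <- setdiff(srows, a)
      anchor_of[rest] <- a
      pool <- c(pool, rest)
    }
  }
  n_cl <- min(n_cl, length(pool))
  if (n_cl > 0) {
    sel <- sample(pool, n_cl)
    masked[sel] <- TRUE
    planted[sel] <- "FN_CLOSE"
    shift <- sel[as.integer(dates[sel] - dates[anchor_of[sel]]) < cfg$lag_days]
    dates[shift] <- dates[anchor_of[shift]] + cfg$lag_days
  }
  list(masked = masked, planted_class = planted, dates = dates)
}

#' Ground-truth classification oracle
#'
#' Classifies every kingdom-level record using the *true* species and
#' family memberships and release dates only - never the pipeline's
#' clustering. `FN_CLOSE` if another record of the same true species is
#' available under the lag with an observed annotation beyond the
#' kingdom; else `FN_REASONABLE` if a record of the same planted family
#' qualifies; else `TP`.
#'
#' @param records Corpus `data.frame` (observed, masked lineages).
#' @param truth Truth `data.frame` from [simulate_corpus()].
#' @param policy An [availability_policy()].
#' @return `data.frame` with `accession` and `classification`, one row
#'   per kingdom-level record, in corpus order.
#' @export
oracle_classify <- function(records, truth,
                            policy = availability_policy()) {
  stopifnot(setequal(records$accession, truth$accession))
  tr <- truth[match(records$accession, truth$accession), , drop = FALSE]
  depth <- as.integer(annotation_depth(records))
  annotated <- depth > 1L
  queries <- which(depth == 1L)
  lag <- policy$lag_days
  cls <- vapply(queries, function(qi) {
    avail <- as.integer(records$release_date[qi] - records$release_date) >= lag
    avail[qi] <- FALSE
    cand <- avail & annotated
    if (any(cand & tr$species_id == tr$species_id[qi])) "FN_CLOSE"
    else if (any(cand & tr$compound_id == tr$compound_id[qi])) "FN_REASONABLE"
    else "TP"
  }, character(1))
  data.frame(accession = records$accession[queries], classification = cls,
             stringsAsFactors = FALSE)
}

#' Write a simulated corpus to disk
#'
#' Writes `corpus.fasta`, `metadata.tsv` (the [corpus_io] dialect) and
#' `truth.tsv` into `dir`.
#'
#' @param sim Output of [simulate_corpus()].
#' @param dir Output directory (created if absent).
#' @return Invisibly the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "corpus.fasta")
  md <- file.path(dir, "metadata.tsv")
  tr <- file.path(dir, "truth.tsv")
  write_corpus(sim$records, fa, md)
  truth <- sim$truth
  write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(c(fasta = fa, metadata = md, truth = tr))
}
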