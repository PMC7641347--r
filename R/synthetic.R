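#' Simulation configuration
#'
#' Central configuration for the synthetic-data generators. Defaults
#' emulate the survey design the pipeline targets: a deep-sea transect
#' survey with triplicate water samples per station x location (surface,
#' deep scattering layer, bottom), small-volume (0.25 L) sampling in 2018
#' and large-volume (1.5 L) sampling in 2019, a volume- and
#' depth-structured DNA-concentration signal, three fish-targeting
#' markers, and an occupancy hierarchy with depth-dependent occupancy.
#'
#' @param seed Default seed used by generators when none is passed.
#' @param tax_n_families Number of fish families in the synthetic taxonomy.
#' @param tax_genera_per_family Genera per family.
#' @param tax_congeneric_pairs Number of genera holding a congeneric
#'   species pair (all other genera are monotypic); these exercise LCA
#'   collapses.
#' @param tax_outgroup_families Non-fish (copepod) families added so group
#'   filtering is exercised.
#' @param stations_2018,stations_2019 Stations sampled per year.
#' @param replicates Water-sample replicates per station x location.
#' @param volume_2018_l,volume_2019_l Filtered volume (L) by year.
#' @param depth_surface_m,depth_dsl_m,depth_bottom_m Depth ranges (m) for
#'   the three sampling locations (deep scattering layer per echosounder
#'   observations, bottom up to abyssal depth).
#' @param dna_baseline,dna_volume_effect,dna_depth_effect,dna_sd
#'   DNA-concentration model (pg/uL): `baseline + volume_effect *
#'   1[volume = large] - depth_effect * 1[deep] + Normal(0, sd)`,
#'   truncated at 0.
#' @param occ_K,occ_I,occ_J,occ_M Detection-array dimensions: taxa, sites,
#'   replicates, markers.
#' @param occ_mu_beta0,occ_sigma_beta0 Community occupancy intercept
#'   hyperparameters (logit).
#' @param occ_mu_beta1,occ_sigma_beta1 Community depth-slope
#'   hyperparameters (logit per SD of depth).
#' @param occ_mu_logit_theta,occ_sigma_logit_theta Community availability
#'   hyperparameters (logit).
#' @param occ_mu_alpha,occ_sigma_alpha Per-marker community detection
#'   hyperparameters (logit), length `occ_M`.
#' @param hit_query_len Simulated amplicon length (bp).
#' @param hit_decoy_max Maximum number of low-scoring decoy hits per ESV.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       tax_n_families = 8L,
                       tax_genera_per_family = 2L,
                       tax_congeneric_pairs = 5L,
                       tax_outgroup_families = 2L,
                       stations_2018 = 7L,
                       stations_2019 = 10L,
                       replicates = 3L,
                       volume_2018_l = 0.25,
                       volume_2019_l = 1.5,
                       depth_surface_m = c(2, 5),
                       depth_dsl_m = c(360, 536),
                       depth_bottom_m = c(1000, 2800),
                       dna_baseline = 8,
                       dna_volume_effect = 12,
                       dna_depth_effect = 4,
                       dna_sd = 3,
                       occ_K = 20L, occ_I = 30L, occ_J = 3L, occ_M = 3L,
                       occ_mu_beta0 = 0, occ_sigma_beta0 = 1,
                       occ_mu_beta1 = -0.75, occ_sigma_beta1 = 0.5,
                       occ_mu_logit_theta = 1, occ_sigma_logit_theta = 0.5,
                       occ_mu_alpha = c(0.5, 0.5, 0.5),
                       occ_sigma_alpha = c(1, 1, 1),
                       hit_query_len = 150L,
                       hit_decoy_max = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$dna_sd > 0, all(cfg$occ_sigma_alpha > 0),
            cfg$occ_sigma_beta0 > 0, cfg$occ_sigma_beta1 > 0,
            cfg$occ_sigma_logit_theta > 0,
            length(cfg$occ_mu_alpha) == cfg$occ_M,
            length(cfg$occ_sigma_alpha) == cfg$occ_M,
            cfg$tax_congeneric_pairs <=
              cfg$tax_n_families * cfg$tax_genera_per_family)
  structure(cfg, class = "sim_config")
}

sim_markers <- function(config) {
  paste0("marker", seq_len(config$occ_M))
}

#' Generate a synthetic ranked taxonomy
#'
#' Builds a consistent 7-rank lineage table: fish taxa (class Actinopteri)
#' organized as orders > families > genera > species, with exactly
#' `tax_congeneric_pairs` genera carrying two species (one genus-sharing
#' species pair each; all other genera are monotypic), plus a small
#' copepod outgroup. Names are deterministic; the table is a pure function
#' of the configuration.
#'
#' @param config A [sim_config()].
#' @return Lineage table data frame (`taxon_key` + the seven ranks), one
#'   row per species-level taxon.
#' @export
make_taxonomy <- function(config = sim_config()) {
  nf <- config$tax_n_families
  gpf <- config$tax_genera_per_family
  npairs <- config$tax_congeneric_pairs
  rows <- list()
  g_total <- 0L
  for (f in seq_len(nf)) {
    ord <- sprintf("Simorder%02d", (f - 1L) %/% 2L + 1L)
    fam <- sprintf("Simfamily%02d", f)
    for (g in seq_len(gpf)) {
      g_total <- g_total + 1L
      gen <- sprintf("Simgenus%03d", g_total)
      n_sp <- if (g_total <= npairs) 2L else 1L
      for (s in seq_len(n_sp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kingdom = "Metazoa", phylum = "Chordata", class = "Actinopteri",
          order = ord, family = fam, genus = gen,
          species = sprintf("%s sp%d", gen, s), stringsAsFactors = FALSE)
      }
    }
  }
  for (f in seq_len(config$tax_outgroup_families)) {
    gen <- sprintf("Simcopgenus%02d", f)
    rows[[length(rows) + 1L]] <- data.frame(
      kingdom = "Metazoa", phylum = "Arthropoda", class = "Copepoda",
      order = "Calanoida", family = sprintf("Simcopfamily%02d", f),
      genus = gen, species = paste(gen, "sp1"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cbind(taxon_key = sprintf("t%04d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Generate a hit table with score-stratified ground truth
#'
#' For each simulated ESV, draws a true source taxon and a score stratum,
#' then emits similarity hits whose best selection score lands in that
#' stratum, so every assignment rank is exercised:
#' `species` (score 100), `genus` (98 to <100), `family` (95 to <98),
#' `above_family` (<95), and `tie_genus` (two congeneric species tied at
#' 100, forcing an LCA collapse to genus). Low-scoring decoy hits to other
#' taxa and an e-value-failing junk hit are added per ESV.
#'
#' @param lineage_table Output of [make_taxonomy()].
#' @param n_esv Number of ESVs to simulate.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param strata Stratum labels sampled uniformly per ESV.
#' @return List: `hits` (13-column hit-table data frame in the layout of
#'   [read_hit_table()], written without header), `truth` (data frame
#'   `esv_id`, `taxon_key`, `stratum`, `expected_rank`).
#' @export
make_hit_table <- function(lineage_table, n_esv = 50L, config = sim_config(),
                           seed = config$seed,
                           strata = c("species", "genus", "family",
                                      "above_family", "tie_genus")) {
  set.seed(seed)
  qlen <- config$hit_query_len
  fish <- lineage_table[lineage_table$class == "Actinopteri", , drop = FALSE]
  genus_count <- table(fish$genus)
  congeneric <- fish[fish$genus %in% names(genus_count)[genus_count >= 2L], ,
                     drop = FALSE]
  if (any(strata == "tie_genus") && nrow(congeneric) == 0L) {
    stop("make_hit_table: taxonomy has no congeneric pair for tie_genus stratum")
  }
  hit_row <- function(esv, key, ident, alen, evalue = 1e-40) {
    data.frame(q = esv, s = key, id = ident, al = alen, mm = 0L, go = 0L,
               qs = 1L, qe = alen, ss = 1L, se = alen, ev = evalue,
               bs = round(2 * alen * ident / 100, 1), ql = qlen,
               stringsAsFactors = FALSE)
  }
  # choose an integer alignment length and back-compute the identity so the
  # recomputed selection score equals `score` exactly (up to float error)
  score_to_hit <- function(score) {
    cand <- seq(ceiling(score * qlen / 100), qlen)
    alen <- cand[sample.int(length(cand), 1L)]
    ov <- 100 * alen / qlen
    list(ident = 100 * score / ov, alen = alen)
  }
  hits <- list(); truth <- list()
  for (e in seq_len(n_esv)) {
    esv <- sprintf("esv%04d", e)
    stratum <- sample(strata, 1L)
    if (stratum == "tie_genus") {
      gen <- sample(unique(congeneric$genus), 1L)
      pair <- congeneric[congeneric$genus == gen, ][1:2, ]
      key <- pair$taxon_key[1L]
      hits[[length(hits) + 1L]] <- hit_row(esv, pair$taxon_key[1L], 100, qlen)
      hits[[length(hits) + 1L]] <- hit_row(esv, pair$taxon_key[2L], 100, qlen)
      best <- 100
      expected <- "genus"
    } else {
      row <- fish[sample(nrow(fish), 1L), ]
      key <- row$taxon_key
      best <- switch(stratum,
                     species = 100,
                     genus = stats::runif(1, 98.01, 99.9),
                     family = stats::runif(1, 95.01, 97.9),
                     above_family = stats::runif(1, 80, 94.9))
      h <- score_to_hit(best)
      hits[[length(hits) + 1L]] <- hit_row(esv, key, h$ident, h$alen)
      expected <- switch(stratum, species = "species", genus = "genus",
                         family = "family", above_family = "above_family")
    }
    # decoys: clearly lower scores to random other taxa
    n_decoy <- sample(0:config$hit_decoy_max, 1L)
    if (n_decoy > 0L) {
      others <- lineage_table[lineage_table$taxon_key != key, , drop = FALSE]
      dec <- others[sample(nrow(others), n_decoy), , drop = FALSE]
      for (dk in dec$taxon_key) {
        h <- score_to_hit(max(best - stats::runif(1, 3, 12), 50))
        hits[[length(hits) + 1L]] <- hit_row(esv, dk, h$ident, h$alen)
      }
    }
    # junk hit failing the e-value cutoff
    junk <- lineage_table$taxon_key[sample(nrow(lineage_table), 1L)]
    hits[[length(hits) + 1L]] <- hit_row(esv, junk, 100, qlen, evalue = 0.01)
    truth[[length(truth) + 1L]] <- data.frame(
      esv_id = esv, taxon_key = key, stratum = stratum,
      expected_rank = expected, stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate sample metadata with a structured DNA-concentration signal
#'
#' Builds triplicate water samples per station x location for the two
#' survey years (small volumes in 2018, large in 2019), with depths drawn
#' from location-specific ranges, one field blank per station (control),
#' and DNA concentration following
#' `baseline + volume_effect * 1[volume = large] - depth_effect * 1[deep]
#' + Normal(0, sd)`, truncated at 0 (concentrations are non-negative;
#' units pg/uL).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Sample-metadata data frame (see [read_sample_metadata()]).
#' @export
make_metadata_and_concentration <- function(config = sim_config(),
                                            seed = config$seed) {
  set.seed(seed)
  rows <- list()
  for (year in c(2018L, 2019L)) {
    n_st <- if (year == 2018L) config$stations_2018 else config$stations_2019
    vol <- if (year == 2018L) config$volume_2018_l else config$volume_2019_l
    for (st in seq_len(n_st)) {
      station <- sprintf("S%d_%02d", year, st)
      transect <- paste0("T", (st - 1L) %% 3L + 1L)
      for (loc in c("surface", "deep_scattering_layer", "bottom")) {
        rng <- switch(loc, surface = config$depth_surface_m,
                      deep_scattering_layer = config$depth_dsl_m,
                      bottom = config$depth_bottom_m)
        depth <- round(stats::runif(1, rng[1L], rng[2L]), 1)
        for (r in seq_len(config$replicates)) {
          is_deep <- depth > 1400
          conc <- config$dna_baseline +
            config$dna_volume_effect * (vol == config$volume_2019_l) -
            config$dna_depth_effect * is_deep +
            stats::rnorm(1, 0, config$dna_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_r%d", station, substr(loc, 1, 3), r),
            station = station, transect = transect, year = year,
            depth_m = depth, location = loc, volume_l = vol,
            dna_conc = max(conc, 0), is_control = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_blank", station), station = station,
        transect = transect, year = year, depth_m = 0, location = "surface",
        volume_l = vol, dna_conc = abs(stats::rnorm(1, 0, 0.05)),
        is_control = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate an ESV read-count table with known detections
#'
#' Places each assigned ESV into a random subset of non-control samples
#' with positive read counts (and explicit zero rows elsewhere for a
#' random subset, so zero-count handling is exercised). The returned truth
#' records, for each ESV, the samples holding at least one read — the
#' ground truth for per-sample richness and taxon-by-depth detection.
#'
#' @param assignments Assignment data frame (its `esv_id`s are placed).
#' @param metadata Sample metadata from
#'   [make_metadata_and_concentration()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param marker Marker label for the table.
#' @param mean_prevalence Mean fraction of samples holding each ESV.
#' @return List: `esv_table` (long-format data frame) and `truth` (data
#'   frame `esv_id`, `sample_id` of every positive placement).
#' @export
make_esv_table <- function(assignments, metadata, config = sim_config(),
                           seed = config$seed, marker = "marker1",
                           mean_prevalence = 0.15) {
  set.seed(seed)
  samples <- metadata$sample_id[!metadata$is_control]
  rows <- list(); truth <- list()
  for (esv in assignments$esv_id) {
    n_here <- max(1L, stats::rbinom(1L, length(samples), mean_prevalence))
    here <- sample(samples, n_here)
    for (s in here) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = marker, esv_id = esv, sample_id = s,
        read_count = stats::rpois(1L, 200) + 1L, stringsAsFactors = FALSE)
    }
    # a few explicit zero rows
    pool <- setdiff(samples, here)
    zeros <- pool[sample.int(length(pool), min(2L, length(pool)))]
    for (s in zeros) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = marker, esv_id = esv, sample_id = s, read_count = 0L,
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      esv_id = esv, sample_id = here, stringsAsFactors = FALSE)
  }
  list(esv_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Forward-simulate detection histories from the occupancy hierarchy
#'
#' Draws taxon-level parameters from the community hyperpriors in the
#' configuration, then latent occupancy `z`, availability `a`, and binary
#' detections `y`, returning both the detection array and the full truth
#' for parameter-recovery tests.
#'
#' @param config A [sim_config()] (fields `occ_*`).
#' @param seed Integer seed.
#' @return List: `y` (a [detection_array()]), `params` (true `beta0`,
#'   `beta1`, `theta`, `alpha` (K x M), hyperparameters, latent `z`, `a`,
#'   `psi` and site depths).
#' @export
make_detection_history <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  K <- config$occ_K; I <- config$occ_I; J <- config$occ_J; M <- config$occ_M
  depth <- stats::runif(I, 5, 2800)
  d_std <- as.numeric(scale(depth))
  beta0 <- stats::rnorm(K, config$occ_mu_beta0, config$occ_sigma_beta0)
  beta1 <- stats::rnorm(K, config$occ_mu_beta1, config$occ_sigma_beta1)
  ltheta <- stats::rnorm(K, config$occ_mu_logit_theta,
                         config$occ_sigma_logit_theta)
  theta <- stats::plogis(ltheta)
  alpha <- matrix(stats::rnorm(K * M, rep(config$occ_mu_alpha, each = K),
                               rep(config$occ_sigma_alpha, each = K)), K, M)
  psi <- stats::plogis(outer(beta0, rep(1, I)) + outer(beta1, d_std))
  z <- matrix(stats::rbinom(K * I, 1L, psi), K, I)
  a <- array(stats::rbinom(K * I * J, 1L,
                           rep(z * theta, times = J)), dim = c(K, I, J))
  p <- stats::plogis(alpha)
  y <- array(0, dim = c(K, I, J, M),
             dimnames = list(sprintf("taxon%02d", seq_len(K)),
                             sprintf("site%02d", seq_len(I)),
                             sprintf("rep%d", seq_len(J)),
                             sim_markers(config)))
  for (m in seq_len(M)) {
    y[, , , m] <- stats::rbinom(K * I * J, 1L, as.numeric(a) * rep(p[, m], times = I * J))
  }
  list(y = detection_array(y, depth),
       params = list(beta0 = beta0, beta1 = beta1, theta = theta,
                     alpha = alpha, z = z, a = a, psi = psi,
                     depth_m = depth,
                     mu_beta0 = config$occ_mu_beta0,
                     sigma_beta0 = config$occ_sigma_beta0,
                     mu_beta1 = config$occ_mu_beta1,
                     sigma_beta1 = config$occ_sigma_beta1,
                     mu_logit_theta = config$occ_mu_logit_theta,
                     sigma_logit_theta = config$occ_sigma_logit_theta,
                     mu_alpha = config$occ_mu_alpha,
                     sigma_alpha = config$occ_sigma_alpha))
}
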