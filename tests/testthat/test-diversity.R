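test_that("depth_category uses the printed interval boundaries", {
  expect_equal(as.character(depth_category(c(0, 499, 500, 1400, 1401, 2500))),
               c("shallow", "shallow", "mid", "mid", "deep", "deep"))
  expect_error(depth_category(-1), "depth_m")
})

test_that("esv_counts_per_sample counts nonzero ESVs", {
  esv <- data.frame(marker = "m", esv_id = c("e1", "e2", "e3", "e1", "e2"),
                    sample_id = c("s1", "s1", "s1", "s2", "s2"),
                    read_count = c(5L, 1L, 2L, 0L, 0L))
  out <- esv_counts_per_sample(esv)
  expect_equal(out$n_esv[out$sample_id == "s1"], 3L)
  expect_equal(out$n_esv[out$sample_id == "s2"], 0L)
})

test_that("per-sample richness recovers generator ground truth", {
  cfg <- sim_config(seed = 9)
  meta <- make_metadata_and_concentration(cfg)
  asg <- data.frame(esv_id = sprintf("esv%03d", 1:40))
  sim <- make_esv_table(asg, meta, cfg, seed = 9)
  got <- esv_counts_per_sample(sim$esv_table)
  want <- table(sim$truth$sample_id)
  for (s in names(want)) {
    expect_equal(got$n_esv[got$sample_id == s], as.integer(want[[s]]))
  }
})

test_that("rank_resolution_summary counts nest and percentages use the group total", {
  counts <- data.frame(marker = "mk", n_esv_total = 20L, n_esv_with_tax = 15L,
                       n_group_esv = 10L, n_family = 8L, n_genus = 5L,
                       n_species = 2L)
  asg <- assignments_from_counts(counts, "fish")
  out <- rank_resolution_summary(asg, "fish")
  expect_equal(out$n_esv_total, 20L)
  expect_equal(out$n_esv_with_tax, 15L)
  expect_equal(out$n_group_esv, 10L)
  expect_equal(c(out$n_family, out$n_genus, out$n_species), c(8L, 5L, 2L))
  expect_equal(c(out$pct_family, out$pct_genus, out$pct_species),
               c(80, 50, 20))
  expect_true(out$n_species <= out$n_genus && out$n_genus <= out$n_family &&
                out$n_family <= out$n_group_esv)

  # degenerate: no group ESVs -> zero counts and zero percentages
  counts0 <- transform(counts, n_group_esv = 0L, n_family = 0L, n_genus = 0L,
                       n_species = 0L)
  out0 <- rank_resolution_summary(assignments_from_counts(counts0, "fish"), "fish")
  expect_equal(out0$n_group_esv, 0L)
  expect_equal(c(out0$pct_family, out0$pct_genus, out0$pct_species), c(0, 0, 0))
})

test_that("fish group membership requires Actinopteri/Chondrichthyes at score >= 90", {
  shark <- lineage("Metazoa", "Chordata", "Chondrichthyes", "Rajiformes",
                   "Rajidae", "Rajella", "Rajella bigelowi")
  asg <- rbind(assign_taxonomy(hit_scored("q1", fish_lineage(), 100)),
               assign_taxonomy(hit_scored("q2", shark, 100)),
               assign_taxonomy(hit_scored("q3", copepod_lineage(), 100)),
               assign_taxonomy(hit_scored("q4", fish_lineage(), 85)))
  asg$marker <- "mk"
  out <- rank_resolution_summary(asg, "fish")
  expect_equal(out$n_group_esv, 2L)  # q4 scores below 90, q3 is a copepod
  out_m <- rank_resolution_summary(asg, "metazoa")
  expect_equal(out_m$n_group_esv, 3L)
})

test_that("taxon_detection_table flags depth categories and excludes controls", {
  meta <- small_metadata()
  lin_deep <- fish_lineage()
  lin_ctrl <- fish_lineage(genus = "Macrourus", species = "Macrourus berglax")
  asg <- rbind(assign_taxonomy(hit_scored("e_deep", lin_deep, 100)),
               assign_taxonomy(hit_scored("e_ctrl", lin_ctrl, 100)))
  esv <- data.frame(marker = "mk",
                    esv_id = c("e_deep", "e_ctrl"),
                    sample_id = c("s3", "s7"),   # s3 is 2000 m, s7 a control
                    read_count = c(12L, 50L))
  out <- taxon_detection_table(asg, esv, meta)
  expect_equal(nrow(out), 1L)
  expect_equal(out$species, "Coryphaenoides rupestris")
  expect_true(out$detected_deep)
  expect_false(out$detected_mid || out$detected_shallow)
  expect_equal(out$n_samples, 1L)
})

test_that("detection table recovers generator ground truth", {
  cfg <- sim_config(seed = 13)
  meta <- make_metadata_and_concentration(cfg)
  tax <- make_taxonomy(cfg)
  fish <- tax[tax$class == "Actinopteri", ][1:10, ]
  asg <- do.call(rbind, lapply(1:10, function(i) {
    lin <- stats::setNames(as.character(unlist(fish[i, RANKS])), RANKS)
    assign_taxonomy(hit_scored(sprintf("esv%03d", i), lin, 100,
                               taxon_key = fish$taxon_key[i]))
  }))
  sim <- make_esv_table(asg, meta, cfg, seed = 13)
  out <- taxon_detection_table(asg, sim$esv_table, meta)
  expect_equal(nrow(out), 10L)  # all species distinct
  # expected flags derived independently from the generator truth
  cat_of_sample <- as.character(depth_category(meta$depth_m))
  names(cat_of_sample) <- meta$sample_id
  for (i in 1:10) {
    samples <- sim$truth$sample_id[sim$truth$esv_id == asg$esv_id[i]]
    cats <- unique(cat_of_sample[samples])
    row <- out[!is.na(out$species) & out$species == fish$species[i], ]
    expect_equal(unname(row$detected_deep), "deep" %in% cats)
    expect_equal(unname(row$detected_mid), "mid" %in% cats)
    expect_equal(unname(row$detected_shallow), "shallow" %in% cats)
    expect_equal(row$n_samples, length(unique(samples)))
  }
})

test_that("count_distinct_taxa counts names once across rows", {
  tab <- read_taxon_detection_table(
    system.file("extdata", "table3_fish_taxa.tsv", package = "deepedna"))
  expect_gt(nrow(tab), 40L)
  # same genus in species-level and genus-level rows counts once
  expect_lt(count_distinct_taxa(tab, "genus"), sum(!is.na(tab$genus)))
  expect_equal(count_distinct_taxa(tab[0, ], "family"), 0L)
})

test_that("method_overlap partitions name sets", {
  expect_equal(unlist(method_overlap(letters[1:5], letters[1:5])),
               c(n_edna_only = 0L, n_shared = 5L, n_conventional_only = 0L))
  expect_equal(unlist(method_overlap(c("a", "b", "c"), c("x", "y"))),
               c(n_edna_only = 3L, n_shared = 0L, n_conventional_only = 2L))
  out <- method_overlap(c("a", "b", "c"), c("b", "c", "d"), rank = "family")
  expect_equal(out$n_shared, 2L)
  expect_equal(out$n_edna_only + out$n_shared, 3L)
})
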