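# Shared fixtures: tiny lineages, in-memory tables written to tempfiles.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

fish_lineage <- function(order = "Gadiformes", family = "Macrouridae",
                         genus = "Coryphaenoides",
                         species = "Coryphaenoides rupestris") {
  lineage("Metazoa", "Chordata", "Actinopteri", order, family, genus, species)
}

copepod_lineage <- function() {
  lineage("Metazoa", "Arthropoda", "Copepoda", "Calanoida", "Calanidae",
          "Calanus", "Calanus finmarchicus")
}

# one-row hit data frame in the joined format of read_hit_table()
hit <- function(query_id, lin, identity = 100, align_len = 150,
                query_len = 150, evalue = 1e-40, bitscore = 250,
                taxon_key = "t1") {
  df <- data.frame(query_id = query_id, taxon_key = taxon_key,
                   identity_pct = identity, align_len = align_len,
                   query_len = query_len, evalue = evalue,
                   bitscore = bitscore, stringsAsFactors = FALSE)
  for (r in RANKS) df[[r]] <- unname(lin[[r]])
  df
}

# hit with an exact target selection score (overlap 100)
hit_scored <- function(query_id, lin, score, taxon_key = "t1") {
  hit(query_id, lin, identity = score, align_len = 150, query_len = 150,
      taxon_key = taxon_key)
}

tmp_tsv <- function(df, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header, na = "")
  path
}

small_metadata <- function() {
  data.frame(
    sample_id = paste0("s", 1:7),
    station = c("A", "A", "A", "B", "B", "B", "A"),
    transect = "T1",
    year = 2019L,
    depth_m = c(3, 450, 2000, 5, 1400, 1500, 0),
    location = c("surface", "deep_scattering_layer", "bottom", "surface",
                 "deep_scattering_layer", "bottom", "surface"),
    volume_l = 1.5,
    dna_conc = c(20, 15, 8, 22, 14, 7, 0.1),
    is_control = c(rep(FALSE, 6), TRUE),
    stringsAsFactors = FALSE
  )
}

# Expand a Table-2-style count row into an assignment table whose
# rank_resolution_summary reproduces those counts.
assignments_from_counts <- function(counts, group = c("fish", "metazoa")) {
  group <- match.arg(group)
  out <- list()
  for (i in seq_len(nrow(counts))) {
    cc <- counts[i, ]
    n_sp <- cc$n_species
    n_ge <- cc$n_genus - cc$n_species
    n_fa <- cc$n_family - cc$n_genus
    n_ab <- cc$n_group_esv - cc$n_family
    n_og <- cc$n_esv_with_tax - cc$n_group_esv   # with tax, not in group
    n_no <- cc$n_esv_total - cc$n_esv_with_tax   # no match at all
    stopifnot(n_sp >= 0, n_ge >= 0, n_fa >= 0, n_ab >= 0, n_og >= 0, n_no >= 0)
    n <- cc$n_esv_total
    king <- c(rep("Metazoa", cc$n_esv_with_tax - n_og),
              rep("Viridiplantae", n_og), rep(NA, n_no))
    if (group == "fish") {
      # in-group rows are Actinopteri; non-group rows with tax are
      # metazoan but non-fish
      king <- c(rep("Metazoa", cc$n_esv_with_tax), rep(NA, n_no))
      cls <- c(rep("Actinopteri", cc$n_group_esv),
               rep("Copepoda", n_og), rep(NA, n_no))
    } else {
      cls <- c(rep("Actinopteri", cc$n_group_esv),
               rep("Magnoliopsida", n_og), rep(NA, n_no))
    }
    depth_n <- c(rep(7L, n_sp), rep(6L, n_ge), rep(5L, n_fa),
                 rep(3L, n_ab + n_og), rep(0L, n_no))
    mk_rank <- function(r, nm) ifelse(depth_n >= r, nm, NA_character_)
    idx <- seq_len(n)
    df <- data.frame(
      esv_id = sprintf("%s_e%06d", gsub("\\W", "", cc$marker), idx),
      marker = cc$marker,
      best_score = c(rep(100, n_sp), rep(98.5, n_ge), rep(96, n_fa),
                     rep(92, n_ab + n_og), rep(NA, n_no)),
      assigned_rank = c(rep("species", n_sp), rep("genus", n_ge),
                        rep("family", n_fa), rep("above_family", n_ab + n_og),
                        rep("none", n_no)),
      n_tied_hits = ifelse(depth_n > 0, 1L, 0L),
      kingdom = ifelse(depth_n >= 1, king, NA),
      phylum = mk_rank(2L, "Chordata"),
      class = ifelse(depth_n >= 3, cls, NA),
      order = mk_rank(4L, "Simorder"),
      family = mk_rank(5L, paste0("Fam", idx %% 997L)),
      genus = mk_rank(6L, paste0("Gen", idx %% 997L)),
      species = mk_rank(7L, paste0("Sp", idx)),
      stringsAsFactors = FALSE
    )
    out[[i]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
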