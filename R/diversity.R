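#' Depth category of a sample
#'
#' Classifies sampling depth into the survey's three strata: shallow
#' (< 500 m), mid-depth (500-1400 m, boundaries inclusive) and deep
#' (> 1400 m).
#'
#' @param depth_m Depth(s) in meters, >= 0.
#' @param shallow_max Lower edge of the mid stratum (default 500 m; depths
#'   strictly below are shallow).
#' @param deep_min Upper edge of the mid stratum (default 1400 m; depths
#'   strictly above are deep).
#' @return Factor with levels `shallow`, `mid`, `deep`.
#' @export
#' @examples
#' depth_category(c(10, 500, 1400, 2500))
depth_category <- function(depth_m, shallow_max = 500, deep_min = 1400) {
  if (any(!is.finite(depth_m)) || any(depth_m < 0)) {
    stop("depth_category: depth_m must be finite and >= 0")
  }
  out <- ifelse(depth_m < shallow_max, "shallow",
                ifelse(depth_m <= deep_min, "mid", "deep"))
  factor(out, levels = c("shallow", "mid", "deep"))
}

#' ESV richness per sample
#'
#' Counts, for each sample, the number of distinct ESVs with at least one
#' read.
#'
#' @param esv_table Long-format ESV table (see [read_esv_table()]).
#' @return Data frame `sample_id`, `n_esv`, one row per sample present in
#'   the table (samples whose rows are all zero count 0).
#' @export
esv_counts_per_sample <- function(esv_table) {
  ids <- unique(esv_table$sample_id)
  nz <- esv_table[esv_table$read_count > 0, , drop = FALSE]
  counts <- tapply(nz$esv_id, factor(nz$sample_id, levels = ids),
                   function(x) length(unique(x)))
  counts[is.na(counts)] <- 0L
  data.frame(sample_id = ids, n_esv = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-marker taxonomic resolution summary
#'
#' For each marker, counts total ESVs, ESVs with any taxonomic match, ESVs
#' belonging to the target group (metazoans, or fish = class Actinopteri or
#' Chondrichthyes) at a minimum selection score, and — among group ESVs —
#' how many carry a family, genus and species name, with percentages of
#' the group total (one decimal). A species-level assignment counts at
#' species, genus and family.
#'
#' @param assignments Assignment data frame with a `marker` column and one
#'   row per ESV (including rank-`"none"` rows; see [assign_taxonomy()]).
#' @param group_filter `"fish"` or `"metazoa"`.
#' @param group_min_score Minimum selection score for group membership
#'   (default 90).
#' @return Data frame, one row per marker: `marker`, `n_esv_total`,
#'   `n_esv_with_tax`, `n_group_esv`, `n_family`, `pct_family`, `n_genus`,
#'   `pct_genus`, `n_species`, `pct_species`.
#' @export
rank_resolution_summary <- function(assignments,
                                    group_filter = c("fish", "metazoa"),
                                    group_min_score = 90) {
  group_filter <- match.arg(group_filter)
  if (is.null(assignments$marker)) {
    stop("rank_resolution_summary: assignments must carry a 'marker' column")
  }
  in_group <- switch(group_filter,
    fish = !is.na(assignments$class) &
      assignments$class %in% c("Actinopteri", "Chondrichthyes"),
    metazoa = !is.na(assignments$kingdom) & assignments$kingdom == "Metazoa"
  )
  in_group <- in_group & !is.na(assignments$best_score) &
    assignments$best_score >= group_min_score
  has_tax <- assignments$assigned_rank != "none"
  markers <- unique(assignments$marker)
  rows <- lapply(markers, function(m) {
    sel <- assignments$marker == m
    grp <- sel & in_group
    n_grp <- sum(grp)
    n_fam <- sum(grp & !is.na(assignments$family))
    n_gen <- sum(grp & !is.na(assignments$genus))
    n_spp <- sum(grp & !is.na(assignments$species))
    pct <- function(n) if (n_grp == 0L) 0 else round(100 * n / n_grp, 1)
    data.frame(marker = m, n_esv_total = sum(sel),
               n_esv_with_tax = sum(sel & has_tax), n_group_esv = n_grp,
               n_family = n_fam, pct_family = pct(n_fam),
               n_genus = n_gen, pct_genus = pct(n_gen),
               n_species = n_spp, pct_species = pct(n_spp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Taxon-by-depth detection table
#'
#' One row per distinct assigned taxon at its assigned rank (family, genus
#' or species; a genus-level taxon and a congeneric species-level taxon are
#' distinct rows). A taxon is flagged in a depth category iff at least
#' `min_reads` reads of an ESV assigned to it occur in at least one
#' non-control sample of that category; `n_samples` counts distinct
#' samples with a detection, pooled across markers.
#'
#' @param assignments Assignment data frame (see [assign_taxonomy()]).
#' @param esv_table Long-format ESV table.
#' @param metadata Sample metadata (see [read_sample_metadata()]).
#' @param min_reads Presence threshold per (ESV, sample), default 1 read.
#' @return Data frame: `order`, `family`, `genus`, `species` (NA below the
#'   assigned rank), `detected_deep`, `detected_mid`, `detected_shallow`,
#'   `n_samples`.
#' @export
taxon_detection_table <- function(assignments, esv_table, metadata,
                                  min_reads = 1L) {
  keep_rank <- assignments$assigned_rank %in% c("family", "genus", "species")
  asg <- assignments[keep_rank, , drop = FALSE]
  reads <- esv_table[esv_table$read_count >= min_reads, , drop = FALSE]
  meta <- metadata[!metadata$is_control, , drop = FALSE]
  reads <- reads[reads$sample_id %in% meta$sample_id, , drop = FALSE]
  reads <- reads[reads$esv_id %in% asg$esv_id, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(data.frame(order = character(0), family = character(0),
                      genus = character(0), species = character(0),
                      detected_deep = logical(0), detected_mid = logical(0),
                      detected_shallow = logical(0), n_samples = integer(0),
                      stringsAsFactors = FALSE))
  }
  ai <- match(reads$esv_id, asg$esv_id)
  mi <- match(reads$sample_id, meta$sample_id)
  taxon_key <- paste(asg$order[ai], asg$family[ai], asg$genus[ai],
                     asg$species[ai], sep = "\r")
  cat3 <- as.character(depth_category(meta$depth_m[mi]))
  det <- data.frame(taxon_key = taxon_key, sample_id = reads$sample_id,
                    category = cat3, ai = ai, stringsAsFactors = FALSE)
  keys <- unique(det$taxon_key)
  rows <- lapply(keys, function(k) {
    d <- det[det$taxon_key == k, , drop = FALSE]
    a <- asg[d$ai[1L], , drop = FALSE]
    data.frame(order = a$order, family = a$family, genus = a$genus,
               species = a$species,
               detected_deep = "deep" %in% d$category,
               detected_mid = "mid" %in% d$category,
               detected_shallow = "shallow" %in% d$category,
               n_samples = length(unique(d$sample_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$order, out$family, out$genus, out$species,
                   method = "radix", na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a taxon-by-depth detection table from delimited text
#'
#' Reads a detection table in the layout written by
#' [taxon_detection_table()] or transcribed from a publication: rank
#' columns with blanks below the assigned rank, and depth flags given as
#' `Y`/blank (or logical).
#'
#' @param path Delimited file with columns `order`, `family`, `genus`,
#'   `species`, `deep`, `mid`, `shallow` (or `detected_*`), `n_samples`.
#' @param sep Field separator.
#' @return Detection-table data frame (see [taxon_detection_table()]).
#' @export
read_taxon_detection_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  names(df) <- sub("^detected_", "", names(df))
  need <- c("order", "family", "genus", "species", "deep", "mid", "shallow",
            "n_samples")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("read_taxon_detection_table: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  flag <- function(x) toupper(trimws(x)) %in% c("Y", "YES", "TRUE", "1")
  out <- data.frame(order = df$order, family = df$family, genus = df$genus,
                    species = df$species,
                    detected_deep = flag(df$deep),
                    detected_mid = flag(df$mid),
                    detected_shallow = flag(df$shallow),
                    n_samples = as.integer(df$n_samples),
                    stringsAsFactors = FALSE)
  for (r in c("order", "family", "genus", "species")) {
    out[[r]][!nzchar(trimws(out[[r]]))] <- NA_character_
  }
  if (any(!out$detected_deep & !out$detected_mid & !out$detected_shallow)) {
    stop("read_taxon_detection_table: every row needs at least one depth flag")
  }
  out
}

#' Count distinct taxa at a rank in a detection table
#'
#' Counts distinct taxon names at the given rank, each name once across
#' rows; optionally restricted to taxa flagged in one depth category.
#'
#' @param detection_table Output of [taxon_detection_table()] or
#'   [read_taxon_detection_table()].
#' @param rank `"family"`, `"genus"` or `"species"`.
#' @param category Optional: `"shallow"`, `"mid"` or `"deep"`.
#' @return Integer count.
#' @export
count_distinct_taxa <- function(detection_table,
                                rank = c("family", "genus", "species"),
                                category = NULL) {
  rank <- match.arg(rank)
  tab <- detection_table
  if (!is.null(category)) {
    category <- match.arg(category, c("shallow", "mid", "deep"))
    tab <- tab[tab[[paste0("detected_", category)]], , drop = FALSE]
  }
  length(unique(stats::na.omit(tab[[rank]])))
}

#' Overlap between eDNA and conventional-survey taxon sets
#'
#' Partitions two taxon-name sets at a common rank into method-exclusive
#' and shared counts.
#'
#' @param edna_taxa,conventional_taxa Character vectors of taxon names.
#' @param rank Optional rank label recorded in the output.
#' @return Data frame with `n_edna_only`, `n_shared`, `n_conventional_only`
#'   (and `rank` if given).
#' @export
#' @examples
#' method_overlap(c("Gadidae", "Rajidae"), c("Rajidae", "Clupeidae"))
method_overlap <- function(edna_taxa, conventional_taxa, rank = NULL) {
  e <- unique(edna_taxa)
  c_ <- unique(conventional_taxa)
  out <- data.frame(n_edna_only = length(setdiff(e, c_)),
                    n_shared = length(intersect(e, c_)),
                    n_conventional_only = length(setdiff(c_, e)))
  if (!is.null(rank)) out <- cbind(rank = rank, out)
  out
}
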