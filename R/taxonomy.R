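#' Selection score for a similarity hit
#'
#' The selection criterion scores a hit as percent sequence identity
#' multiplied by percent overlap between query and reference, on a 0-100
#' scale: `score = identity_pct * overlap_pct / 100`.
#'
#' @param identity_pct Percent identity in \[0, 100\].
#' @param overlap_pct Percent overlap (query coverage) in \[0, 100\]; see
#'   [overlap_pct()].
#' @return Numeric score(s) in \[0, 100\].
#' @export
#' @examples
#' selection_score(98, 100)  # 98
#' selection_score(90, 50)   # 45
selection_score <- function(identity_pct, overlap_pct) {
  if (any(!is.finite(identity_pct)) || any(identity_pct < 0 | identity_pct > 100)) {
    stop("selection_score: identity_pct must lie in [0, 100]")
  }
  if (any(!is.finite(overlap_pct)) || any(overlap_pct < 0 | overlap_pct > 100)) {
    stop("selection_score: overlap_pct must lie in [0, 100]")
  }
  identity_pct * overlap_pct / 100
}

#' Percent overlap (query coverage) of an alignment
#'
#' Overlap is read as query coverage, `100 * align_len / query_len`, capped
#' at 100 (gapped alignments can exceed the query length).
#'
#' @param align_len Alignment length (positive integer).
#' @param query_len Query sequence length (positive integer).
#' @return Percent overlap in \[0, 100\].
#' @export
overlap_pct <- function(align_len, query_len) {
  if (any(align_len <= 0) || any(query_len <= 0)) {
    stop("overlap_pct: lengths must be positive")
  }
  pmin(100, 100 * align_len / query_len)
}

#' Rank-specific selection-score thresholds
#'
#' Minimum selection scores at which an assignment is reported at family,
#' genus and species rank. Thresholds are inclusive: a score of exactly
#' `family_min` is reported at family. Defaults: family 95, genus 98,
#' species 100 (a perfect match).
#'
#' @param family_min,genus_min,species_min Minimum scores, non-decreasing,
#'   `species_min <= 100`.
#' @param tie_tol Score tolerance used both for tie detection among hits
#'   and for threshold comparison; defaults to 1e-9 (exact ties only).
#' @return List of class `"taxonomy_thresholds"`.
#' @export
taxonomy_thresholds <- function(family_min = 95, genus_min = 98,
                                species_min = 100, tie_tol = 1e-9) {
  if (!(family_min <= genus_min && genus_min <= species_min && species_min <= 100)) {
    stop("taxonomy_thresholds: need family_min <= genus_min <= species_min <= 100")
  }
  if (tie_tol < 0) stop("taxonomy_thresholds: tie_tol must be >= 0")
  structure(list(family_min = family_min, genus_min = genus_min,
                 species_min = species_min, tie_tol = tie_tol),
            class = "taxonomy_thresholds")
}

empty_assignment <- function(esv_id) {
  out <- data.frame(esv_id = esv_id, best_score = NA_real_,
                    assigned_rank = "none", n_tied_hits = 0L,
                    stringsAsFactors = FALSE)
  for (r in lineage_ranks()) out[[r]] <- NA_character_
  out
}

#' Assign taxonomy to one ESV from its similarity hits
#'
#' Implements the selection-criterion / lowest-common-ancestor rule:
#' 1. score every hit with [selection_score()] (overlap = query coverage,
#'    capped at 100);
#' 2. keep only the best-scoring hit per subject taxon, take the maximum
#'    score, and collect the hits tying it within `tie_tol`;
#' 3. collapse the tied hits' lineages to their lowest common ancestor;
#' 4. truncate the result to the deepest rank whose threshold the best
#'    score meets (species / genus / family, inclusive); scores below the
#'    family threshold are reported above family rank.
#'
#' @param hits Hit data frame for a single query (see [read_hit_table()]).
#' @param thresholds A [taxonomy_thresholds()] object.
#' @return One-row data frame: `esv_id`, `best_score`, `assigned_rank` (one
#'   of `"species"`, `"genus"`, `"family"`, `"above_family"`, `"none"`),
#'   `n_tied_hits`, and the seven lineage rank columns.
#' @export
assign_esv <- function(hits, thresholds = taxonomy_thresholds()) {
  stopifnot(inherits(thresholds, "taxonomy_thresholds"))
  if (nrow(hits) == 0L) return(empty_assignment(NA_character_))
  qid <- unique(hits$query_id)
  if (length(qid) != 1L) {
    stop("assign_esv: hits must share one query_id, got: ",
         paste(qid, collapse = ", "))
  }
  score <- selection_score(hits$identity_pct,
                           overlap_pct(hits$align_len, hits$query_len))
  # one hit per subject taxon (its best-scoring one) so a multiply-hit
  # taxon cannot dominate the tied set
  ord <- order(-score)
  hits <- hits[ord, , drop = FALSE]
  score <- score[ord]
  taxon <- apply(hits[, lineage_ranks()], 1L, paste, collapse = "\r")
  first <- !duplicated(taxon)
  hits <- hits[first, , drop = FALSE]
  score <- score[first]

  tol <- thresholds$tie_tol
  best <- score[1L]
  tied <- which(score >= best - tol)
  cand <- lca(hits[tied, , drop = FALSE])

  rank_allowed <- if (best >= thresholds$species_min - tol) 7L
  else if (best >= thresholds$genus_min - tol) 6L
  else if (best >= thresholds$family_min - tol) 5L
  else 4L  # reported above family: keep at most kingdom..order
  depth <- min(rank_allowed, lineage_depth(cand))
  assigned <- cand
  if (depth < 7L) assigned[(depth + 1L):7L] <- NA_character_
  rank_label <- if (lineage_depth(assigned) >= 7L) "species"
  else if (lineage_depth(assigned) == 6L) "genus"
  else if (lineage_depth(assigned) == 5L) "family"
  else "above_family"

  out <- data.frame(esv_id = qid, best_score = best,
                    assigned_rank = rank_label, n_tied_hits = length(tied),
                    stringsAsFactors = FALSE)
  for (r in lineage_ranks()) out[[r]] <- unname(assigned[[r]])
  out
}

#' Assign taxonomy to every ESV in a hit table
#'
#' Applies [assign_esv()] per query id. ESVs listed in `all_esv_ids` but
#' absent from the hit table receive an assignment of rank `"none"` so that
#' total-ESV accounting (e.g. [rank_resolution_summary()]) is possible.
#'
#' @param hits Hit data frame (see [read_hit_table()]).
#' @param thresholds A [taxonomy_thresholds()] object.
#' @param all_esv_ids Optional character vector of every ESV id in the
#'   marker's table (defaults to the ids present in `hits`).
#' @return Assignment data frame, one row per ESV.
#' @export
assign_taxonomy <- function(hits, thresholds = taxonomy_thresholds(),
                            all_esv_ids = NULL) {
  ids <- unique(hits$query_id)
  rows <- lapply(split(hits, factor(hits$query_id, levels = ids)),
                 assign_esv, thresholds = thresholds)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_assignment(character(0))[0L, ]
  if (!is.null(all_esv_ids)) {
    missing <- setdiff(all_esv_ids, ids)
    if (length(missing) > 0L) {
      out <- rbind(out, do.call(rbind, lapply(missing, empty_assignment)))
    }
    out <- out[match(all_esv_ids, out$esv_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Drop assignments matching a blocklist of spurious taxa
#'
#' Removes assignments whose lineage contains any blocklisted name at any
#' rank (e.g. terrestrial or domestic species flagged as irrelevant for a
#' marine survey). Off by default in the pipeline: an empty blocklist is
#' the identity.
#'
#' @param assignments Assignment data frame (see [assign_taxonomy()]).
#' @param blocklist Character vector of taxon names at any rank.
#' @return Filtered assignment data frame; the number of removals is
#'   reported via `message()`.
#' @export
filter_spurious <- function(assignments, blocklist = character(0)) {
  if (length(blocklist) == 0L || nrow(assignments) == 0L) return(assignments)
  hit <- Reduce(`|`, lapply(lineage_ranks(), function(r) {
    !is.na(assignments[[r]]) & assignments[[r]] %in% blocklist
  }))
  if (any(hit)) {
    message("filter_spurious: removed ", sum(hit), " assignment(s)")
  }
  out <- assignments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
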