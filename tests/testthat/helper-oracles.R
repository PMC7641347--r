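# Independent oracles, deliberately written as plain enumerations so they
# share no code path with the package implementation.

# Brute-force taxonomy assignment: explicit loops over hits, taxa and ranks.
oracle_assign <- function(hits, family_min = 95, genus_min = 98,
                          species_min = 100, tol = 1e-9) {
  stopifnot(nrow(hits) >= 1L)
  n <- nrow(hits)
  score <- numeric(n)
  for (i in seq_len(n)) {
    ov <- 100 * hits$align_len[i] / hits$query_len[i]
    if (ov > 100) ov <- 100
    score[i] <- hits$identity_pct[i] * ov / 100
  }
  best <- max(score)
  # a taxon belongs to the tied set iff its best hit ties the maximum
  key <- character(n)
  for (i in seq_len(n)) {
    key[i] <- paste(sapply(RANKS, function(r) hits[[r]][i]), collapse = "|")
  }
  tied_taxa <- character(0)
  for (k in unique(key)) {
    if (max(score[key == k]) >= best - tol) tied_taxa <- c(tied_taxa, k)
  }
  # shared prefix of the tied lineages, rank by rank
  rows <- match(tied_taxa, key)
  anc <- rep(NA_character_, 7L)
  for (r in seq_len(7L)) {
    vals <- unique(sapply(rows, function(i) hits[[RANKS[r]]][i]))
    if (length(vals) == 1L && !is.na(vals)) anc[r] <- vals else break
  }
  allowed <- if (best >= species_min - tol) 7L else
    if (best >= genus_min - tol) 6L else
      if (best >= family_min - tol) 5L else 4L
  depth <- 0L
  for (r in seq_len(7L)) if (!is.na(anc[r])) depth <- r
  final <- min(allowed, depth)
  lin <- anc
  if (final < 7L) for (r in (final + 1L):7L) lin[r] <- NA_character_
  rank_label <- if (final >= 7L) "species" else if (final == 6L) "genus" else
    if (final == 5L) "family" else "above_family"
  list(best_score = best, assigned_rank = rank_label,
       lineage = stats::setNames(lin, RANKS), n_tied = length(tied_taxa))
}

# random hit set against a synthetic lineage table
random_hit_set <- function(lineage_table, query_id = "q1") {
  n <- sample(1:6, 1L)
  rows <- lineage_table[sample(nrow(lineage_table), n, replace = TRUE), ]
  ident <- round(runif(n, 80, 100), 3)
  # occasionally force perfect identity and exact ties
  ident[runif(n) < 0.3] <- 100
  if (n >= 2L && runif(1) < 0.4) ident[2L] <- ident[1L]
  alen <- sample(110:150, n, replace = TRUE)
  out <- list()
  for (i in seq_len(n)) {
    lin <- stats::setNames(as.character(unlist(rows[i, RANKS])), RANKS)
    out[[i]] <- hit(query_id, lin, identity = ident[i], align_len = alen[i],
                    query_len = 150, taxon_key = rows$taxon_key[i])
  }
  do.call(rbind, out)
}

# Rank-regression oracle: iteratively reweighted L1 on pairwise
# differences (the Wilcoxon dispersion is proportional to the L1 norm of
# pairwise residual differences, so both routes share a minimizer).
oracle_rank_coef <- function(y, X) {
  n <- length(y)
  pr <- t(utils::combn(n, 2L))
  dy <- y[pr[, 1L]] - y[pr[, 2L]]
  dX <- X[pr[, 1L], , drop = FALSE] - X[pr[, 2L], , drop = FALSE]
  b <- stats::coef(stats::lm.fit(dX, dy))
  b[is.na(b)] <- 0
  for (it in 1:400) {
    r <- dy - drop(dX %*% b)
    w <- 1 / pmax(abs(r), 1e-9)
    bn <- stats::coef(stats::lm.fit(dX * sqrt(w), dy * sqrt(w)))
    bn[is.na(bn)] <- 0
    if (max(abs(bn - b)) < 1e-11) { b <- bn; break }
    b <- bn
  }
  unname(b)
}
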