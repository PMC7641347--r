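#' Taxonomic rank ladder
#'
#' The seven Linnaean ranks used throughout the package, ordered from the
#' root (kingdom) to the tip (species).
#'
#' @return Character vector of rank names, root first.
#' @export
#' @examples
#' lineage_ranks()
lineage_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a taxonomic lineage
#'
#' A lineage is a named character vector over the seven ranks of
#' [lineage_ranks()], with `NA` for unnamed ranks. Named ranks must form a
#' prefix from the root: a rank may only be named if every rank above it is
#' named.
#'
#' @param kingdom,phylum,class,order,family,genus,species Rank names
#'   (character scalars) or `NA`.
#' @return Named character vector of length 7.
#' @export
#' @examples
#' lineage(kingdom = "Metazoa", phylum = "Chordata", class = "Actinopteri")
lineage <- function(kingdom = NA, phylum = NA, class = NA, order = NA,
                    family = NA, genus = NA, species = NA) {
  lin <- c(kingdom = as.character(kingdom), phylum = as.character(phylum),
           class = as.character(class), order = as.character(order),
           family = as.character(family), genus = as.character(genus),
           species = as.character(species))
  validate_lineage(lin)
  lin
}

validate_lineage <- function(lin, what = "lineage") {
  named <- !is.na(lin) & nzchar(lin)
  if (any(named & !nzchar(trimws(lin)))) {
    stop(what, ": rank names must be non-empty strings")
  }
  # prefix closure: no named rank below an unnamed one
  if (any(named)) {
    deepest <- max(which(named))
    if (!all(named[seq_len(deepest)])) {
      stop(what, ": rank '", lineage_ranks()[deepest],
           "' is named but an ancestor rank is missing")
    }
  }
  invisible(lin)
}

#' Depth of a lineage
#'
#' @param lin A lineage vector (see [lineage()]).
#' @return Integer 0..7: index of the deepest named rank (0 = empty lineage).
#' @export
lineage_depth <- function(lin) {
  named <- which(!is.na(lin) & nzchar(lin))
  if (length(named) == 0L) 0L else max(named)
}

#' Truncate a lineage at a rank
#'
#' Blanks all ranks below `rank`.
#'
#' @param lin A lineage vector.
#' @param rank One of [lineage_ranks()].
#' @return The truncated lineage.
#' @export
truncate_lineage <- function(lin, rank) {
  ranks <- lineage_ranks()
  rank <- match.arg(rank, ranks)
  keep <- seq_len(match(rank, ranks))
  out <- lin
  out[setdiff(seq_along(ranks), keep)] <- NA_character_
  out
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest lineage prefix shared by every input; the empty
#' lineage (all `NA`) if the inputs share no rank. Used to resolve
#' taxonomically ambiguous similarity hits that tie on the selection score.
#'
#' @param lineages A list of lineage vectors, or a data frame with the seven
#'   rank columns of [lineage_ranks()] (one lineage per row).
#' @return A single lineage vector.
#' @export
#' @examples
#' a <- lineage("Metazoa", "Chordata", "Actinopteri", "Gadiformes",
#'              "Macrouridae", "Coryphaenoides", "Coryphaenoides rupestris")
#' b <- lineage("Metazoa", "Chordata", "Actinopteri", "Gadiformes",
#'              "Macrouridae", "Macrourus", "Macrourus berglax")
#' lca(list(a, b))["family"]
lca <- function(lineages) {
  if (is.data.frame(lineages)) {
    stopifnot(all(lineage_ranks() %in% names(lineages)))
    lineages <- lapply(seq_len(nrow(lineages)), function(i) {
      v <- as.character(unlist(lineages[i, lineage_ranks()]))
      names(v) <- lineage_ranks()
      v
    })
  }
  if (length(lineages) == 0L) stop("lca: empty set of lineages")
  out <- stats::setNames(rep(NA_character_, 7L), lineage_ranks())
  for (r in seq_len(7L)) {
    vals <- vapply(lineages, function(l) as.character(l[[r]]), character(1))
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    out[r] <- vals[1L]
  }
  out
}
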