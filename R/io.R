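#' Read ESV sequences from a FASTA file
#'
#' Reads a FASTA file of exact sequence variants (ESVs). Record ids are the
#' header up to the first whitespace; sequences are uppercased and input
#' order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping ESV id to sequence. An empty file
#'   yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L || !any(grepl("^>", readLines(path, warn = FALSE)))) {
    warning("read_fasta: no FASTA records in ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("read_fasta: duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  }
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Read a taxon-key to lineage table
#'
#' A lineage table maps a taxon key (e.g. an accession or taxid used in the
#' hit table) to the seven ranks of [lineage_ranks()]. Empty strings are
#' treated as missing ranks. Each row must satisfy the lineage prefix rule
#' (no named rank below an unnamed one).
#'
#' @param path Delimited text file with columns `taxon_key` plus the seven
#'   rank columns.
#' @param sep Field separator (default tab).
#' @return Data frame with `taxon_key` and rank columns (`NA` for missing).
#' @export
read_lineage_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("taxon_key", lineage_ranks())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("read_lineage_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  for (r in lineage_ranks()) df[[r]][!nzchar(trimws(df[[r]]))] <- NA_character_
  if (anyDuplicated(df$taxon_key)) {
    stop("read_lineage_table: duplicate taxon_key(s): ",
         paste(unique(df$taxon_key[duplicated(df$taxon_key)]), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    lin <- stats::setNames(as.character(unlist(df[i, lineage_ranks()])), lineage_ranks())
    validate_lineage(lin, what = paste0("lineage for taxon_key '", df$taxon_key[i], "'"))
  }
  df[, need]
}

# Default column layout: the common 12-column tabular similarity-search
# output extended with query length in column 13.
default_hit_columns <- function() {
  c(query_id = 1L, subject_key = 2L, identity_pct = 3L, align_len = 4L,
    mismatch = 5L, gapopen = 6L, qstart = 7L, qend = 8L, sstart = 9L,
    send = 10L, evalue = 11L, bitscore = 12L, query_len = 13L)
}

#' Read a tabular similarity-search hit table
#'
#' Reads hits in the common 12-column tabular format (query id, subject key,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score) extended with query length as column 13,
#' filters them at an e-value cutoff, and joins each subject key to its
#' ranked lineage.
#'
#' @param path Path to the tab-delimited hit table (no header by default).
#' @param lineage Lineage table from [read_lineage_table()].
#' @param evalue_max Maximum e-value retained (default 0.001).
#' @param col_map Optional named integer vector remapping the required
#'   fields (`query_id`, `subject_key`, `identity_pct`, `align_len`,
#'   `evalue`, `bitscore`, `query_len`) to column positions.
#' @param sep Field separator.
#' @param header Logical; does the file carry a header line?
#' @return Data frame of hits: `query_id`, `taxon_key`, `identity_pct`,
#'   `align_len`, `query_len`, `evalue`, `bitscore` plus the seven lineage
#'   rank columns. Rows whose subject key is absent from `lineage` are
#'   dropped with a warning.
#' @export
read_hit_table <- function(path, lineage, evalue_max = 0.001, col_map = NULL,
                           sep = "\t", header = FALSE) {
  empty_file <- length(readLines(path, n = 1L + as.integer(header),
                                 warn = FALSE)) <= as.integer(header)
  raw <- if (empty_file) {
    data.frame()
  } else {
    utils::read.delim(path, sep = sep, header = header,
                      stringsAsFactors = FALSE, colClasses = "character",
                      fileEncoding = "UTF-8")
  }
  cols <- default_hit_columns()
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  need <- c("query_id", "subject_key", "identity_pct", "align_len",
            "evalue", "bitscore", "query_len")
  if (nrow(raw) == 0L) {
    out <- data.frame(query_id = character(0), taxon_key = character(0),
                      identity_pct = numeric(0), align_len = integer(0),
                      query_len = integer(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
    for (r in lineage_ranks()) out[[r]] <- character(0)
    return(out)
  }
  if (max(cols[need]) > ncol(raw)) {
    stop("read_hit_table: table has ", ncol(raw), " columns but column map needs ",
         max(cols[need]))
  }
  num <- function(field) {
    x <- suppressWarnings(as.numeric(raw[[cols[[field]]]]))
    bad <- which(is.na(x) & nzchar(raw[[cols[[field]]]]))
    if (length(bad) > 0L) {
      stop("read_hit_table: malformed ", field, " at line ",
           bad[1L] + as.integer(header))
    }
    x
  }
  hits <- data.frame(
    query_id = raw[[cols[["query_id"]]]],
    taxon_key = raw[[cols[["subject_key"]]]],
    identity_pct = num("identity_pct"),
    align_len = as.integer(num("align_len")),
    query_len = as.integer(num("query_len")),
    evalue = num("evalue"),
    bitscore = num("bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100, na.rm = TRUE)) {
    stop("read_hit_table: identity_pct outside [0, 100]")
  }
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  unknown <- !(hits$taxon_key %in% lineage$taxon_key)
  if (any(unknown)) {
    warning("read_hit_table: dropped ", sum(unknown),
            " hit(s) with taxon_key absent from the lineage table: ",
            paste(unique(hits$taxon_key[unknown]), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
  }
  idx <- match(hits$taxon_key, lineage$taxon_key)
  for (r in lineage_ranks()) hits[[r]] <- lineage[[r]][idx]
  rownames(hits) <- NULL
  hits
}

#' Read sample metadata
#'
#' Reads per-water-sample metadata: station, transect, year, sampling depth
#' (m), sampling location (surface, deep scattering layer, or bottom),
#' filtered volume (L), optional DNA concentration (pg/uL) and a control
#' flag. Controls (field blanks, extraction/PCR negatives) are carried in
#' the metadata but excluded from every downstream statistic.
#'
#' @param path Delimited text file with columns `sample_id`, `station`,
#'   `transect`, `year`, `depth_m`, `location`, `volume_l` and optionally
#'   `dna_conc`, `is_control`.
#' @param sep Field separator (default tab).
#' @return Data frame with validated columns; `is_control` is logical
#'   (default `FALSE` when absent), `dna_conc` is `NA` when absent.
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("sample_id", "station", "transect", "year", "depth_m",
            "location", "volume_l")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("read_sample_metadata: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("read_sample_metadata: duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$depth_m <- as.numeric(df$depth_m)
  df$volume_l <- as.numeric(df$volume_l)
  df$year <- as.integer(df$year)
  if (any(!is.finite(df$depth_m)) || any(df$depth_m < 0)) {
    stop("read_sample_metadata: depth_m must be finite and >= 0")
  }
  if (any(!is.finite(df$volume_l)) || any(df$volume_l <= 0)) {
    stop("read_sample_metadata: volume_l must be > 0")
  }
  ok_loc <- c("surface", "deep_scattering_layer", "bottom")
  bad <- setdiff(unique(df$location), ok_loc)
  if (length(bad) > 0L) {
    stop("read_sample_metadata: unknown location label(s): ",
         paste(bad, collapse = ", "), " (expected ",
         paste(ok_loc, collapse = ", "), ")")
  }
  if (is.null(df$dna_conc)) df$dna_conc <- NA_real_ else df$dna_conc <- as.numeric(df$dna_conc)
  if (any(df$dna_conc < 0, na.rm = TRUE)) {
    stop("read_sample_metadata: dna_conc must be >= 0")
  }
  if (is.null(df$is_control)) {
    df$is_control <- FALSE
  } else {
    df$is_control <- parse_logical(df$is_control, "is_control")
  }
  df[, c(need, "dna_conc", "is_control")]
}

parse_logical <- function(x, what) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "n", "0", "")] <- FALSE
  if (anyNA(out)) stop("unrecognized ", what, " value(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read an ESV read-count table
#'
#' Long-format read counts: one row per (marker, ESV, sample) with a
#' non-negative integer read count. (ESV, sample) pairs must be unique
#' within a marker.
#'
#' @param path Delimited file with columns `marker`, `esv_id`, `sample_id`,
#'   `read_count`.
#' @param sep Field separator.
#' @return Validated data frame.
#' @export
read_esv_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("marker", "esv_id", "sample_id", "read_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("read_esv_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$marker <- as.character(df$marker)
  df$esv_id <- as.character(df$esv_id)
  df$sample_id <- as.character(df$sample_id)
  df$read_count <- as.integer(df$read_count)
  if (any(is.na(df$read_count)) || any(df$read_count < 0)) {
    stop("read_esv_table: read_count must be a non-negative integer")
  }
  key <- paste(df$marker, df$esv_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("read_esv_table: duplicate (marker, esv_id, sample_id) row(s)")
  }
  df[, need]
}

#' Read a taxonomy-assignment table
#'
#' Reads assignments previously written by [write_edna_table()] (the format
#' produced by `edna assign`): one row per ESV with the selection score,
#' assigned rank and the seven lineage rank columns.
#'
#' @param path Delimited file.
#' @param sep Field separator.
#' @return Assignment data frame (see [assign_taxonomy()]).
#' @export
read_assignment_table <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", na.strings = c("NA", ""))
  need <- c("esv_id", "best_score", "assigned_rank", "n_tied_hits", lineage_ranks())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("read_assignment_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$esv_id <- as.character(df$esv_id)
  for (r in lineage_ranks()) df[[r]] <- as.character(df[[r]])
  df
}

#' Write a pipeline table to delimited text
#'
#' UTF-8, tab-separated by default, no quoting, no row names; `NA` written
#' as empty string. Tables written with this function round-trip through
#' the matching reader.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_edna_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
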