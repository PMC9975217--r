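# Domain types are represented with plain base-R containers:
#   * records:   data.frame(id, sequence, dataset, short_amplicon,
#                best_ref_identity)
#   * taxonomy:  data.frame(id, kingdom, ..., species) -- 8 rank columns
#   * abundance: numeric matrix, rows = metabarcode ids, cols = sample ids
#   * metadata:  data.frame, one row per sample (region, station, date,
#                depth_m, depth_type, size_fraction, lat/lon, 10 env vars)

#' Read a FASTA file of metabarcode sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' invariants the pipeline relies on: unique ids, non-empty uppercase
#' sequences restricted to A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("invalid sequence characters in ", path)
      }
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (length(ids) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(ids) || any(ids == "")) {
    stop("FASTA record with empty header in ", path)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty)) {
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC-core characters (outside A/C/G/T/N) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read the abundance / metadata / taxonomy table triple
#'
#' Loads the three TSV inputs and validates their cross-references: every
#' abundance row id must have a taxonomy entry and every abundance column
#' id a metadata row. Missing environmental values are encoded as empty
#' cells and read as `NA`.
#'
#' @param abundance_path TSV, first column metabarcode id, remaining
#'   columns one per sample, non-negative numeric values.
#' @param metadata_path TSV, one row per sample; must contain columns
#'   `sample_id`, `dataset`, `region`, `station`, `date`, `depth_m`,
#'   `depth_type`, plus any of [ENV_VARIABLES].
#' @param taxonomy_path TSV with columns `id` and the 8 [PR2_RANKS].
#' @param regions Allowed region vocabulary.
#' @return A list with elements `abundance` (matrix), `metadata`
#'   (data.frame) and `taxonomy` (data.frame).
#' @export
read_tables <- function(abundance_path, metadata_path, taxonomy_path,
                        regions = DEFAULT_REGIONS) {
  ab <- read.delim(abundance_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(ab) < 2L) stop("abundance table needs id column plus samples")
  ids <- as.character(ab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate metabarcode id(s) in abundance table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(ab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample id(s) in abundance table")
  if (anyNA(m)) stop("missing values in abundance table")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop("negative abundance at row ", rownames(m)[bad[1L, 1L]],
         ", sample ", colnames(m)[bad[1L, 2L]])
  }

  md <- read.delim(metadata_path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("sample_id", "dataset", "region", "station", "date",
            "depth_m", "depth_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  bad_region <- setdiff(unique(md$region), regions)
  if (length(bad_region)) {
    stop("region(s) outside the configured vocabulary: ",
         paste(bad_region, collapse = ", "))
  }
  md$date <- as.Date(md$date)

  tx <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", PR2_RANKS), names(tx))
  if (length(miss)) stop("taxonomy missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tx$id)) stop("duplicate id in taxonomy table")

  no_tax <- setdiff(rownames(m), tx$id)
  if (length(no_tax)) {
    stop("metabarcode id(s) without taxonomy entry: ",
         paste(no_tax, collapse = ", "))
  }
  no_md <- setdiff(colnames(m), md$sample_id)
  if (length(no_md)) {
    stop("sample id(s) without metadata: ", paste(no_md, collapse = ", "))
  }
  list(abundance = m, metadata = md, taxonomy = tx)
}

#' Write an abundance matrix as TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize each sample to relative abundance
#'
#' Divides every column (sample) of the abundance matrix by its total, so
#' that columns sum to 1 and values lie in \[0, 1\]. This is the
#' read-count normalization applied after merging datasets; the zero
#' pattern of the matrix is preserved.
#'
#' @param m Non-negative abundance matrix (metabarcodes x samples).
#' @return Matrix of the same shape with unit column sums.
#' @export
normalize_samples <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("abundance matrix has negative values")
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2L, totals, "/")
}

#' Taxonomic status of one rank in an 8-rank path
#'
#' A rank labelled with the `"Unknown"` sentinel is *unassigned* when no
#' more specific rank is assigned either, but is only a *gap* in the
#' hierarchy when some lower rank carries an assignment (the lineage is
#' known more precisely further down, so the intermediate rank is missing
#' from the reference hierarchy rather than genuinely unassigned).
#'
#' @param tax Character vector of 8 rank labels in [PR2_RANKS] order, or a
#'   one-row data.frame with the 8 rank columns.
#' @param rank One of [PR2_RANKS].
#' @return `"assigned"`, `"unassigned"` or `"gap"`.
#' @export
rank_status <- function(tax, rank) {
  if (is.data.frame(tax)) tax <- unlist(tax[1L, PR2_RANKS], use.names = FALSE)
  tax <- as.character(tax)
  if (length(tax) != 8L) stop("taxonomy path must have exactly 8 ranks")
  i <- match(rank, PR2_RANKS)
  if (is.na(i)) stop("unknown rank name: ", rank)
  if (tax[i] != UNKNOWN_LABEL) return("assigned")
  lower <- if (i < 8L) tax[(i + 1L):8L] else character()
  if (any(lower != UNKNOWN_LABEL)) "gap" else "unassigned"
}

#' Classify a sampling depth into a depth layer
#'
#' Surface is depth <= 5 m, mesopelagic >= 200 m, bathypelagic >= 1000 m.
#' The deep chlorophyll maximum cannot be inferred from depth alone, so an
#' explicit `dcm_flag` takes precedence over the thresholds. Depths in
#' (5, 200) without the flag fall into `OTHER`.
#'
#' @param depth_m Non-negative depth in metres (vectorized).
#' @param dcm_flag Logical, whether the sample was taken at the DCM.
#' @return Character vector of [DEPTH_TYPES] values.
#' @export
depth_layer <- function(depth_m, dcm_flag = FALSE) {
  if (any(is.na(depth_m)) || any(depth_m < 0)) {
    stop("depth must be non-negative")
  }
  n <- max(length(depth_m), length(dcm_flag))
  depth_m <- rep_len(depth_m, n)
  dcm_flag <- rep_len(dcm_flag, n)
  out <- rep("OTHER", n)
  out[depth_m <= 5] <- "SRF"
  out[depth_m >= 200] <- "MESO"
  out[depth_m >= 1000] <- "BATHY"
  out[dcm_flag] <- "DCM"
  out
}

#' Meteorological season of a date (northern hemisphere)
#'
#' DJF = winter, MAM = spring, JJA = summer, SON = autumn. All
#' time-series sites handled by the pipeline are in the Northern
#' Hemisphere.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Character vector in `c("DJF","MAM","JJA","SON")`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}
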