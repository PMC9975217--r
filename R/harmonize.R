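# Per-dataset homogenization: every dataset passes the same three screens
# (taxon blocklist, minimum database identity, minimum length) before the
# abundance tables are merged and normalized together.

#' Remove records whose taxonomy matches a blocklist
#'
#' A record is removed when *any* of its 8 rank labels is in the
#' blocklist. The default list screens out metazoans, land plants
#' (Streptophyta) and macroalgal classes.
#'
#' @param records Records data.frame (see [read_fasta()] plus `dataset`).
#' @param taxonomy Taxonomy data.frame covering all record ids.
#' @param blocklist Character vector of taxon names.
#' @return List with `records` (retained rows) and `removed` (count).
#' @export
filter_blocklist <- function(records, taxonomy,
                             blocklist = DEFAULT_BLOCKLIST) {
  tx <- taxonomy[match(records$id, taxonomy$id), PR2_RANKS, drop = FALSE]
  if (anyNA(tx[[1L]]) && any(!records$id %in% taxonomy$id)) {
    stop("record id(s) without taxonomy: ",
         paste(setdiff(records$id, taxonomy$id), collapse = ", "))
  }
  hit <- Reduce(`|`, lapply(tx, function(col) col %in% blocklist))
  list(records = records[!hit, , drop = FALSE], removed = sum(hit))
}

#' Remove records below a reference-database identity threshold
#'
#' Drops records with `best_ref_identity` strictly below `min_identity`
#' (the homogenization screen is "less than 80 percent", so 80.0 itself is
#' retained). Identity is an input column carried over from the upstream
#' assignment; records missing it are kept by default since the screen was
#' applied upstream for most datasets.
#'
#' @param records Records data.frame with a `best_ref_identity` column.
#' @param min_identity Percentage threshold in \[0, 100\].
#' @param keep_missing Keep records whose identity is `NA`?
#' @return List with `records` and `removed`.
#' @export
filter_identity <- function(records, min_identity = 80,
                            keep_missing = TRUE) {
  idy <- records$best_ref_identity
  ok <- !is.na(idy)
  if (any(idy[ok] < 0 | idy[ok] > 100)) {
    stop("best_ref_identity outside [0, 100]")
  }
  drop <- (ok & idy < min_identity) | (!ok & !keep_missing)
  list(records = records[!drop, , drop = FALSE], removed = sum(drop))
}

#' Remove records at or below a minimum length
#'
#' Only sequences strictly longer than `min_len` base pairs are kept, so a
#' 200 bp sequence is removed at the default threshold.
#'
#' @param records Records data.frame.
#' @param min_len Length threshold in bp (strict).
#' @return List with `records` and `removed`.
#' @export
filter_length <- function(records, min_len = 200) {
  keep <- nchar(records$sequence) > min_len
  list(records = records[keep, , drop = FALSE], removed = sum(!keep))
}

#' Harmonize and merge per-dataset metabarcoding inputs
#'
#' Applies the three screens independently to each dataset, in the order
#' blocklist, identity, length (a record failing several screens is
#' attributed to the first), merges the abundance tables on the union of
#' samples, and normalizes every sample to relative abundance. Metabarcode
#' ids duplicated across datasets are namespaced as `dataset:id`.
#'
#' @param datasets Named list; each element a list with components
#'   `records` (data.frame: id, sequence, dataset, short_amplicon,
#'   best_ref_identity), `abundance` (matrix, rows = record ids) and
#'   `taxonomy` (data.frame).
#' @param blocklist,min_identity,min_len,keep_missing Filter settings,
#'   see [filter_blocklist()], [filter_identity()], [filter_length()].
#' @return List with `records` (merged data.frame), `abundance`
#'   (normalized merged matrix), `taxonomy` (merged data.frame) and
#'   `report` (one row per dataset: removed_blocklist,
#'   removed_low_identity, removed_short, retained).
#' @export
harmonize <- function(datasets, blocklist = DEFAULT_BLOCKLIST,
                      min_identity = 80, min_len = 200,
                      keep_missing = TRUE) {
  if (length(datasets) == 0L) stop("no datasets to harmonize")
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a named list")
  }

  all_ids <- unlist(lapply(datasets, function(d) d$records$id),
                    use.names = FALSE)
  namespace <- anyDuplicated(all_ids) > 0L

  rec_list <- list(); ab_list <- list(); tax_list <- list()
  report <- data.frame(dataset = names(datasets), input = 0L,
                       removed_blocklist = 0L, removed_low_identity = 0L,
                       removed_short = 0L, retained = 0L,
                       stringsAsFactors = FALSE)

  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    nm <- names(datasets)[k]
    rec <- d$records
    tax <- d$taxonomy
    ab <- d$abundance
    report$input[k] <- nrow(rec)

    f1 <- filter_blocklist(rec, tax, blocklist)
    f2 <- filter_identity(f1$records, min_identity, keep_missing)
    f3 <- filter_length(f2$records, min_len)
    report$removed_blocklist[k] <- f1$removed
    report$removed_low_identity[k] <- f2$removed
    report$removed_short[k] <- f3$removed
    report$retained[k] <- nrow(f3$records)

    rec <- f3$records
    keep_tax <- tax[tax$id %in% rec$id, , drop = FALSE]
    miss_ab <- setdiff(rec$id, rownames(ab))
    if (length(miss_ab)) {
      stop("dataset ", nm, ": record id(s) absent from abundance table: ",
           paste(miss_ab, collapse = ", "))
    }
    ab <- ab[rec$id, , drop = FALSE]
    if (namespace) {
      new_ids <- paste(nm, rec$id, sep = ":")
      rec$id <- new_ids
      keep_tax$id <- paste(nm, keep_tax$id, sep = ":")
      rownames(ab) <- new_ids
    }
    rec_list[[nm]] <- rec
    tax_list[[nm]] <- keep_tax
    ab_list[[nm]] <- ab
  }

  records <- do.call(rbind, c(rec_list, list(make.row.names = FALSE)))
  taxonomy <- do.call(rbind, c(tax_list, list(make.row.names = FALSE)))

  samples <- unique(unlist(lapply(ab_list, colnames), use.names = FALSE))
  merged <- matrix(0, nrow = nrow(records), ncol = length(samples),
                   dimnames = list(records$id, samples))
  for (ab in ab_list) {
    if (nrow(ab)) merged[rownames(ab), colnames(ab)] <- ab
  }
  empty <- colSums(merged) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " sample(s) with no retained metabarcodes: ",
            paste(colnames(merged)[empty], collapse = ", "))
    merged <- merged[, !empty, drop = FALSE]
  }
  merged <- normalize_samples(merged)

  list(records = records, abundance = merged, taxonomy = taxonomy,
       report = report)
}
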