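# Geographic occurrence of connected components across sea regions and
# depth layers, and abundance-based dissimilarity between regions.

#' Region and depth-layer occurrence profiles of connected components
#'
#' A component occurs in a region when it has positive abundance in at
#' least one sample of that region; within each occupied region, the set
#' of depth layers with positive abundance is recorded.
#'
#' @param ccs Named list of member vectors (see [extract_ccs()]).
#' @param abundance Normalized abundance matrix (metabarcodes x samples).
#' @param metadata Sample metadata data.frame (`sample_id`, `region`,
#'   `depth_type`).
#' @param regions Allowed region vocabulary.
#' @return Named list (one element per component) with fields `regions`
#'   (character vector) and `layers_by_region` (named list of layer sets).
#'   Components with all-zero abundance get an empty region set.
#' @export
occurrence_profiles <- function(ccs, abundance, metadata,
                                regions = DEFAULT_REGIONS) {
  samp <- colnames(abundance)
  i <- match(samp, metadata$sample_id)
  if (anyNA(i)) {
    stop("sample(s) without metadata: ",
         paste(samp[is.na(i)], collapse = ", "))
  }
  reg <- metadata$region[i]
  bad <- setdiff(unique(reg), regions)
  if (length(bad)) stop("sample(s) with unknown region: ",
                        paste(bad, collapse = ", "))
  lay <- metadata$depth_type[i]
  lapply(ccs, function(members) {
    v <- cc_abundance(members, abundance)
    pos <- v > 0
    r <- sort(unique(reg[pos]))
    lbr <- lapply(r, function(rr) sort(unique(lay[pos & reg == rr])))
    names(lbr) <- r
    list(regions = r, layers_by_region = lbr)
  })
}

#' Count components per exact region combination
#'
#' Each component counts once, for its full region set; combinations are
#' keyed by the sorted region names joined with `" + "`. Counts over all
#' combinations sum to the number of profiled components; singleton
#' combinations are the region-endemic components.
#'
#' @param profiles Output of [occurrence_profiles()].
#' @return Named integer vector (combination key -> component count),
#'   sorted by ascending combination size then key.
#' @export
combination_counts <- function(profiles) {
  if (length(profiles) == 0L) return(integer(0))
  keys <- vapply(profiles, function(p) paste(p$regions, collapse = " + "),
                 "")
  keys <- keys[keys != ""]
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sizes <- lengths(strsplit(names(counts), " + ", fixed = TRUE))
  counts[order(sizes, names(counts))]
}

#' Depth-layer sharing matrix between two regions
#'
#' For components exclusively shared between two regions, the percentage
#' of components present in depth layer `lx` of the first region and layer
#' `ly` of the second. A component occupying several layers in a region
#' contributes to several cells, so the matrix can sum past 100%.
#'
#' @param profiles Output of [occurrence_profiles()].
#' @param region_x,region_y The two regions compared (columns, rows).
#' @param restrict Character vector of component ids to use; defaults to
#'   the components whose region set is exactly `{region_x, region_y}`.
#' @param layers Layer vocabulary ordering the matrix.
#' @return Numeric matrix (layers of `region_y` x layers of `region_x`)
#'   of percentages in \[0, 100\].
#' @export
depth_sharing_matrix <- function(profiles, region_x, region_y,
                                 restrict = NULL, layers = DEPTH_TYPES) {
  if (is.null(restrict)) {
    restrict <- names(profiles)[vapply(profiles, function(p) {
      setequal(p$regions, c(region_x, region_y))
    }, NA)]
  }
  if (length(restrict) == 0L) {
    stop("no components exclusively shared between ", region_x, " and ",
         region_y)
  }
  prof <- profiles[restrict]
  m <- matrix(0, nrow = length(layers), ncol = length(layers),
              dimnames = list(layers, layers))
  for (p in prof) {
    lx <- p$layers_by_region[[region_x]]
    ly <- p$layers_by_region[[region_y]]
    m[ly, lx] <- m[ly, lx] + 1
  }
  100 * m / length(restrict)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `B = sum(|x - y|) / sum(x + y)`, in \[0, 1\] for non-negative input.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return The dissimilarity `B`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Abundance-based Jaccard dissimilarity from Bray-Curtis
#'
#' The transform `J = 2B / (1 + B)` mapping Bray-Curtis dissimilarity to
#' its Jaccard-type counterpart.
#'
#' @param B Bray-Curtis dissimilarity value(s) in \[0, 1\].
#' @return Jaccard dissimilarity value(s).
#' @export
jaccard_from_bray <- function(B) {
  if (any(B < 0 | B > 1)) stop("B must lie in [0, 1]")
  2 * B / (1 + B)
}

#' Pairwise region dissimilarity for one taxonomic division
#'
#' Metabarcodes of the given division are aggregated into one composite
#' vector per region (mean of normalized sample abundances, so regions
#' with few samples are not dominated by regions with many), and the
#' Bray-Curtis and Jaccard dissimilarities are computed between region
#' composites.
#'
#' @param abundance Normalized abundance matrix.
#' @param taxonomy Taxonomy data.frame.
#' @param division Division name to subset on.
#' @param metadata Sample metadata data.frame.
#' @return List of two symmetric region x region matrices, `bray_curtis`
#'   and `jaccard`. Regions with no samples are absent.
#' @export
region_dissimilarity <- function(abundance, taxonomy, division, metadata) {
  ids <- taxonomy$id[taxonomy$division == division]
  ids <- intersect(ids, rownames(abundance))
  if (length(ids) == 0L) stop("no metabarcodes in division ", division)
  sub <- abundance[ids, , drop = FALSE]
  i <- match(colnames(sub), metadata$sample_id)
  reg <- metadata$region[i]
  regions <- sort(unique(reg))
  comp <- vapply(regions, function(r) {
    rowMeans(sub[, reg == r, drop = FALSE])
  }, numeric(nrow(sub)))
  if (!is.matrix(comp)) comp <- matrix(comp, nrow = nrow(sub),
                                       dimnames = list(ids, regions))
  nr <- length(regions)
  B <- matrix(0, nr, nr, dimnames = list(regions, regions))
  for (a in seq_len(nr)) {
    for (b in seq_len(nr)) {
      if (a < b) B[a, b] <- B[b, a] <- bray_curtis(comp[, a], comp[, b])
    }
  }
  list(bray_curtis = B, jaccard = jaccard_from_bray(B))
}
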