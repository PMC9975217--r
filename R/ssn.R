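# Sequence similarity network at 100% identity: two metabarcodes are
# linked when they share a gap-free exact segment covering >= min_cov of
# both sequences (a zero-mismatch local alignment reduces to the longest
# common substring). Connected components of this graph are the pipeline's
# genus-level proxy units.

#' Longest common substring of two DNA sequences
#'
#' Length in bp of the longest contiguous segment shared exactly by `a`
#' and `b`; 0 when no character is shared. Vectorized over pairs.
#'
#' @param a,b Non-empty character vectors of equal length.
#' @return Integer vector of segment lengths.
#' @export
longest_common_substring <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty sequence")
  .lcs_length_cpp(as.character(a), as.character(b))
}

#' Evaluate the edge rule for one pair of records
#'
#' An edge exists when the longest exact shared segment covers at least
#' `min_cov` of *both* sequences. When exactly one of the two records is a
#' short amplicon (`short_amplicon = TRUE`, e.g. a 230 bp dataset among
#' ~430 bp datasets), coverage is tested on the short record only, so that
#' full containment of the short amplicon suffices.
#'
#' @param rec_a,rec_b One-row record data.frames (columns `id`,
#'   `sequence`, `short_amplicon`).
#' @param min_cov Coverage fraction threshold (inclusive).
#' @return A one-row data.frame (id_a, id_b, match_len, coverage_a,
#'   coverage_b) or `NULL` when the rule fails.
#' @export
pair_edge <- function(rec_a, rec_b, min_cov = 0.8) {
  L <- longest_common_substring(rec_a$sequence, rec_b$sequence)
  cov_a <- L / nchar(rec_a$sequence)
  cov_b <- L / nchar(rec_b$sequence)
  sa <- isTRUE(rec_a$short_amplicon)
  sb <- isTRUE(rec_b$short_amplicon)
  ok <- if (xor(sa, sb)) {
    if (sa) cov_a >= min_cov else cov_b >= min_cov
  } else {
    cov_a >= min_cov && cov_b >= min_cov
  }
  if (!ok) return(NULL)
  data.frame(id_a = rec_a$id, id_b = rec_b$id, match_len = L,
             coverage_a = cov_a, coverage_b = cov_b,
             stringsAsFactors = FALSE)
}

#' Build the exact-identity sequence similarity network
#'
#' Evaluates the edge rule on every unordered pair of records (with a
#' length-ratio prefilter that cannot change the edge set) and returns the
#' edge list. Self-pairs and duplicate pairs never occur by construction.
#'
#' @param records Records data.frame (`id`, `sequence`, `short_amplicon`).
#' @param min_cov Coverage fraction threshold (inclusive).
#' @return data.frame with columns id_a, id_b, match_len, coverage_a,
#'   coverage_b; zero rows when no pair qualifies.
#' @export
build_ssn <- function(records, min_cov = 0.8) {
  stopifnot(nrow(records) >= 1L)
  if (anyDuplicated(records$id)) stop("duplicate record id(s)")
  sa <- records$short_amplicon
  if (is.null(sa)) sa <- rep(FALSE, nrow(records))
  sa[is.na(sa)] <- FALSE
  hits <- .ssn_edge_scan_cpp(records$sequence, as.logical(sa), min_cov)
  data.frame(id_a = records$id[hits$ia], id_b = records$id[hits$ib],
             match_len = hits$match_len, coverage_a = hits$coverage_a,
             coverage_b = hits$coverage_b, stringsAsFactors = FALSE)
}

#' Extract connected components above a minimum size
#'
#' Components are found on the undirected graph of the edge list;
#' components with fewer than `min_size` member sequences are discarded
#' (small components cannot represent all integrated datasets). Components
#' are ordered and isolated nodes never survive the default threshold.
#'
#' @param edges Edge list from [build_ssn()].
#' @param node_ids All node ids (members with no edges form singletons).
#' @param min_size Minimum component size to keep.
#' @return Named list of member-id character vectors (sorted within each
#'   component), ordered by lexicographically smallest member id; names
#'   are provisional `CC1`, `CC2`, ... labels (see [label_ccs()]).
#' @export
extract_ccs <- function(edges, node_ids, min_size = 6) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_ids), name = as.character(node_ids))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$id_a, edges$id_b))
  }
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  members <- members[lengths(members) >= min_size]
  members <- lapply(members, sort)
  if (length(members) == 0L) return(structure(list(), names = character()))
  members <- members[order(vapply(members, `[`, "", 1L))]
  names(members) <- paste0("CC", seq_along(members))
  members
}

#' Extrapolate a genus label to a whole connected component
#'
#' When exactly one assigned genus occurs among the members of a
#' component, that name is extended to the members of unknown genus; with
#' none the component is `"unknown"`, with two or more `"ambiguous"`.
#'
#' @param members Character vector of member ids.
#' @param taxonomy Taxonomy data.frame covering the members.
#' @return A single genus label string.
#' @export
extrapolate_genus <- function(members, taxonomy) {
  g <- taxonomy$genus[match(members, taxonomy$id)]
  if (anyNA(g)) {
    stop("member id(s) without taxonomy: ",
         paste(members[is.na(g)], collapse = ", "))
  }
  assigned <- unique(g[g != UNKNOWN_LABEL])
  if (length(assigned) == 0L) "unknown"
  else if (length(assigned) == 1L) assigned
  else "ambiguous"
}

#' Order-level label of a connected component
#'
#' The single assigned order among members, or `"Unknown"` when none or
#' several occur.
#'
#' @param members Character vector of member ids.
#' @param taxonomy Taxonomy data.frame covering the members.
#' @return A single order label string.
#' @export
cc_order_label <- function(members, taxonomy) {
  o <- taxonomy$order[match(members, taxonomy$id)]
  assigned <- unique(o[!is.na(o) & o != UNKNOWN_LABEL])
  if (length(assigned) == 1L) assigned else UNKNOWN_LABEL
}

#' Per-sample abundance of a connected component
#'
#' Element-wise sum of the member rows of the abundance matrix.
#'
#' @param members Character vector of member ids.
#' @param abundance Abundance matrix (metabarcodes x samples).
#' @return Named numeric vector, one value per sample.
#' @export
cc_abundance <- function(members, abundance) {
  miss <- setdiff(members, rownames(abundance))
  if (length(miss)) {
    stop("member id(s) absent from abundance table: ",
         paste(miss, collapse = ", "))
  }
  colSums(abundance[members, , drop = FALSE])
}

#' Abundance matrix aggregated to connected components
#'
#' @param ccs Named list of member vectors (from [extract_ccs()]).
#' @param abundance Abundance matrix (metabarcodes x samples).
#' @return Matrix with one row per component.
#' @export
cc_abundance_matrix <- function(ccs, abundance) {
  m <- t(vapply(ccs, cc_abundance, numeric(ncol(abundance)),
                abundance = abundance))
  colnames(m) <- colnames(abundance)
  m
}

#' Assign final identifiers and labels to connected components
#'
#' Components are named `CC_<genus label>_<k>` in the style used for the
#' network units, where `<genus label>` comes from [extrapolate_genus()]
#' and `k` ranks components by descending total abundance (ties broken by
#' smallest member id).
#'
#' @param ccs Named list of member vectors.
#' @param taxonomy Taxonomy data.frame.
#' @param abundance Abundance matrix used for the abundance ranking.
#' @return List with `members` (relabelled list, in rank order) and
#'   `summary` (data.frame: cc_id, size, genus_label, order_label,
#'   total_abundance).
#' @export
label_ccs <- function(ccs, taxonomy, abundance) {
  if (length(ccs) == 0L) {
    return(list(members = structure(list(), names = character()),
                summary = data.frame(cc_id = character(), size = integer(),
                                     genus_label = character(),
                                     order_label = character(),
                                     total_abundance = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  tot <- vapply(ccs, function(m) sum(cc_abundance(m, abundance)), 0)
  first <- vapply(ccs, `[`, "", 1L)
  ord <- order(-tot, first)
  ccs <- ccs[ord]
  tot <- tot[ord]
  genus <- vapply(ccs, extrapolate_genus, "", taxonomy = taxonomy)
  ordlab <- vapply(ccs, cc_order_label, "", taxonomy = taxonomy)
  ids <- paste0("CC_", genus, "_", seq_along(ccs))
  names(ccs) <- ids
  list(members = ccs,
       summary = data.frame(cc_id = ids, size = lengths(ccs),
                            genus_label = unname(genus),
                            order_label = unname(ordlab),
                            total_abundance = unname(tot),
                            row.names = NULL, stringsAsFactors = FALSE))
}
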