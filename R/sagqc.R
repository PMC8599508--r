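PROTEIN_CATEGORIES <- c("prokaryotic_viral_only", "other", "no_hit")

#' Flag putatively contaminant contigs
#'
#' A contig is flagged as putative prokaryotic/viral contamination when at
#' least 60% (inclusive) of its predicted proteins hit only prokaryotic or
#' viral references. All predicted proteins - including those with no hit -
#' count in the denominator. Contigs with zero proteins are reported
#' unflagged with a note.
#'
#' @param assignments data.frame with columns `contig_id`, `protein_id`,
#'   `category` (one of `prokaryotic_viral_only`, `other`, `no_hit`).
#' @param contigs Optional character vector of all contig ids (so
#'   protein-less contigs appear in the report).
#' @param threshold Flagging threshold (default 0.60, inclusive).
#' @return data.frame with columns `contig_id`, `n_proteins`,
#'   `n_prok_viral_only`, `fraction`, `flagged`, `note`.
#' @export
flag_contaminant_contigs <- function(assignments, contigs = NULL,
                                     threshold = 0.60) {
  stopifnot(is.data.frame(assignments))
  req <- c("contig_id", "protein_id", "category")
  if (!all(req %in% names(assignments))) {
    stop("assignments must have columns: ", paste(req, collapse = ", "))
  }
  bad <- !(assignments$category %in% PROTEIN_CATEGORIES)
  if (any(bad)) {
    stop("malformed category '", assignments$category[bad][1L],
         "' (expected one of ", paste(PROTEIN_CATEGORIES, collapse = ", "), ")")
  }
  ids <- unique(c(as.character(assignments$contig_id), contigs))
  n_prot <- as.integer(table(factor(assignments$contig_id, levels = ids)))
  prok <- assignments$contig_id[assignments$category == "prokaryotic_viral_only"]
  n_prok <- as.integer(table(factor(prok, levels = ids)))
  frac <- ifelse(n_prot > 0L, n_prok / n_prot, 0)
  data.frame(
    contig_id = ids,
    n_proteins = n_prot,
    n_prok_viral_only = n_prok,
    fraction = frac,
    flagged = n_prot > 0L & frac >= threshold,
    note = ifelse(n_prot == 0L, "zero_proteins", ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cluster ribotypes for co-assembly
#'
#' Single-linkage connected components over pairs whose percent identity is
#' strictly greater than the threshold ("above 99%"): any chain of
#' above-threshold links joins cells into one co-assembly group. Input pairs
#' are symmetrised; self-pairs are ignored; cells appearing only in
#' below-threshold pairs come back as singletons.
#'
#' @param identities data.frame with columns `a`, `b`, `percent_identity`
#'   (0-100).
#' @param threshold Percent identity threshold (default 99.0, strict `>`).
#' @param inclusive If `TRUE`, use `>=` instead (default `FALSE`).
#' @return List of character vectors (each sorted), ordered by smallest
#'   member id.
#' @export
cluster_ribotypes <- function(identities, threshold = 99.0,
                              inclusive = FALSE) {
  stopifnot(is.data.frame(identities))
  req <- c("a", "b", "percent_identity")
  if (!all(req %in% names(identities))) {
    stop("identities must have columns: ", paste(req, collapse = ", "))
  }
  pid <- as.numeric(identities$percent_identity)
  if (any(pid < 0 | pid > 100, na.rm = TRUE)) {
    stop("percent_identity outside [0, 100]")
  }
  ids <- sort(unique(c(as.character(identities$a), as.character(identities$b))))
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  link <- if (inclusive) pid >= threshold else pid > threshold
  keep <- link & as.character(identities$a) != as.character(identities$b)
  for (r in which(keep)) {
    i <- find(match(as.character(identities$a[r]), ids))
    j <- find(match(as.character(identities$b[r]), ids))
    if (i != j) parent[[max(i, j)]] <- min(i, j)
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  clusters <- unname(split(ids, roots))
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[[`, character(1L), 1L))]
}

#' Construct a marker presence/absence matrix
#' @param mat Logical matrix, markers in rows, assemblies in columns, with
#'   dimnames.
#' @param marker_set Name of the marker set (e.g. `"BUSCO-255"`,
#'   `"phylo-317"`).
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(mat, marker_set = "markers") {
  stopifnot(is.matrix(mat), is.logical(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("presence matrix needs marker row names and assembly column names")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate marker ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate assembly ids")
  structure(list(mat = mat, marker_set = marker_set),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix '%s': %d markers x %d assemblies (%.1f%% filled)\n",
              x$marker_set, nrow(x$mat), ncol(x$mat), 100 * mean(x$mat)))
  invisible(x)
}

#' Marker completeness summary
#'
#' Per-assembly completeness is the fraction of markers present; union
#' (meta-assembly) completeness is the fraction present in at least one
#' assembly - for fragmentary single-cell assemblies the union is typically
#' far more complete than any individual one. Assemblies with strictly
#' fewer than `min_markers_keep` markers are listed for exclusion.
#'
#' @param presence A [presence_matrix] (or logical matrix).
#' @param min_markers_keep Minimum marker count to keep an assembly
#'   (default 5).
#' @return List with `per_assembly` (named fractions), `union_completeness`,
#'   `n_markers`, `excluded` (assembly ids with < `min_markers_keep`
#'   markers); class `completeness_report`.
#' @export
completeness_summary <- function(presence, min_markers_keep = 5L) {
  mat <- if (inherits(presence, "presence_matrix")) presence$mat else presence
  stopifnot(is.matrix(mat), is.logical(mat))
  if (length(mat) == 0L) stop("empty presence matrix")
  per <- colMeans(mat)
  n_present <- colSums(mat)
  structure(
    list(per_assembly = per,
         union_completeness = mean(rowSums(mat) > 0L),
         n_markers = nrow(mat),
         min_markers_keep = as.integer(min_markers_keep),
         excluded = colnames(mat)[n_present < min_markers_keep]),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("completeness over %d markers: union %.1f%%\n",
              x$n_markers, 100 * x$union_completeness))
  for (a in names(x$per_assembly)) {
    cat(sprintf("  %-20s %5.1f%%%s\n", a, 100 * x$per_assembly[[a]],
                if (a %in% x$excluded) "  [excluded: < min markers]" else ""))
  }
  invisible(x)
}
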