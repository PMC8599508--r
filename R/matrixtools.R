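AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHARS <- c("-", "X")

#' Construct a gene alignment
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector: taxon -> aligned amino-acid string.
#'   Rows must have equal length; the alphabet is the 20 amino acids plus
#'   `-` (gap) and `X` (unknown residue, treated as non-gap missing data by
#'   occupancy rules and as missing by composition/rate rules).
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate taxa in alignment '", gene_id, "': ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment '", gene_id, "' rows have unequal lengths")
  }
  bad <- grepl(sprintf("[^%s-]", paste(c(AA_STATES, "X"), collapse = "")), seqs)
  if (any(bad)) {
    stop("alignment '", gene_id, "' row '", names(seqs)[bad][1L],
         "' contains characters outside the amino-acid alphabet")
  }
  structure(list(gene_id = gene_id, seqs = seqs, width = widths[[1L]]),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment '%s': %d taxa x %d sites\n",
              x$gene_id, length(x$seqs), x$width))
  invisible(x)
}

#' Read one aligned FASTA file as a gene alignment
#' @param path FASTA path.
#' @param gene_id Defaults to the filename stem.
#' @return A [gene_alignment].
#' @export
read_gene_alignment <- function(path, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gene_alignment(gene_id, seqs)
}

#' Write an alignment (or supermatrix rows) as FASTA
#' @param x A `gene_alignment`, `supermatrix`, or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- if (inherits(x, "gene_alignment") || inherits(x, "supermatrix")) {
    x$seqs
  } else {
    x
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con, sep = "\n")
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

## Character matrix view (taxa x sites) of alignment rows.
seq_char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

char_matrix_to_seqs <- function(m) {
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

n_missing <- function(s) {
  nchar(s) - nchar(gsub("[-X]", "", s))
}

#' Merge taxa into OTUs to reduce missing data
#'
#' Per gene, each OTU is represented by the member row with the fewest
#' missing characters (gaps plus `X`), ties broken by member order; an OTU is
#' absent from a gene only when all its members are. Merging closely related
#' taxa this way increases per-taxon gene occupancy in sparse single-cell
#' datasets.
#'
#' @param genes List of [gene_alignment] objects.
#' @param otus Named list: `otu_id -> character vector of member taxon ids`.
#' @return List of [gene_alignment] objects with members replaced by OTUs
#'   (non-member taxa keep their original order; OTUs are appended in
#'   `otus` order).
#' @export
merge_otus <- function(genes, otus) {
  stopifnot(is.list(otus), !is.null(names(otus)))
  members <- unlist(otus, use.names = FALSE)
  all_taxa <- unique(unlist(lapply(genes, function(g) names(g$seqs))))
  clash <- intersect(names(otus), setdiff(all_taxa, members))
  if (length(clash) > 0L) {
    stop("otu_id collides with existing taxon_id: ",
         paste(clash, collapse = ", "))
  }
  lapply(genes, function(g) {
    keep <- g$seqs[setdiff(names(g$seqs), members)]
    for (otu in names(otus)) {
      present <- intersect(otus[[otu]], names(g$seqs))
      if (length(present) == 0L) next
      miss <- n_missing(g$seqs[present])
      best <- present[which.min(miss)]  # which.min keeps first on ties
      keep[[otu]] <- g$seqs[[best]]
    }
    gene_alignment(g$gene_id, keep)
  })
}

#' Keep genes with enough focal-species sequences
#'
#' A focal row counts only if it is non-empty (not all gaps/`X`).
#'
#' @param genes List of [gene_alignment] objects.
#' @param map A [taxon_map]; rows whose taxon resolves to a focal record are
#'   counted.
#' @param focal Focal species display name (unused for matching; focality
#'   comes from the map).
#' @param min_seqs Minimum number of non-empty focal rows (default 2).
#' @return The filtered list, order preserved.
#' @export
filter_genes_by_focal_count <- function(genes, map, focal = NULL,
                                        min_seqs = 2L) {
  stopifnot(min_seqs >= 0)
  keep <- vapply(genes, function(g) {
    ann <- resolve_leaf(map, names(g$seqs), strict = FALSE)
    rows <- g$seqs[ann$focal]
    sum(nchar(rows) - n_missing(rows) > 0L) >= min_seqs
  }, logical(1L))
  genes[keep]
}

#' Concatenate gene alignments into a supermatrix
#'
#' @param genes List of [gene_alignment] objects (order fixes partition
#'   order).
#' @param taxa Optional ordered taxon vector; defaults to the union of gene
#'   taxa in order of first appearance. Taxa absent from a gene get all-gap
#'   blocks.
#' @return An object of class `supermatrix`: `seqs` (named character
#'   vector) and `partitions` (data.frame `gene_id`, `start`, `end`,
#'   1-based inclusive).
#' @export
concatenate_genes <- function(genes, taxa = NULL) {
  if (length(genes) == 0L) stop("cannot concatenate an empty gene list")
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(genes, function(g) names(g$seqs))))
  }
  widths <- vapply(genes, function(g) g$width, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blocks <- lapply(genes, function(g) {
    gap <- strrep("-", g$width)
    out <- g$seqs[match(taxa, names(g$seqs))]
    out[is.na(out)] <- gap
    unname(out)
  })
  seqs <- stats::setNames(do.call(paste0, blocks), taxa)
  new_supermatrix(seqs, data.frame(gene_id = ids, start = starts, end = ends,
                                   stringsAsFactors = FALSE))
}

new_supermatrix <- function(seqs, partitions) {
  structure(list(seqs = seqs, partitions = partitions,
                 width = nchar(seqs[[1L]])),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d sites, %d partitions\n",
              length(x$seqs), x$width, nrow(x$partitions)))
  invisible(x)
}

#' Slice one gene back out of a supermatrix
#' @param matrix A `supermatrix`.
#' @param gene_id Partition to extract.
#' @param drop_empty Drop all-gap rows (taxa absent from the gene)?
#'   Default `TRUE`.
#' @return A [gene_alignment].
#' @export
slice_partition <- function(matrix, gene_id, drop_empty = TRUE) {
  p <- matrix$partitions[matrix$partitions$gene_id == gene_id, , drop = FALSE]
  if (nrow(p) != 1L) stop("no such partition: ", gene_id)
  seqs <- substr(matrix$seqs, p$start, p$end)
  if (drop_empty) seqs <- seqs[gsub("-", "", seqs) != ""]
  gene_alignment(gene_id, seqs)
}

#' Write a RAxML-style partition file
#' @param matrix A `supermatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partitions <- function(matrix, path) {
  lines <- sprintf("PROT, %s = %d-%d", matrix$partitions$gene_id,
                   matrix$partitions$start, matrix$partitions$end)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-site rate table
#'
#' Whitespace-delimited, `#`-comment lines skipped, columns `site` and
#' `rate` (header optional if the two columns are in that order).
#'
#' @param path Rate-table path.
#' @param n_sites Optional expected number of sites (validated).
#' @return Numeric vector of rates ordered by site index.
#' @export
read_site_rates <- function(path, n_sites = NULL) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("site", "rate") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, comment.char = "#")
    names(df)[1:2] <- c("site", "rate")
  }
  df <- df[order(df$site), , drop = FALSE]
  if (!is.null(n_sites) && nrow(df) != n_sites) {
    stop("rate table has ", nrow(df), " sites, expected ", n_sites)
  }
  if (any(df$rate < 0)) stop("site rates must be non-negative")
  df$rate
}

## residue -> bitmask over the 20 amino acids; gap/X -> 0 (missing).
aa_bitmask <- function() {
  stats::setNames(bitwShiftL(1L, seq_along(AA_STATES) - 1L), AA_STATES)
}

#' Parsimony step counts per site (a built-in rate proxy)
#'
#' Counts, for every supermatrix column, the minimum number of state changes
#' on a fixed guide topology (Fitch parsimony, computed with Hartigan's
#' counting rule so multifurcations - including the basal trifurcation of an
#' unrooted tree - are scored exactly). Gap and `X` cells are excluded from
#' the state sets; columns with fewer than two observed residues score 0.
#' Useful as a deterministic stand-in when externally inferred per-site
#' rates are not available.
#'
#' @param matrix A `supermatrix`.
#' @param guide_tree A `gene_tree` whose leaves are a subset of the matrix
#'   taxa.
#' @param strict Error on guide-tree taxa missing from the matrix (default
#'   `TRUE`; otherwise they are dropped from the tree-side computation).
#' @return Numeric vector of per-site step counts (class `site_rates`).
#' @export
fitch_site_rates <- function(matrix, guide_tree, strict = TRUE) {
  stopifnot(inherits(matrix, "supermatrix"), inherits(guide_tree, "gene_tree"))
  missing_taxa <- setdiff(guide_tree$labels, names(matrix$seqs))
  if (length(missing_taxa) > 0L) {
    if (strict) {
      stop("guide tree taxa absent from matrix: ",
           paste(missing_taxa, collapse = ", "))
    }
  }
  present <- intersect(guide_tree$labels, names(matrix$seqs))
  m <- seq_char_matrix(matrix$seqs[present])
  mask_map <- aa_bitmask()
  L <- ncol(m)
  ph <- ape::reorder.phylo(guide_tree$phylo, "postorder")
  ntip <- length(ph$tip.label)
  nnode <- ph$Nnode
  tip_masks <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) {
    lbl <- ph$tip.label[t]
    if (lbl %in% rownames(m)) {
      mk <- mask_map[m[lbl, ]]
      mk[is.na(mk)] <- 0L
      tip_masks[[t]] <- unname(mk)
    } else {
      tip_masks[[t]] <- integer(L)
    }
  }
  steps <- numeric(L)
  e <- ph$edge
  children <- split(e[, 2L], e[, 1L])
  ## postorder over internal nodes: parents appear after all their children
  node_order <- unique(e[, 1L])
  for (v in node_order) {
    ch <- children[[as.character(v)]]
    masks <- tip_masks[ch]
    nonzero <- lapply(masks, function(mk) mk != 0L)
    nchild <- Reduce(`+`, lapply(nonzero, as.integer))
    counts <- matrix(0L, nrow = length(AA_STATES), ncol = L)
    for (s in seq_along(AA_STATES)) {
      bit <- bitwShiftL(1L, s - 1L)
      for (mk in masks) {
        counts[s, ] <- counts[s, ] + as.integer(bitwAnd(mk, bit) != 0L)
      }
    }
    maxc <- apply(counts, 2L, max)
    node_mask <- integer(L)
    for (s in seq_along(AA_STATES)) {
      bit <- bitwShiftL(1L, s - 1L)
      hit <- counts[s, ] == maxc & maxc > 0L
      node_mask[hit] <- bitwOr(node_mask[hit], bit)
    }
    add <- nchild - maxc
    add[maxc == 0L] <- 0L
    ## children with no data contribute nothing; a single informative child
    ## passes its mask up at zero cost (nchild - maxc == 0 there)
    steps <- steps + add
    tip_masks[[v]] <- node_mask
  }
  structure(steps, class = "site_rates")
}

## Subset a supermatrix to the given (sorted ascending) site indices,
## re-spanning partitions; zero-length partitions are dropped.
subset_sites <- function(matrix, keep) {
  keep <- sort(keep)
  m <- seq_char_matrix(matrix$seqs)
  seqs <- char_matrix_to_seqs(m[, keep, drop = FALSE])
  p <- matrix$partitions
  counts <- vapply(seq_len(nrow(p)), function(i) {
    sum(keep >= p$start[i] & keep <= p$end[i])
  }, integer(1L))
  nz <- counts > 0L
  ends <- cumsum(counts[nz])
  newp <- data.frame(gene_id = p$gene_id[nz],
                     start = ends - counts[nz] + 1L, end = ends,
                     stringsAsFactors = FALSE)
  new_supermatrix(seqs, newp)
}

#' Iteratively remove the fastest-evolving sites
#'
#' Sites are ranked by rate (descending, ties by site index ascending); the
#' k-th output matrix removes the top `k * step` sites, for
#' `k = 1 .. floor(max_removed / step)`. With the defaults (5000-site steps
#' up to 55,000 removed) a matrix longer than 55,000 sites yields 11 nested
#' alignments for robustness analysis.
#'
#' @param matrix A `supermatrix`.
#' @param rates Per-site rates, length equal to the matrix width.
#' @param step Sites removed per iteration (default 5000).
#' @param max_removed Total sites removed at the last iteration
#'   (default 55000); must be smaller than the matrix width.
#' @return List of `supermatrix` objects, most to least complete.
#' @export
remove_fastest_sites <- function(matrix, rates, step = 5000L,
                                 max_removed = 55000L) {
  stopifnot(inherits(matrix, "supermatrix"))
  rates <- as.numeric(rates)
  if (length(rates) != matrix$width) {
    stop("rates length (", length(rates), ") != matrix width (",
         matrix$width, ")")
  }
  if (step < 1L) stop("step must be >= 1")
  if (max_removed < step) stop("max_removed must be >= step")
  if (max_removed >= matrix$width) {
    stop("max_removed (", max_removed, ") would empty the ", matrix$width,
         "-site matrix")
  }
  ord <- order(-rates, seq_along(rates))
  k_max <- floor(max_removed / step)
  lapply(seq_len(k_max), function(k) {
    removed <- ord[seq_len(k * step)]
    subset_sites(matrix, setdiff(seq_len(matrix$width), removed))
  })
}

## Total compositional chi-squared heterogeneity of a count matrix
## (taxa x states): sum over cells of (observed - expected)^2 / expected
## with expected = row total x global state frequency; empty-expectation
## terms contribute 0.
comp_chi2_total <- function(counts) {
  n_t <- rowSums(counts)
  C_s <- colSums(counts)
  N <- sum(counts)
  if (N == 0) stop("matrix has no observed residues")
  f <- C_s / N
  E <- outer(n_t, f)
  ok <- E > 0
  sum((counts[ok] - E[ok])^2 / E[ok])
}

site_state_counts <- function(m) {
  t(vapply(seq_len(nrow(m)), function(i) {
    tabulate(match(m[i, ], AA_STATES), nbins = length(AA_STATES))
  }, integer(length(AA_STATES))))
}

#' Per-site compositional heterogeneity scores
#'
#' The total compositional chi-squared statistic X2 sums, over taxa and
#' amino-acid states, the squared deviation of each taxon's residue counts
#' from the expectation under matrix-wide state frequencies (gaps and `X`
#' excluded). The score of a site is the reduction of X2 when that site is
#' removed: `score(i) = X2(full) - X2(without i)`. High-scoring sites are
#' the ones driving compositional heterogeneity across taxa.
#'
#' @param matrix A `supermatrix` (or [gene_alignment]) with >= 2 taxa and
#'   >= 2 sites.
#' @return Numeric vector of per-site scores.
#' @export
chi2_site_scores <- function(matrix) {
  seqs <- matrix$seqs
  if (length(seqs) < 2L) stop("need >= 2 taxa")
  m <- seq_char_matrix(seqs)
  L <- ncol(m)
  if (L < 2L) stop("need >= 2 sites")
  counts <- site_state_counts(m)
  rownames(counts) <- rownames(m)
  colnames(counts) <- AA_STATES
  if (sum(counts) == 0) stop("matrix is all gaps")
  x2_full <- comp_chi2_total(counts)
  scores <- numeric(L)
  state_idx <- match(m, AA_STATES)  # column-major over m
  dim(state_idx) <- dim(m)
  for (i in seq_len(L)) {
    ci <- counts
    si <- state_idx[, i]
    obs <- which(!is.na(si))
    for (t in obs) ci[t, si[t]] <- ci[t, si[t]] - 1L
    x2_wo <- if (sum(ci) == 0) 0 else comp_chi2_total(ci)
    scores[i] <- x2_full - x2_wo
  }
  scores
}

#' Trim the most compositionally heterogeneous sites
#'
#' Removes the `ceiling(fraction * width)` highest-scoring sites under
#' [chi2_site_scores()] (ties broken by site index ascending), re-spanning
#' partitions.
#'
#' @param matrix A `supermatrix`.
#' @param fraction Fraction of sites to remove, in (0, 1); the 25% and 50%
#'   levels are the conventional robustness checks.
#' @return A trimmed `supermatrix`.
#' @export
trim_heterogeneous_sites <- function(matrix, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)")
  }
  scores <- chi2_site_scores(matrix)
  n_remove <- ceiling(fraction * matrix$width)
  if (n_remove >= matrix$width) stop("trimming would empty the matrix")
  ord <- order(-scores, seq_along(scores))
  removed <- ord[seq_len(n_remove)]
  subset_sites(matrix, setdiff(seq_len(matrix$width), removed))
}

#' Extract a two-residue signature from an alignment
#'
#' Classifies each taxon by the residues at two alignment columns: `derived`
#' for S+A, `ancestral` for G+S, `other` for any other fully observed pair,
#' `missing` if either position is a gap or `X`. In elongation factor 2 the
#' derived SA pair (replacing ancestral GS) is a rare signature uniting red
#' algae, rhodelphids, Picozoa and some other lineages.
#'
#' @param gene A [gene_alignment].
#' @param positions Integer vector of two 1-based column indices.
#' @param derived,ancestral Two-letter residue pairs defining the classes
#'   (defaults `"SA"` and `"GS"`).
#' @return data.frame with columns `taxon`, `residues`, `state`.
#' @export
ef2_signature <- function(gene, positions, derived = "SA", ancestral = "GS") {
  stopifnot(inherits(gene, "gene_alignment"), length(positions) == 2L)
  if (any(positions < 1L) || any(positions > gene$width)) {
    stop("positions out of range 1..", gene$width)
  }
  r1 <- substr(gene$seqs, positions[1L], positions[1L])
  r2 <- substr(gene$seqs, positions[2L], positions[2L])
  pair <- paste0(r1, r2)
  state <- ifelse(r1 %in% GAP_CHARS | r2 %in% GAP_CHARS, "missing",
           ifelse(pair == derived, "derived",
           ifelse(pair == ancestral, "ancestral", "other")))
  data.frame(taxon = names(gene$seqs), residues = pair, state = state,
             stringsAsFactors = FALSE, row.names = NULL)
}
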