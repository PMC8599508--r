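#' @keywords internal
"_PACKAGE"

## The six recognised plastid-ancestry groups. Plastid ancestry is defined as
## membership in either plastid_* group (photosynthetic or not: rhodelphid-like
## cryptic plastids count as plastid-bearing).
TAXON_GROUPS <- c(
  "cyanobacteria", "other_bacteria", "plastid_photosynthetic",
  "plastid_nonphotosynthetic", "plastid_lacking", "unknown"
)

PLASTID_GROUPS <- c("plastid_photosynthetic", "plastid_nonphotosynthetic")
PROK_GROUPS <- c("cyanobacteria", "other_bacteria")

#' Construct a taxon map
#'
#' A taxon map assigns every taxon a plastid-ancestry group, a focal flag and
#' (for focal single-cell species) an assembly identifier. It is the semantic
#' ground for all tree sorting: leaves of gene trees are resolved to these
#' records by their `taxon_id` prefix.
#'
#' @param records A data.frame with columns `taxon_id`, `group`, `focal`, and
#'   optionally `assembly_id` and `higher_group` (empty strings allowed).
#' @param leaf_delimiter Single character separating `taxon_id` from a
#'   sequence id in gene-tree leaf labels (default `"@"`).
#' @return An object of class `taxon_map`.
#' @export
taxon_map <- function(records, leaf_delimiter = "@") {
  stopifnot(is.data.frame(records))
  req <- c("taxon_id", "group", "focal")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("taxon map is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.character(leaf_delimiter) || length(leaf_delimiter) != 1L ||
      nchar(leaf_delimiter) != 1L) {
    stop("leaf_delimiter must be a single character")
  }
  records$taxon_id <- as.character(records$taxon_id)
  records$group <- as.character(records$group)
  dup <- records$taxon_id[duplicated(records$taxon_id)]
  if (length(dup) > 0L) {
    stop("duplicate taxon_id in taxon map: ", paste(unique(dup), collapse = ", "))
  }
  bad <- !(records$group %in% TAXON_GROUPS)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown group label '%s' in taxon map row %d (taxon '%s')",
                 records$group[i], i, records$taxon_id[i]))
  }
  if (is.character(records$focal)) {
    records$focal <- tolower(records$focal) %in% c("true", "t", "1", "yes")
  }
  records$focal <- as.logical(records$focal)
  if (anyNA(records$focal)) stop("focal column must be logical (true/false)")
  if (is.null(records$assembly_id)) records$assembly_id <- ""
  if (is.null(records$higher_group)) records$higher_group <- ""
  records$assembly_id <- ifelse(is.na(records$assembly_id), "",
                                as.character(records$assembly_id))
  records$higher_group <- ifelse(is.na(records$higher_group), "",
                                 as.character(records$higher_group))
  rownames(records) <- records$taxon_id
  structure(
    list(records = records[, c("taxon_id", "group", "focal", "assembly_id",
                               "higher_group")],
         leaf_delimiter = leaf_delimiter),
    class = "taxon_map"
  )
}

#' Load a taxon map from TSV
#'
#' The file must have header columns `taxon_id`, `group`, `focal`,
#' `assembly_id`, `higher_group` (the last two may be empty). Lines starting
#' with `#` are skipped. `group` must be one of: `cyanobacteria`,
#' `other_bacteria`, `plastid_photosynthetic`, `plastid_nonphotosynthetic`,
#' `plastid_lacking`, `unknown`.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams taxon_map
#' @return A [taxon_map] object.
#' @export
load_taxon_map <- function(path, leaf_delimiter = "@") {
  if (!file.exists(path)) stop("taxon map file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", fill = TRUE)
  taxon_map(df, leaf_delimiter = leaf_delimiter)
}

#' Write a taxon map to TSV
#' @param map A [taxon_map].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_taxon_map <- function(map, path) {
  stopifnot(inherits(map, "taxon_map"))
  df <- map$records
  df$focal <- ifelse(df$focal, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @export
print.taxon_map <- function(x, ...) {
  tab <- table(factor(x$records$group, levels = TAXON_GROUPS))
  cat(sprintf("taxon_map: %d taxa (%d focal), leaf delimiter '%s'\n",
              nrow(x$records), sum(x$records$focal), x$leaf_delimiter))
  for (g in names(tab)) if (tab[[g]] > 0) cat(sprintf("  %-26s %d\n", g, tab[[g]]))
  invisible(x)
}

#' Resolve a gene-tree leaf label to its taxon record
#'
#' Leaf labels are either a bare `taxon_id` or
#' `taxon_id<delimiter>sequence_id`; only the prefix before the first
#' delimiter is used, so all sequences of a taxon resolve to the same record.
#'
#' @param map A [taxon_map].
#' @param leaf_label Character leaf label(s).
#' @param strict If `TRUE` (default) an unmapped taxon is an error; if
#'   `FALSE` a record with group `"unknown"` is returned for it.
#' @return A data.frame with one row per leaf label (columns `taxon_id`,
#'   `group`, `focal`, `assembly_id`, `higher_group`).
#' @export
resolve_leaf <- function(map, leaf_label, strict = TRUE) {
  stopifnot(inherits(map, "taxon_map"))
  tid <- leaf_taxon_id(leaf_label, map$leaf_delimiter)
  idx <- match(tid, map$records$taxon_id)
  if (strict && anyNA(idx)) {
    bad <- leaf_label[is.na(idx)][1L]
    stop("leaf '", bad, "' does not resolve to any taxon in the map")
  }
  out <- map$records[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  if (anyNA(idx)) {
    na <- is.na(idx)
    out$taxon_id[na] <- tid[na]
    out$group[na] <- "unknown"
    out$focal[na] <- FALSE
    out$assembly_id[na] <- ""
    out$higher_group[na] <- ""
  }
  rownames(out) <- NULL
  out
}

leaf_taxon_id <- function(leaf_label, delimiter) {
  vapply(strsplit(as.character(leaf_label), delimiter, fixed = TRUE),
         `[[`, character(1L), 1L)
}

#' Does a group label carry plastid ancestry?
#'
#' Plastid ancestry is defined as descent from a plastid-bearing lineage,
#' photosynthetic or not; exactly the groups `plastid_photosynthetic` and
#' `plastid_nonphotosynthetic` qualify.
#'
#' @param group Character vector of group labels.
#' @return Logical vector.
#' @export
is_plastid_group <- function(group) {
  group %in% PLASTID_GROUPS
}

## Number of distinct non-empty assembly ids among focal records; >= 2 means
## the focal species is a multi-assembly (SAG/CO-SAG) species and the
## monophyly-of-assemblies rule applies.
n_focal_assemblies <- function(map) {
  a <- map$records$assembly_id[map$records$focal]
  length(unique(a[nzchar(a)]))
}
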