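#' Configuration for the transfer scan
#'
#' Encodes the tree-sorting rules: a eukaryote clade containing the focal
#' taxon may carry at most `contamination_max` (default 10%, inclusive)
#' sequences from groups with no plastid ancestry; the sister clade must be
#' at least `min_cyano` (default 2) pure cyanobacterial sequences for EGT,
#' or at least `min_bacteria` pure non-cyanobacterial bacteria for HGT; for
#' multi-assembly focal species (single-cell SAG/CO-SAG data) the focal
#' sequences must span at least `min_focal_assemblies` distinct assemblies
#' and be monophyletic.
#'
#' @param contamination_max Maximum tolerated fraction of non-focal,
#'   non-plastid-ancestry sequences on the eukaryote side (default 0.10).
#' @param min_cyano Minimum size of a pure cyanobacterial donor clade
#'   (default 2).
#' @param min_focal_assemblies Minimum number of distinct focal assemblies
#'   that must group together, applied only to multi-assembly focal species
#'   (default 2).
#' @param min_bacteria Minimum size of a pure bacterial donor clade for the
#'   HGT rule (default 2, for symmetry with the EGT rule).
#' @param min_other_plastid Minimum number of non-focal plastid-ancestry
#'   sequences on the eukaryote side of an EGT (default 1).
#' @param higher_group Optional label: sequences whose taxon record carries
#'   this `higher_group` are allowed on the focal side of an HGT without
#'   counting as contamination (the "larger taxonomic group" rule).
#' @param contamination_inclusive If `TRUE` (default) the threshold is
#'   `<= contamination_max` ("up to 10%" read inclusively), else strict `<`.
#' @param donor_pure If `TRUE` (default) the donor clade must consist
#'   exclusively of the donor group.
#' @param multi_assembly `NULL` (default) to auto-detect from the taxon map
#'   (>= 2 distinct assembly ids among focal records), or a logical override.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(contamination_max = 0.10,
                        min_cyano = 2L,
                        min_focal_assemblies = 2L,
                        min_bacteria = 2L,
                        min_other_plastid = 1L,
                        higher_group = NULL,
                        contamination_inclusive = TRUE,
                        donor_pure = TRUE,
                        multi_assembly = NULL) {
  if (contamination_max < 0 || contamination_max > 1) {
    stop("contamination_max must be in [0, 1]")
  }
  for (nm in c("min_cyano", "min_focal_assemblies", "min_bacteria",
               "min_other_plastid")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      stop(nm, " must be an integer >= 1")
    }
  }
  structure(
    list(contamination_max = contamination_max,
         min_cyano = as.integer(min_cyano),
         min_focal_assemblies = as.integer(min_focal_assemblies),
         min_bacteria = as.integer(min_bacteria),
         min_other_plastid = as.integer(min_other_plastid),
         higher_group = higher_group,
         contamination_inclusive = isTRUE(contamination_inclusive),
         donor_pure = isTRUE(donor_pure),
         multi_assembly = multi_assembly),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config:\n")
  cat(sprintf("  contamination_max      %.3f (%s)\n", x$contamination_max,
              if (x$contamination_inclusive) "inclusive" else "exclusive"))
  cat(sprintf("  min_cyano              %d\n", x$min_cyano))
  cat(sprintf("  min_bacteria           %d\n", x$min_bacteria))
  cat(sprintf("  min_other_plastid      %d\n", x$min_other_plastid))
  cat(sprintf("  min_focal_assemblies   %d\n", x$min_focal_assemblies))
  cat(sprintf("  higher_group           %s\n",
              if (is.null(x$higher_group)) "<none>" else x$higher_group))
  invisible(x)
}

## Resolve all leaves of a tree once; returns the resolve_leaf data.frame
## with an extra `label` column.
annotate_leaves <- function(tree, map, strict = TRUE) {
  ann <- resolve_leaf(map, tree$labels, strict = strict)
  ann$label <- tree$labels
  ann
}

#' Is a gene cluster eligible for the EGT scan?
#'
#' A cluster qualifies if it contains at least one sequence of the focal
#' species, at least one cyanobacterial sequence, and at least one
#' photosynthetic plastid-bearing (archaeplastid-like) sequence.
#'
#' @param leaves Character vector of leaf labels (or taxon ids).
#' @param map A [taxon_map].
#' @param focal Display name of the focal species (focality itself comes from
#'   the map's `focal` flags).
#' @return `TRUE` or `FALSE`.
#' @export
cluster_eligible_egt <- function(leaves, map, focal = NULL) {
  ann <- resolve_leaf(map, leaves, strict = FALSE)
  any(ann$focal) &&
    any(ann$group == "cyanobacteria") &&
    any(ann$group == "plastid_photosynthetic" & !ann$focal)
}

#' Is a gene cluster eligible for the HGT scan?
#'
#' A cluster qualifies if it contains at least one focal sequence and at
#' least one non-cyanobacterial bacterial sequence.
#'
#' @inheritParams cluster_eligible_egt
#' @return `TRUE` or `FALSE`.
#' @export
cluster_eligible_hgt <- function(leaves, map, focal = NULL) {
  ann <- resolve_leaf(map, leaves, strict = FALSE)
  any(ann$focal) && any(ann$group == "other_bacteria" & !ann$focal)
}

## Reject-reason stages, in increasing order of "how far the check got".
EGT_STAGES <- c(no_focal = 1L, cyano_impure = 2L, cyano_too_small = 3L,
                no_other_plastid = 4L, assemblies = 5L,
                not_monophyletic = 6L, contamination = 7L)
HGT_STAGES <- c(no_focal = 1L, donor_impure = 2L, donor_too_small = 3L,
                contamination = 4L)

contamination_ok <- function(frac, cfg) {
  if (cfg$contamination_inclusive) frac <= cfg$contamination_max + 1e-12
  else frac < cfg$contamination_max - 1e-12
}

## Evaluate one orientation (euk side E, donor side D) under the EGT rule.
## clade_keys: environment of canonical clade keys for the monophyly check.
eval_egt_orientation <- function(E, D, ann, cfg, multi, clade_keys) {
  annE <- ann[match(E, ann$label), , drop = FALSE]
  annD <- ann[match(D, ann$label), , drop = FALSE]
  if (!any(annE$focal)) return(list(ok = FALSE, reason = "no_focal"))
  if (any(annD$group != "cyanobacteria") && cfg$donor_pure) {
    return(list(ok = FALSE, reason = "cyano_impure"))
  }
  if (sum(annD$group == "cyanobacteria") < cfg$min_cyano) {
    return(list(ok = FALSE, reason = "cyano_too_small"))
  }
  n_other_plastid <- sum(!annE$focal & is_plastid_group(annE$group))
  if (n_other_plastid < cfg$min_other_plastid) {
    return(list(ok = FALSE, reason = "no_other_plastid"))
  }
  foc <- annE[annE$focal, , drop = FALSE]
  assemblies <- unique(foc$assembly_id[nzchar(foc$assembly_id)])
  if (multi) {
    if (length(assemblies) < cfg$min_focal_assemblies) {
      return(list(ok = FALSE, reason = "assemblies"))
    }
    fkey <- paste(sort(foc$label), collapse = ",")
    if (nrow(foc) > 1L && !exists(fkey, envir = clade_keys, inherits = FALSE)) {
      return(list(ok = FALSE, reason = "not_monophyletic"))
    }
  }
  n_contam <- sum(!annE$focal & !is_plastid_group(annE$group))
  frac <- n_contam / nrow(annE)
  if (!contamination_ok(frac, cfg)) {
    return(list(ok = FALSE, reason = "contamination"))
  }
  list(ok = TRUE, reason = "", contamination = frac,
       focal_assemblies = sort(assemblies))
}

eval_hgt_orientation <- function(E, D, ann, cfg) {
  annE <- ann[match(E, ann$label), , drop = FALSE]
  annD <- ann[match(D, ann$label), , drop = FALSE]
  if (!any(annE$focal)) return(list(ok = FALSE, reason = "no_focal"))
  if (any(annD$group != "other_bacteria") && cfg$donor_pure) {
    return(list(ok = FALSE, reason = "donor_impure"))
  }
  if (sum(annD$group == "other_bacteria") < cfg$min_bacteria) {
    return(list(ok = FALSE, reason = "donor_too_small"))
  }
  nonfocal <- annE[!annE$focal, , drop = FALSE]
  allowed <- if (is.null(cfg$higher_group)) {
    rep(FALSE, nrow(nonfocal))
  } else {
    nonfocal$higher_group == cfg$higher_group
  }
  n_contam <- sum(!allowed)
  frac <- n_contam / nrow(annE)
  if (!contamination_ok(frac, cfg)) {
    return(list(ok = FALSE, reason = "contamination"))
  }
  foc <- annE[annE$focal, , drop = FALSE]
  list(ok = TRUE, reason = "", contamination = frac,
       focal_assemblies = sort(unique(foc$assembly_id[nzchar(foc$assembly_id)])))
}

classify_pair_impl <- function(pair, map, focal, cfg, kind, tree = NULL,
                               ann = NULL, clade_keys = NULL, multi = NULL) {
  if (is.null(ann)) {
    labels <- c(pair$side_a, pair$side_b)
    ann <- resolve_leaf(map, labels, strict = FALSE)
    ann$label <- labels
  }
  if (is.null(multi)) {
    multi <- if (is.null(cfg$multi_assembly)) n_focal_assemblies(map) >= 2L
             else isTRUE(cfg$multi_assembly)
  }
  if (is.null(clade_keys) && !is.null(tree) && kind == "EGT") {
    clade_keys <- tree_clade_keys(tree)
  }
  stages <- if (kind == "EGT") EGT_STAGES else HGT_STAGES
  best <- NULL
  best_stage <- 0L
  orientations <- list(list(E = pair$side_a, D = pair$side_b),
                       list(E = pair$side_b, D = pair$side_a))
  for (o in orientations) {
    r <- if (kind == "EGT") {
      eval_egt_orientation(o$E, o$D, ann, cfg, multi, clade_keys)
    } else {
      eval_hgt_orientation(o$E, o$D, ann, cfg)
    }
    if (r$ok) {
      ev <- list(kind = kind, focal_species = focal,
                 focal_assemblies = r$focal_assemblies,
                 euk_side = sort(o$E), donor_side = sort(o$D),
                 contamination = r$contamination)
      class(ev) <- "transfer_event"
      return(ev)
    }
    st <- stages[[r$reason]]
    if (st > best_stage) {
      best_stage <- st
      best <- r$reason
    }
  }
  structure(list(reject_reason = best), class = "transfer_reject")
}

#' Machine-readable reject reason of a classification result
#'
#' @param x Result of [classify_egt_pair()] or [classify_hgt_pair()].
#' @return The reject reason string for a rejected pair, `NA` for an
#'   accepted event.
#' @export
reject_reason <- function(x) {
  if (inherits(x, "transfer_reject")) x$reject_reason else NA_character_
}

#' Was a pair accepted as a transfer event?
#' @param x Result of [classify_egt_pair()] or [classify_hgt_pair()].
#' @return `TRUE` for a `transfer_event`.
#' @export
is_transfer_event <- function(x) inherits(x, "transfer_event")

## Environment of canonical clade keys (tip-label keys) for one tree; a leaf
## set is a clade iff its sorted-label key is present (singletons always).
tree_clade_keys <- function(tree) {
  sets <- directed_leafsets(tree)
  keys <- new.env(parent = emptyenv())
  labels <- tree$labels
  for (nm in ls(sets)) {
    s <- get(nm, envir = sets)
    assign(paste(sort(labels[s]), collapse = ","), TRUE, envir = keys)
  }
  for (l in labels) assign(l, TRUE, envir = keys)
  keys
}

#' Classify a sister pair under the EGT rule
#'
#' One side (the eukaryote side) must contain at least one focal sequence
#' and at least `min_other_plastid` non-focal plastid-ancestry sequences,
#' with contamination (non-focal, non-plastid-ancestry sequences over the
#' side total) within `contamination_max`; for multi-assembly focal species
#' the focal sequences on that side must span `min_focal_assemblies`
#' assemblies and be monophyletic in the tree. The other side must be a pure
#' cyanobacterial clade of at least `min_cyano` sequences.
#'
#' @param pair One element of [sister_pairs()] output (a list with `side_a`
#'   and `side_b` character vectors).
#' @param map A [taxon_map].
#' @param focal Focal species display name.
#' @param cfg A [scan_config].
#' @param tree The `gene_tree` the pair came from; required for the
#'   monophyly check of multi-assembly focal species.
#' @return A `transfer_event` (list with `kind`, `focal_species`,
#'   `focal_assemblies`, `euk_side`, `donor_side`, `contamination`) or a
#'   `transfer_reject` whose [reject_reason()] is one of `no_focal`,
#'   `no_other_plastid`, `contamination`, `cyano_too_small`, `cyano_impure`,
#'   `assemblies`, `not_monophyletic`.
#' @export
classify_egt_pair <- function(pair, map, focal, cfg = scan_config(),
                              tree = NULL) {
  classify_pair_impl(pair, map, focal, cfg, "EGT", tree = tree)
}

#' Classify a sister pair under the HGT rule
#'
#' One side must contain at least one focal sequence; non-focal sequences on
#' it either belong to `cfg$higher_group` (the "larger taxonomic group") or
#' count toward contamination under the same threshold as the EGT rule. The
#' other side must be a pure clade of at least `min_bacteria`
#' non-cyanobacterial bacteria.
#'
#' @inheritParams classify_egt_pair
#' @return A `transfer_event` or a `transfer_reject` whose [reject_reason()]
#'   is one of `no_focal`, `donor_impure`, `donor_too_small`,
#'   `contamination`.
#' @export
classify_hgt_pair <- function(pair, map, focal, cfg = scan_config(),
                              tree = NULL) {
  classify_pair_impl(pair, map, focal, cfg, "HGT", tree = tree)
}

#' @export
print.transfer_event <- function(x, ...) {
  cat(sprintf("%s event for %s: euk side %d leaves (contamination %.3f), donor %d leaves\n",
              x$kind, x$focal_species, length(x$euk_side), x$contamination,
              length(x$donor_side)))
  invisible(x)
}

#' Scan gene trees for EGT / HGT events
#'
#' Per tree, cluster eligibility is checked first (the tree must contain the
#' focal species plus a cyanobacterium and a photosynthetic archaeplastid
#' sequence for EGT, or a non-cyanobacterial bacterium for HGT). Candidate
#' sister pairs are then enumerated in deterministic order and classified;
#' each tree contributes at most one event per mode (the first qualifying
#' configuration is recorded, all qualifying ones are listed in the detail
#' table), matching tree-level counting of putative transfers.
#'
#' @param trees A list of `gene_tree` objects (or a directory / file paths,
#'   passed to [read_gene_trees()]).
#' @param map A [taxon_map].
#' @param focal Focal species display name.
#' @param cfg A [scan_config].
#' @param mode `"egt"`, `"hgt"` or `"both"`.
#' @param strict If `TRUE` (default), a leaf not resolving in the map is an
#'   error; if `FALSE` such leaves get group `"unknown"` (counting as
#'   contamination).
#' @param detail If `TRUE`, also return every qualifying configuration per
#'   tree (not just the first).
#' @return A list with `events` (data.frame: one row per tree with a
#'   detected event; columns `tree_id`, `kind`, `focal_species`,
#'   `assemblies`, `euk_side`, `donor_side`, `contamination`), `summary`
#'   (data.frame `species`, `n_egt`, `n_hgt`, `ratio`), and `details` when
#'   requested.
#' @export
scan_trees <- function(trees, map, focal = "focal", cfg = scan_config(),
                       mode = c("both", "egt", "hgt"), strict = TRUE,
                       detail = FALSE) {
  mode <- match.arg(mode)
  if (is.character(trees)) trees <- read_gene_trees(trees)
  stopifnot(all(vapply(trees, inherits, logical(1L), "gene_tree")))
  modes <- switch(mode, both = c("EGT", "HGT"), egt = "EGT", hgt = "HGT")
  multi <- if (is.null(cfg$multi_assembly)) n_focal_assemblies(map) >= 2L
           else isTRUE(cfg$multi_assembly)
  ev_rows <- list()
  det_rows <- list()
  n_egt <- 0L
  n_hgt <- 0L
  for (tree in trees) {
    ann <- annotate_leaves(tree, map, strict = strict)
    do_egt <- "EGT" %in% modes && cluster_eligible_egt(tree$labels, map)
    do_hgt <- "HGT" %in% modes && cluster_eligible_hgt(tree$labels, map)
    if (!do_egt && !do_hgt) next
    pairs <- sister_pairs(tree)
    clade_keys <- if (do_egt && multi) tree_clade_keys(tree) else NULL
    for (kind in modes) {
      if (kind == "EGT" && !do_egt) next
      if (kind == "HGT" && !do_hgt) next
      found <- NULL
      for (pair in pairs) {
        ev <- classify_pair_impl(pair, map, focal, cfg, kind, ann = ann,
                                 clade_keys = clade_keys, multi = multi)
        if (is_transfer_event(ev)) {
          if (is.null(found)) found <- ev
          if (detail) {
            det_rows[[length(det_rows) + 1L]] <- event_row(tree$tree_id, ev)
          } else {
            break
          }
        }
      }
      if (!is.null(found)) {
        if (kind == "EGT") n_egt <- n_egt + 1L else n_hgt <- n_hgt + 1L
        ev_rows[[length(ev_rows) + 1L]] <- event_row(tree$tree_id, found)
      }
    }
  }
  events <- do.call(rbind, c(list(empty_event_df()), ev_rows))
  summary <- data.frame(
    species = focal,
    n_egt = if ("EGT" %in% modes) n_egt else NA_integer_,
    n_hgt = if ("HGT" %in% modes) n_hgt else NA_integer_,
    stringsAsFactors = FALSE
  )
  summary$ratio <- if ("EGT" %in% modes && "HGT" %in% modes) {
    egt_hgt_ratio(n_egt, n_hgt)
  } else {
    NA_real_
  }
  out <- list(events = events, summary = summary)
  if (detail) {
    out$details <- do.call(rbind, c(list(empty_event_df()), det_rows))
  }
  out
}

event_row <- function(tree_id, ev) {
  data.frame(
    tree_id = tree_id, kind = ev$kind, focal_species = ev$focal_species,
    assemblies = paste(ev$focal_assemblies, collapse = ","),
    euk_side = paste(ev$euk_side, collapse = ","),
    donor_side = paste(ev$donor_side, collapse = ","),
    contamination = ev$contamination,
    stringsAsFactors = FALSE
  )
}

empty_event_df <- function() {
  data.frame(tree_id = character(0L), kind = character(0L),
             focal_species = character(0L), assemblies = character(0L),
             euk_side = character(0L), donor_side = character(0L),
             contamination = numeric(0L), stringsAsFactors = FALSE)
}

#' EGT:HGT ratio
#'
#' The ratio of detected endosymbiotic to horizontal transfers: a value
#' below 1 indicates more HGT than EGT (no plastid footprint above the
#' bacterial-transfer background), above 1 the reverse. Undefined (`NA`)
#' when no HGT events were detected.
#'
#' @param n_egt,n_hgt Non-negative event counts.
#' @return `n_egt / n_hgt`, or `NA_real_` when `n_hgt` is 0.
#' @export
egt_hgt_ratio <- function(n_egt, n_hgt) {
  if (n_egt < 0 || n_hgt < 0) stop("event counts must be non-negative")
  if (n_hgt == 0) return(NA_real_)
  n_egt / n_hgt
}

#' Write scan results to TSV files
#'
#' @param scan Result of [scan_trees()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scan_results <- function(scan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev_path <- file.path(out_dir, "events.tsv")
  sum_path <- file.path(out_dir, "summary.tsv")
  utils::write.table(scan$events, ev_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  s <- scan$summary
  s$ratio <- ifelse(is.na(s$ratio), "NA", format(s$ratio, digits = 6))
  utils::write.table(s, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  paths <- c(events = ev_path, summary = sum_path)
  if (!is.null(scan$details)) {
    det_path <- file.path(out_dir, "events_detail.tsv")
    utils::write.table(scan$details, det_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    paths <- c(paths, details = det_path)
  }
  invisible(paths)
}
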