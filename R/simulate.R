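## Seed-deterministic synthetic data: taxon sets, gene trees with planted
## EGT/HGT events plus a truth table, alignments with rate/composition
## structure, and sparse marker presence matrices. Branch lengths are
## decorative (exponential draws): the transfer detector is purely
## topological, and the simulator is honest about that.

local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulator configuration
#'
#' The default taxon set is a scaled-down mirror of a broad
#' phylogenomic screen: one focal plastid-lacking species split over several
#' single-cell assemblies, cyanobacteria, other bacteria, photosynthetic and
#' non-photosynthetic plastid-bearing eukaryotes, and plastid-lacking
#' eukaryotes.
#'
#' @param seed Integer RNG seed (all outputs are byte-deterministic in it).
#' @param n_focal_assemblies Number of focal single-cell assemblies
#'   (default 4).
#' @param n_cyano,n_other_bact,n_plastid_photo,n_plastid_nonphoto,n_plastid_lacking
#'   Group sizes (defaults 8, 8, 10, 4, 8).
#' @param n_genes Number of gene trees (default 100).
#' @param p_egt,p_hgt,p_background Event-type probabilities, must sum to 1
#'   (defaults 0.2, 0.2, 0.6).
#' @param contamination_level Fraction of non-plastid contaminant sequences
#'   planted on event eukaryote sides (default 0).
#' @param donor_clade_size Size of planted donor clades (default 2).
#' @param assemblies_per_event Distinct focal assemblies grafted
#'   (monophyletically) into each planted event (default 2).
#' @param n_plastid_in_clade Non-focal plastid-bearing sequences on planted
#'   EGT eukaryote sides (default 2).
#' @param leaves_min,leaves_max Range of target tree sizes (defaults 12, 24).
#' @param focal_name Focal species display name (default `"Picozoa"`).
#' @param allow_substandard Permit configs that plant events below the
#'   default scan minima (negative-control mode; default `FALSE`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_focal_assemblies = 4L,
                       n_cyano = 8L, n_other_bact = 8L,
                       n_plastid_photo = 10L, n_plastid_nonphoto = 4L,
                       n_plastid_lacking = 8L,
                       n_genes = 100L,
                       p_egt = 0.2, p_hgt = 0.2, p_background = 0.6,
                       contamination_level = 0,
                       donor_clade_size = 2L,
                       assemblies_per_event = 2L,
                       n_plastid_in_clade = 2L,
                       leaves_min = 12L, leaves_max = 24L,
                       focal_name = "Picozoa",
                       allow_substandard = FALSE) {
  p <- c(p_egt, p_hgt, p_background)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    stop("p_egt, p_hgt, p_background must lie in [0,1] and sum to 1")
  }
  if (contamination_level < 0 || contamination_level >= 0.5) {
    stop("contamination_level must be in [0, 0.5)")
  }
  if (!allow_substandard) {
    if (donor_clade_size < 2L) {
      stop("donor_clade_size < 2 would plant events below the default ",
           "scan minima; set allow_substandard = TRUE if intended")
    }
    if (assemblies_per_event < 2L) {
      stop("assemblies_per_event < 2 would plant events below the default ",
           "scan minima; set allow_substandard = TRUE if intended")
    }
  }
  if (assemblies_per_event > n_focal_assemblies) {
    stop("assemblies_per_event exceeds n_focal_assemblies")
  }
  if (donor_clade_size > min(n_cyano, n_other_bact)) {
    stop("donor_clade_size exceeds a donor group size")
  }
  if (leaves_min < 8L || leaves_max < leaves_min) {
    stop("need leaves_max >= leaves_min >= 8")
  }
  structure(as.list(environment()), class = "sim_config")
}

## ---- internal growing-tree representation ------------------------------
## Nodes are integers; node 1 is the root; par[v] is v's parent (0 for the
## root); label[v] is NA for internal nodes. Every non-root node identifies
## the edge (par[v], v), so "attach to an edge" is "attach at node v".

bt_single <- function(label) {
  list(par = 0L, label = label)
}

bt_star3 <- function(labels) {
  list(par = c(0L, 1L, 1L, 1L), label = c(NA_character_, labels))
}

bt_cherry <- function(sub_a, sub_b) {
  bt_join(sub_a, sub_b)
}

## Join two subtrees under a fresh root (root has exactly 2 children).
bt_join <- function(a, b) {
  na <- length(a$par)
  nb <- length(b$par)
  par <- c(0L, a$par + 1L, b$par + 1L + na)
  par[2L] <- 1L           # a's root
  par[2L + na] <- 1L      # b's root
  list(par = par, label = c(NA_character_, a$label, b$label))
}

## Attach a new leaf onto the edge above node `at` (at != root).
bt_attach_leaf <- function(tree, label, at) {
  n <- length(tree$par)
  v <- n + 1L   # new internal node
  x <- n + 2L   # new leaf
  par <- c(tree$par, tree$par[at], v)
  par[at] <- v
  list(par = par, label = c(tree$label, NA_character_, label))
}

## Replace the leaf `at` by a whole subtree (keeps the rest untouched, so
## grafting a focal subtree this way preserves its monophyly).
bt_replace_leaf <- function(tree, at, sub) {
  if (length(sub$par) == 1L) {
    tree$label[at] <- sub$label
    return(tree)
  }
  n <- length(tree$par)
  off <- n - 1L  # sub node i (i >= 2) -> n + i - 1
  par_sub <- sub$par[-1L]
  tree$par <- c(tree$par, ifelse(par_sub == 1L, at, par_sub + off))
  tree$label <- c(tree$label, sub$label[-1L])
  tree$label[at] <- NA_character_
  tree
}

## Attach a whole subtree onto the edge above node `at`.
bt_attach_subtree <- function(tree, sub, at) {
  n <- length(tree$par)
  v <- n + 1L
  off <- n + 1L
  par <- c(tree$par, tree$par[at], sub$par + off)
  par[at] <- v
  par[off + 1L] <- v  # sub's root under v
  list(par = par, label = c(tree$label, NA_character_, sub$label))
}

## Candidate attachment points: any non-root node whose pendant leaf label
## (if a leaf) passes `ok_label`.
bt_candidates <- function(tree, ok_label) {
  cand <- which(seq_along(tree$par) != 1L)
  keep <- vapply(cand, function(v) {
    lb <- tree$label[v]
    is.na(lb) || ok_label(lb)
  }, logical(1L))
  cand[keep]
}

## Random rooted binary tree over a list of units (labels or subtrees),
## by sequential attachment to uniformly chosen edges.
bt_random <- function(units) {
  units <- units[sample.int(length(units))]
  as_sub <- function(u) if (is.character(u)) bt_single(u) else u
  if (length(units) == 1L) return(as_sub(units[[1L]]))
  tree <- bt_join(as_sub(units[[1L]]), as_sub(units[[2L]]))
  if (length(units) > 2L) {
    for (i in 3L:length(units)) {
      at <- sample(which(seq_along(tree$par) != 1L), 1L)
      u <- units[[i]]
      tree <- if (is.character(u)) bt_attach_leaf(tree, u, at)
              else bt_attach_subtree(tree, u, at)
    }
  }
  tree
}

## Serialise with exponential branch lengths drawn in deterministic
## (child-id ascending, recursive) order.
bt_newick <- function(tree, brlen = TRUE) {
  children <- vector("list", length(tree$par))
  for (v in seq_along(tree$par)[-1L]) {
    p <- tree$par[v]
    children[[p]] <- c(children[[p]], v)
  }
  fmt <- function(v) {
    if (!is.na(tree$label[v])) {
      tree$label[v]
    } else {
      paste0("(", paste(vapply(children[[v]], function(ch) {
        s <- fmt(ch)
        if (brlen) paste0(s, ":", sprintf("%.6f", stats::rexp(1L, rate = 10)))
        else s
      }, character(1L)), collapse = ","), ")")
    }
  }
  paste0(fmt(1L), ";")
}

## ---- dataset generation ------------------------------------------------

sim_taxa_table <- function(cfg) {
  rows <- list()
  add <- function(ids, group, focal = FALSE, assembly = "", higher = "") {
    data.frame(taxon_id = ids, group = group, focal = focal,
               assembly_id = assembly, higher_group = higher,
               stringsAsFactors = FALSE)
  }
  sag <- sprintf("SAG%02d", seq_len(cfg$n_focal_assemblies))
  rows[[1L]] <- add(paste0(cfg$focal_name, "_", sag), "plastid_lacking",
                    focal = TRUE, assembly = sag, higher = cfg$focal_name)
  rows[[2L]] <- add(sprintf("Cyano%02d", seq_len(cfg$n_cyano)), "cyanobacteria")
  rows[[3L]] <- add(sprintf("Bacteria%02d", seq_len(cfg$n_other_bact)),
                    "other_bacteria")
  rows[[4L]] <- add(sprintf("Alga%02d", seq_len(cfg$n_plastid_photo)),
                    "plastid_photosynthetic")
  rows[[5L]] <- add(sprintf("NpPlast%02d", seq_len(cfg$n_plastid_nonphoto)),
                    "plastid_nonphotosynthetic")
  rows[[6L]] <- add(sprintf("Hetero%02d", seq_len(cfg$n_plastid_lacking)),
                    "plastid_lacking")
  do.call(rbind, rows)
}

## Build the constrained background over the given taxon ids (labelled
## taxon@g<g>): prokaryote leaves never attach onto the pendant edge of a
## prokaryote or focal leaf (so no pure-prokaryote clade of size >= 2 can
## form: it would require a prokaryote cherry), and focal leaves never
## attach onto a prokaryote pendant edge. Returns the builder tree.
bg_build <- function(taxa, g, kind_of) {
  lab <- paste0(taxa, "@g", g)
  kind <- kind_of(taxa)
  ord <- sample.int(length(taxa))
  lab <- lab[ord]
  kind <- kind[ord]
  ## initial 3-leaf star: at most one prokaryote, and at least one plain
  ## eukaryote so prokaryote attachments never run out of legal edges
  euk_i <- which(kind == "euk")
  if (length(euk_i) == 0L) {
    stop("cannot build background: no non-focal eukaryote taxa available")
  }
  a <- euk_i[1L]
  b <- setdiff(which(kind != "prok"), a)[1L]
  if (is.na(b)) b <- setdiff(seq_along(lab), a)[1L]
  first3 <- c(a, b, setdiff(seq_along(lab), c(a, b))[1L])
  rest <- setdiff(seq_along(lab), first3)
  tree <- bt_star3(lab[first3])
  leaf_kind <- stats::setNames(kind, lab)
  for (i in rest) {
    ok <- switch(kind[i],
      prok = function(l) leaf_kind[[l]] == "euk",
      focal = function(l) leaf_kind[[l]] != "prok",
      euk = function(l) TRUE)
    cand <- bt_candidates(tree, ok)
    at <- cand[sample.int(length(cand), 1L)]
    tree <- bt_attach_leaf(tree, lab[i], at)
  }
  tree
}

## Sample a background taxon composition of size n from the pools; at least
## 3 eukaryotes, prokaryotes capped at one third.
bg_sample_taxa <- function(n, pools, must = character(0L)) {
  n <- max(n, length(must) + 3L)
  euks <- setdiff(c(pools$photo, pools$nonphoto, pools$lacking), must)
  proks <- setdiff(c(pools$cyano, pools$bact), must)
  out <- must
  n_prok_have <- sum(out %in% c(pools$cyano, pools$bact))
  max_prok <- max(n_prok_have, floor(n / 3))
  while (length(out) < n) {
    allow_prok <- sum(out %in% c(pools$cyano, pools$bact)) < max_prok &&
      length(proks) > 0L
    pool <- if (allow_prok) c(euks, proks) else euks
    if (length(pool) == 0L) break
    pick <- pool[sample.int(length(pool), 1L)]
    out <- c(out, pick)
    euks <- setdiff(euks, pick)
    proks <- setdiff(proks, pick)
  }
  out
}

#' Simulate a gene-tree dataset with planted transfer events
#'
#' For each gene an event type is drawn (`EGT`, `HGT` or background). Event
#' trees graft a eukaryote clade - focal sequences from
#' `assemblies_per_event` assemblies (monophyletic), plus plastid-bearing
#' companions (EGT only), plus plastid-lacking contaminants at
#' `contamination_level` - sister to a pure donor clade (cyanobacteria for
#' EGT, other bacteria for HGT), embedded in a constrained random
#' background. Background trees place focal sequences inside mixed
#' eukaryote surroundings and are constructed so that no pure prokaryote
#' clade of two or more sequences exists anywhere (a prokaryote-prokaryote
#' cherry is never allowed to form), making them certifiably event-free
#' under the default scan minima - false-positive counts on them are exact,
#' not statistical.
#'
#' @param cfg A [sim_config].
#' @param out_dir Optional output directory; when given, writes
#'   `taxa.tsv`, `truth.tsv` and one newick file per tree under `trees/`.
#' @return A list of class `sim_dataset`: `map` (a [taxon_map]), `trees`
#'   (named list of `gene_tree`), `newick` (named character vector),
#'   `truth` (data.frame: `tree_id`, `planted`, `contamination`,
#'   `focal_assemblies_in_clade`, `donor_size`, `euk_side`, `donor_side`),
#'   `taxa` (the annotation data.frame) and `config`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    taxa_df <- sim_taxa_table(cfg)
    map <- taxon_map(taxa_df)
    pools <- list(
      focal = taxa_df$taxon_id[taxa_df$focal],
      cyano = taxa_df$taxon_id[taxa_df$group == "cyanobacteria"],
      bact = taxa_df$taxon_id[taxa_df$group == "other_bacteria"],
      photo = taxa_df$taxon_id[taxa_df$group == "plastid_photosynthetic"],
      nonphoto = taxa_df$taxon_id[taxa_df$group == "plastid_nonphotosynthetic"],
      lacking = setdiff(taxa_df$taxon_id[taxa_df$group == "plastid_lacking"],
                        taxa_df$taxon_id[taxa_df$focal])
    )
    kind_of <- function(taxa) {
      ifelse(taxa %in% c(pools$cyano, pools$bact), "prok",
             ifelse(taxa %in% pools$focal, "focal", "euk"))
    }
    types <- sample(c("EGT", "HGT", "none"), cfg$n_genes, replace = TRUE,
                    prob = c(cfg$p_egt, cfg$p_hgt, cfg$p_background))
    newick <- character(cfg$n_genes)
    truth <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      id <- sprintf("gene%04d", g)
      n_leaves <- sample(cfg$leaves_min:cfg$leaves_max, 1L)
      if (types[g] == "none") {
        n_foc <- sample(1:min(2L, cfg$n_focal_assemblies), 1L)
        must <- c(pools$focal[sample.int(length(pools$focal), n_foc)],
                  pools$cyano[sample.int(length(pools$cyano), 1L)],
                  pools$bact[sample.int(length(pools$bact), 1L)],
                  pools$photo[sample.int(length(pools$photo), 1L)])
        taxa <- bg_sample_taxa(n_leaves, pools, must = must)
        tree <- bg_build(taxa, g, kind_of)
        newick[g] <- bt_newick(tree)
        truth[[g]] <- data.frame(
          tree_id = id, planted = "none", contamination = NA_real_,
          focal_assemblies_in_clade = NA_integer_, donor_size = NA_integer_,
          euk_side = "", donor_side = "", stringsAsFactors = FALSE)
        next
      }
      ## --- planted event tree ---
      k <- cfg$assemblies_per_event
      foc <- pools$focal[sample.int(length(pools$focal), k)]
      if (types[g] == "EGT") {
        comp <- pools$photo[sample.int(length(pools$photo),
                                       cfg$n_plastid_in_clade)]
        donors <- pools$cyano[sample.int(length(pools$cyano),
                                         cfg$donor_clade_size)]
      } else {
        comp <- character(0L)
        donors <- pools$bact[sample.int(length(pools$bact),
                                        cfg$donor_clade_size)]
      }
      n_clean <- k + length(comp)
      m <- round(cfg$contamination_level * n_clean /
                   (1 - cfg$contamination_level))
      m <- min(m, length(pools$lacking))
      contam <- if (m > 0L) pools$lacking[sample.int(length(pools$lacking), m)]
                else character(0L)
      achieved <- m / (n_clean + m)
      ## NB: paste0(character(0), ...) recycles to "" once other args are
      ## longer, so guard the empty case explicitly
      lab <- function(x) {
        if (length(x) == 0L) character(0L) else paste0(x, "@g", g)
      }
      focal_sub <- bt_random(as.list(lab(foc)))
      ## build the eukaryote clade around a placeholder so companions and
      ## contaminants never land inside the focal subtree (its monophyly is
      ## part of the planted event)
      euk_units <- c(list("__FOCAL__"), as.list(lab(c(comp, contam))))
      euk_sub <- bt_random(euk_units)
      euk_sub <- bt_replace_leaf(euk_sub, which(euk_sub$label == "__FOCAL__"),
                                 focal_sub)
      donor_sub <- bt_random(as.list(lab(donors)))
      planted <- bt_join(euk_sub, donor_sub)
      used <- c(foc, comp, contam, donors)
      n_bg <- max(4L, n_leaves - length(used))
      bg_pools <- pools
      bg_pools$focal <- character(0L)  # focal sequences only in the planted clade
      must <- c(setdiff(pools$photo, used)[1L],
                setdiff(pools$lacking, used)[1L])
      must <- must[!is.na(must)]
      if (length(must) == 0L) {
        stop("config sizes insufficient: no eukaryote taxa left for the ",
             "background of tree ", id)
      }
      bg_pools$photo <- setdiff(bg_pools$photo, used)
      bg_pools$nonphoto <- setdiff(bg_pools$nonphoto, used)
      bg_pools$lacking <- setdiff(bg_pools$lacking, used)
      bg_pools$cyano <- setdiff(bg_pools$cyano, used)
      bg_pools$bact <- setdiff(bg_pools$bact, used)
      bg_taxa <- bg_sample_taxa(n_bg, bg_pools, must = must)
      tree <- bg_build(bg_taxa, g, kind_of)
      ## attach the planted clade anywhere except a prokaryote pendant edge
      ok <- function(l) kind_of(sub("@.*$", "", l)) != "prok"
      cand <- bt_candidates(tree, ok)
      at <- cand[sample.int(length(cand), 1L)]
      tree <- bt_attach_subtree(tree, planted, at)
      newick[g] <- bt_newick(tree)
      truth[[g]] <- data.frame(
        tree_id = id, planted = types[g], contamination = achieved,
        focal_assemblies_in_clade = k,
        donor_size = cfg$donor_clade_size,
        euk_side = paste(sort(lab(c(foc, comp, contam))), collapse = ","),
        donor_side = paste(sort(lab(donors)), collapse = ","),
        stringsAsFactors = FALSE)
    }
    names(newick) <- sprintf("gene%04d", seq_len(cfg$n_genes))
    truth <- do.call(rbind, truth)
    trees <- lapply(seq_along(newick), function(i) {
      parse_newick(newick[[i]], tree_id = names(newick)[i])
    })
    names(trees) <- names(newick)
    out <- structure(
      list(map = map, trees = trees, newick = newick, truth = truth,
           taxa = taxa_df, config = cfg),
      class = "sim_dataset")
    if (!is.null(out_dir)) write_sim_dataset(out, out_dir)
    out
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  tab <- table(factor(x$truth$planted, levels = c("EGT", "HGT", "none")))
  cat(sprintf("sim_dataset: %d trees over %d taxa (planted: %d EGT, %d HGT, %d background)\n",
              length(x$trees), nrow(x$taxa), tab[["EGT"]], tab[["HGT"]],
              tab[["none"]]))
  invisible(x)
}

#' Write a simulated dataset to disk
#' @param sim A `sim_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE,
             recursive = TRUE)
  write_taxon_map(sim$map, file.path(out_dir, "taxa.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  for (id in names(sim$newick)) {
    writeLines(sim$newick[[id]], file.path(out_dir, "trees",
                                           paste0(id, ".nwk")))
  }
  invisible(out_dir)
}

## ---- alignment simulation ---------------------------------------------

## A fixed, roughly empirical amino-acid base composition.
SIM_BASE_FREQS <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137, Q = 0.0393,
  E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596, L = 0.0966, K = 0.0584,
  M = 0.0242, F = 0.0386, P = 0.0470, S = 0.0656, T = 0.0534, W = 0.0108,
  Y = 0.0292, V = 0.0687
)

#' Simulate an amino-acid alignment with rate and compositional structure
#'
#' Sites get gamma-distributed rates (mean 1): each taxon copies the site's
#' consensus residue with probability `exp(-rate)` and otherwise draws a
#' fresh residue, so slow sites are conserved and fast sites variable. A
#' designated taxon subset draws, at a designated site subset, from a
#' shifted residue-frequency vector mixed into the base frequencies at
#' `bias_strength` - the planted compositional heterogeneity that
#' chi-squared site trimming is meant to find. No substitution model along a
#' tree is simulated: the generator provides exactly the structure the site
#' filters consume, nothing more.
#'
#' @param n_taxa,n_sites Alignment dimensions.
#' @param gamma_shape Shape of the site-rate distribution (default 1).
#' @param biased_taxa Character vector of taxon names (of the form
#'   `t01, t02, ...`) or an integer count (the first so-many taxa).
#' @param biased_sites Fraction of sites carrying the bias (default 0.1).
#' @param bias_strength Mixing weight of the shifted composition in [0, 1]
#'   (0 = no bias).
#' @param seed RNG seed.
#' @return A [gene_alignment] (`gene_id` `"sim"`), with attributes
#'   `biased_sites` (site indices) and `rates`.
#' @export
simulate_alignment <- function(n_taxa, n_sites, gamma_shape = 1,
                               biased_taxa = 0L, biased_sites = 0.1,
                               bias_strength = 0, seed = 1L) {
  if (biased_sites > 1) stop("biased_sites is a fraction and must be <= 1")
  if (bias_strength < 0 || bias_strength > 1) {
    stop("bias_strength must be in [0, 1]")
  }
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  if (is.numeric(biased_taxa)) biased_taxa <- utils::head(taxa, biased_taxa)
  if (!all(biased_taxa %in% taxa)) stop("biased_taxa outside the taxon set")
  local_seed(seed, {
    rates <- stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
    n_biased <- round(biased_sites * n_sites)
    biased_idx <- if (n_biased > 0L) sort(sample.int(n_sites, n_biased))
                  else integer(0L)
    base <- SIM_BASE_FREQS
    ## the shifted composition concentrates on globally rare residues
    ## (tryptophan/cysteine), the regime where compositional attraction is
    ## detectable per site: a shift onto already-common residues disappears
    ## into multinomial noise
    favoured <- c("W", "C")
    shifted <- stats::setNames(rep(0, length(base)), names(base))
    shifted[favoured] <- 1 / length(favoured)
    mixed <- (1 - bias_strength) * base + bias_strength * shifted
    m <- matrix("", nrow = n_taxa, ncol = n_sites, dimnames = list(taxa, NULL))
    states <- names(base)
    for (i in seq_len(n_sites)) {
      consensus <- sample(states, 1L, prob = base)
      ## substitution probability is rate scaled by 1/2 so the bulk of
      ## sites stay recognisably conserved, as in curated marker alignments
      p_new <- 1 - exp(-rates[i] / 2)
      for (t in seq_len(n_taxa)) {
        biased_here <- (i %in% biased_idx) && (taxa[t] %in% biased_taxa)
        if (biased_here) {
          m[t, i] <- sample(states, 1L, prob = mixed)
        } else if (stats::runif(1L) < p_new) {
          m[t, i] <- sample(states, 1L, prob = base)
        } else {
          m[t, i] <- consensus
        }
      }
    }
    aln <- gene_alignment("sim", char_matrix_to_seqs(m))
    attr(aln, "biased_sites") <- biased_idx
    attr(aln, "rates") <- rates
    aln
  })
}

#' Simulate a sparse marker presence matrix
#'
#' Each assembly's present marker set is drawn uniformly at the requested
#' completeness (exact counts, rounded to nearest).
#'
#' @param n_markers,n_assemblies Matrix dimensions.
#' @param per_assembly_completeness Vector of fractions in [0, 1], recycled
#'   to `n_assemblies`.
#' @param seed RNG seed.
#' @return A [presence_matrix].
#' @export
simulate_presence <- function(n_markers, n_assemblies,
                              per_assembly_completeness, seed = 1L) {
  f <- rep_len(per_assembly_completeness, n_assemblies)
  if (any(f < 0 | f > 1)) stop("completeness fractions must be in [0, 1]")
  local_seed(seed, {
    mat <- matrix(FALSE, nrow = n_markers, ncol = n_assemblies,
                  dimnames = list(sprintf("marker%03d", seq_len(n_markers)),
                                  sprintf("asm%02d", seq_len(n_assemblies))))
    for (j in seq_len(n_assemblies)) {
      k <- round(f[j] * n_markers)
      if (k > 0L) mat[sample.int(n_markers, k), j] <- TRUE
    }
    presence_matrix(mat, marker_set = sprintf("sim-%d", n_markers))
  })
}
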