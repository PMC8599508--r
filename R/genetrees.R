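#' Parse a newick string into an unrooted gene tree
#'
#' Parsing itself is delegated to [ape::read.tree()]; the result is unrooted
#' (a rooted, degree-2 root is suppressed) and degree-2 internal nodes are
#' collapsed, so every internal node of the returned tree has degree >= 3.
#' Branch lengths and internal (support) labels are carried but never
#' interpreted by the tree-sorting rules, which are purely topological.
#'
#' @param text A single newick string (terminating `;` optional).
#' @param tree_id Identifier attached to the tree (default `"tree1"`).
#' @return An object of class `gene_tree` with elements `tree_id`, `phylo`
#'   (the unrooted [ape::phylo] object), `ntip` and `labels`.
#' @export
parse_newick <- function(text, tree_id = "tree1") {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error in tree '", tree_id, "'")
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s) in tree '", tree_id, "': ",
         paste(dup, collapse = ", "))
  }
  tr <- ape::collapse.singles(tr)
  if (ape::Ntip(tr) >= 3L && ape::is.rooted(tr)) tr <- ape::unroot(tr)
  new_gene_tree(tr, tree_id)
}

new_gene_tree <- function(phylo, tree_id) {
  structure(
    list(tree_id = tree_id, phylo = phylo, ntip = ape::Ntip(phylo),
         labels = phylo$tip.label),
    class = "gene_tree"
  )
}

## Positional syntax check so parse errors can name an offset; ape's own
## messages do not.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of string")
  }
  invisible(TRUE)
}

#' Read gene trees from files
#'
#' Each file may hold one newick per line; `tree_id` defaults to the filename
#' stem for single-tree files and `<stem>.<line>` for multi-tree files.
#'
#' @param paths Character vector of newick file paths, or a directory, in
#'   which case all `.nwk`/`.tre`/`.treefile`/`.newick` files in it are read
#'   (sorted by name).
#' @return A named list of `gene_tree` objects.
#' @export
read_gene_trees <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(nwk|tre|treefile|newick)$",
                             full.names = TRUE))
  }
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("cannot read tree file: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("tree file is empty: ", p)
    stem <- sub("\\.[^.]*$", "", basename(p))
    for (i in seq_along(lines)) {
      id <- if (length(lines) == 1L) stem else sprintf("%s.%d", stem, i)
      out[[id]] <- parse_newick(lines[i], tree_id = id)
    }
  }
  out
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree '%s': %d leaves, %d internal nodes\n",
              x$tree_id, x$ntip, x$phylo$Nnode))
  invisible(x)
}

## Adjacency list over all nodes (tips 1..ntip, internals ntip+1..), with
## neighbours sorted ascending for deterministic enumeration.
tree_adjacency <- function(tree) {
  e <- tree$phylo$edge
  n <- tree$ntip + tree$phylo$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1L]]] <- c(adj[[e[i, 1L]]], e[i, 2L])
    adj[[e[i, 2L]]] <- c(adj[[e[i, 2L]]], e[i, 1L])
  }
  lapply(adj, sort)
}

## For every directed edge u->v, the set of tip indices on v's side (away
## from u), as a list keyed "u|v". One postorder pass gives the down-sets;
## up-sets are complements.
directed_leafsets <- function(tree) {
  ph <- ape::reorder.phylo(tree$phylo, "postorder")
  ntip <- tree$ntip
  nnode <- ph$Nnode
  down <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) down[[t]] <- t
  e <- ph$edge
  for (i in seq_len(nrow(e))) {
    down[[e[i, 1L]]] <- c(down[[e[i, 1L]]], down[[e[i, 2L]]])
  }
  down <- lapply(down, sort)
  all_tips <- seq_len(ntip)
  sets <- new.env(parent = emptyenv(), size = 2L * nrow(e))
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    assign(paste0(p, "|", ch), down[[ch]], envir = sets)
    assign(paste0(ch, "|", p), setdiff(all_tips, down[[ch]]), envir = sets)
  }
  sets
}

#' Enumerate candidate sister-subtree pairs of an unrooted tree
#'
#' At every internal node of degree d, every unordered pair of the d adjacent
#' subtrees is a candidate "sister pair": the two clades are joined at that
#' node to the exclusion of the rest of the tree. For a fully binary tree
#' this yields exactly 3(L-2) pairs, and the set equals the union of rooted
#' sister pairs over all possible rootings, so no rooting decision is needed.
#'
#' @param tree A `gene_tree` with >= 4 leaves.
#' @return A list of pairs; each element has `side_a`, `side_b` (character
#'   vectors of leaf labels, sorted) and `anchor` (internal node index).
#'   Order is deterministic: by anchor node index, then neighbour indices.
#' @export
sister_pairs <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  if (tree$ntip < 4L) stop("sister_pairs requires >= 4 leaves")
  adj <- tree_adjacency(tree)
  sets <- directed_leafsets(tree)
  labels <- tree$labels
  internal <- (tree$ntip + 1L):(tree$ntip + tree$phylo$Nnode)
  out <- vector("list", 0L)
  k <- 0L
  for (v in internal) {
    nb <- adj[[v]]
    d <- length(nb)
    if (d < 3L) next
    for (i in seq_len(d - 1L)) {
      sa <- get(paste0(v, "|", nb[i]), envir = sets)
      for (j in (i + 1L):d) {
        sb <- get(paste0(v, "|", nb[j]), envir = sets)
        k <- k + 1L
        out[[k]] <- list(side_a = labels[sa], side_b = labels[sb], anchor = v)
      }
    }
  }
  out
}

#' Is a leaf set a clade of the unrooted tree?
#'
#' A set is a clade iff it equals one side of some bipartition (one tree
#' edge); single leaves count as clades by convention.
#'
#' @param tree A `gene_tree`.
#' @param leafset Character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_clade <- function(tree, leafset) {
  stopifnot(inherits(tree, "gene_tree"))
  leafset <- unique(as.character(leafset))
  if (length(leafset) == 0L) stop("leafset must be non-empty")
  idx <- match(leafset, tree$labels)
  if (anyNA(idx)) {
    stop("leafset contains labels not in the tree: ",
         paste(leafset[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1L) return(TRUE)
  if (length(idx) == tree$ntip) return(FALSE)
  key <- paste(sort(idx), collapse = ",")
  sets <- directed_leafsets(tree)
  for (nm in ls(sets)) {
    if (paste(get(nm, envir = sets), collapse = ",") == key) return(TRUE)
  }
  FALSE
}

## Canonical key for an unordered pair of label sets (used by tests and
## determinism checks).
pair_key <- function(side_a, side_b) {
  a <- paste(sort(side_a), collapse = ",")
  b <- paste(sort(side_b), collapse = ",")
  if (a <= b) paste(a, b, sep = " || ") else paste(b, a, sep = " || ")
}

#' Serialise a gene tree to newick
#' @param tree A `gene_tree`.
#' @return A newick string (with branch lengths if present).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  ape::write.tree(tree$phylo)
}
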