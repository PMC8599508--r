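# Independent oracles, deliberately implemented with different algorithms
# from the package code paths they check.

# Canonical key for an unordered pair of label sets.
o_pair_key <- function(a, b) {
  a <- paste(sort(a), collapse = ",")
  b <- paste(sort(b), collapse = ",")
  if (a <= b) paste(a, b, sep = " || ") else paste(b, a, sep = " || ")
}

pairs_to_keys <- function(pairs) {
  sort(vapply(pairs, function(p) o_pair_key(p$side_a, p$side_b), character(1)))
}

# Exhaustive-rerooting oracle: root the unrooted tree on every edge; in each
# rooting, every internal node's children subtrees give rooted sister pairs;
# the union over rootings (deduplicated) is the reference pair set.
oracle_sister_pairs <- function(phy) {
  e <- phy$edge
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  labels <- phy$tip.label
  adj <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  # tips reachable from `node`, never stepping back through `from`
  tips_beyond <- function(from, node) {
    acc <- integer(0)
    stack <- node
    prev <- from
    seen <- c(from)
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      seen <- c(seen, v)
      if (v <= ntip) acc <- c(acc, v)
      nxt <- setdiff(adj[[v]], seen)
      stack <- c(stack, nxt)
    }
    acc
  }
  keys <- character(0)
  for (k in seq_len(nrow(e))) {
    # rooting on edge k orients every node toward one endpoint
    for (endpoint in e[k, ]) {
      other <- setdiff(e[k, ], endpoint)
      # parent pointers by BFS from `endpoint`, banned from crossing `other`
      parent <- rep(NA_integer_, ntip + nnode)
      parent[endpoint] <- -1L  # virtual root
      queue <- endpoint
      while (length(queue) > 0) {
        v <- queue[[1]]
        queue <- queue[-1]
        for (w in adj[[v]]) {
          if (v == endpoint && w == other) next
          if (is.na(parent[w]) && w != endpoint) {
            parent[w] <- v
            queue <- c(queue, w)
          }
        }
      }
      for (w in which(!is.na(parent))) {
        if (w <= ntip) next
        kids <- setdiff(adj[[w]], parent[w])
        if (w == endpoint) kids <- setdiff(adj[[w]], other)
        if (length(kids) < 2) next
        sets <- lapply(kids, function(kd) labels[tips_beyond(w, kd)])
        for (i in seq_len(length(sets) - 1)) {
          for (j in (i + 1):length(sets)) {
            keys <- c(keys, o_pair_key(sets[[i]], sets[[j]]))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# Full-recomputation chi2 oracle: rebuild the count table from scratch for
# the complete matrix and for each single-site-removed matrix.
oracle_chi2_total <- function(char_mat) {
  states <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
              "S","T","W","Y","V")
  counts <- t(apply(char_mat, 1, function(r) {
    table(factor(r[r %in% states], levels = states))
  }))
  n_t <- rowSums(counts)
  f_s <- colSums(counts) / sum(counts)
  total <- 0
  for (t in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      expct <- n_t[t] * f_s[s]
      if (expct > 0) total <- total + (counts[t, s] - expct)^2 / expct
    }
  }
  total
}

oracle_chi2_scores <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  full <- oracle_chi2_total(m)
  vapply(seq_len(ncol(m)), function(i) {
    sub <- m[, -i, drop = FALSE]
    wo <- if (all(!sub %in% c("A","R","N","D","C","Q","E","G","H","I","L",
                              "K","M","F","P","S","T","W","Y","V"))) 0
          else oracle_chi2_total(sub)
    full - wo
  }, numeric(1))
}

# Brute-force parsimony oracle: minimum changes over all assignments of
# observed states to internal nodes (feasible for tiny trees only).
oracle_parsimony <- function(phy, tip_states) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  obs <- unique(tip_states[!is.na(tip_states)])
  if (length(obs) <= 1) return(0L)
  internal <- (ntip + 1):(ntip + nnode)
  grids <- expand.grid(rep(list(obs), nnode), stringsAsFactors = FALSE)
  e <- phy$edge
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    assign_state <- function(v) {
      if (v <= ntip) tip_states[[phy$tip.label[v]]]
      else grids[r, v - ntip][[1]]
    }
    changes <- 0L
    for (i in seq_len(nrow(e))) {
      s1 <- assign_state(e[i, 1])
      s2 <- assign_state(e[i, 2])
      if (!is.na(s1) && !is.na(s2) && s1 != s2) changes <- changes + 1L
    }
    best <- min(best, changes)
  }
  best
}
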