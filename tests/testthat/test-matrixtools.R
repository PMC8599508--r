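test_that("gene_alignment validates shape and alphabet", {
  g <- gene_alignment("g1", c(A = "KK-R", B = "KRXR"))
  expect_equal(g$width, 4L)
  expect_error(gene_alignment("g1", c(A = "KK", B = "KKR")), "unequal")
  expect_error(gene_alignment("g1", c(A = "K1", B = "KK")), "alphabet")
  expect_error(gene_alignment("g1", c(A = "KK", A = "KK")), "duplicate")
})

test_that("FASTA round-trip via Biostrings", {
  g <- gene_alignment("g1", c(tax1 = "KKARNDCQ", tax2 = "KR-RNDCQ"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, path, width = 5)
  g2 <- read_gene_alignment(path, gene_id = "g1")
  expect_identical(g2$seqs, g$seqs)
})

test_that("merge_otus picks the least-gappy member and preserves occupancy", {
  g1 <- gene_alignment("g1", c(m1 = "KKKK", out = "RRRR"))
  g2 <- gene_alignment("g2", c(m2 = "DDDD", out = "RRRR"))
  merged <- merge_otus(list(g1, g2), list(OTU1 = c("m1", "m2")))
  expect_true(all(vapply(merged, function(g) "OTU1" %in% names(g$seqs),
                         logical(1))))

  # fewest gaps+X wins; ties go to the first-listed member
  g3 <- gene_alignment("g3", c(m1 = "K--K", m2 = "KKK-", out = "RRRR"))
  m3 <- merge_otus(list(g3), list(OTU1 = c("m1", "m2")))[[1]]
  expect_equal(unname(m3$seqs["OTU1"]), "KKK-")
  g4 <- gene_alignment("g4", c(m1 = "K--K", m2 = "KK--", out = "RRRR"))
  m4 <- merge_otus(list(g4), list(OTU1 = c("m1", "m2")))[[1]]
  expect_equal(unname(m4$seqs["OTU1"]), "K--K")

  expect_error(merge_otus(list(g1), list(out = c("m1"))), "collides")

  # occupancy never decreases relative to the best member
  set.seed(31)
  genes <- lapply(1:6, function(i) random_gene(paste0("r", i),
                                               sprintf("t%02d", 1:8), 30))
  otus <- list(OTU_A = c("t01", "t02"), OTU_B = c("t03", "t04", "t05"))
  merged <- merge_otus(genes, otus)
  for (i in seq_along(genes)) {
    for (otu in names(otus)) {
      present <- intersect(otus[[otu]], names(genes[[i]]$seqs))
      best <- min(vapply(genes[[i]]$seqs[present], function(s) {
        nchar(s) - nchar(gsub("[-X]", "", s))
      }, numeric(1)))
      got <- merged[[i]]$seqs[[otu]]
      expect_equal(nchar(got) - nchar(gsub("[-X]", "", got)), best)
    }
  }
})

test_that("filter_genes_by_focal_count counts only non-empty focal rows", {
  map <- fixture_map(sags = 3)
  mk <- function(id, focal_rows) {
    seqs <- c(stats::setNames(rep("KKKK", length(focal_rows)), focal_rows),
              Red1 = "RRRR")
    gene_alignment(id, seqs)
  }
  genes <- list(
    gene_alignment("f0", c(Red1 = "RRRR", Cyano1 = "KKKK")),
    mk("f1", "Picozoa_SAG1"),
    mk("f2", c("Picozoa_SAG1", "Picozoa_SAG2")),
    mk("f3", c("Picozoa_SAG1", "Picozoa_SAG2", "Picozoa_SAG3")))
  kept <- filter_genes_by_focal_count(genes, map, min_seqs = 2)
  expect_equal(vapply(kept, function(g) g$gene_id, character(1)),
               c("f2", "f3"))
  expect_length(filter_genes_by_focal_count(genes, map, min_seqs = 0), 4L)

  # an all-gap focal row does not count
  g_gap <- gene_alignment("gap", c(Picozoa_SAG1 = "----", Picozoa_SAG2 = "KKKK",
                                   Red1 = "RRRR"))
  expect_length(filter_genes_by_focal_count(list(g_gap), map, min_seqs = 2), 0L)
})

test_that("concatenation records partitions and fills missing blocks", {
  taxa <- c("tA", "tB", "tC")
  g1 <- gene_alignment("g1", stats::setNames(strrep(c("K", "R", "D"), 10), taxa))
  g2 <- gene_alignment("g2", stats::setNames(strrep(c("E", "G"), 20),
                                             c("tA", "tC")))
  g3 <- gene_alignment("g3", stats::setNames(strrep(c("H", "I", "L"), 30), taxa))
  sm <- concatenate_genes(list(g1, g2, g3))
  expect_equal(sm$width, 60L)
  expect_equal(sm$partitions$start, c(1L, 11L, 31L))
  expect_equal(sm$partitions$end, c(10L, 30L, 60L))
  expect_equal(substr(sm$seqs[["tB"]], 11, 30), strrep("-", 20))
  expect_error(concatenate_genes(list()), "empty")
  expect_error(concatenate_genes(list(g1, g1)), "duplicate")
})

test_that("concatenate then slice recovers every input gene", {
  set.seed(41)
  taxa <- sprintf("t%02d", 1:6)
  genes <- lapply(1:5, function(i) {
    rows <- sample(taxa, sample(3:6, 1))
    random_gene(paste0("g", i), rows, sample(10:40, 1))
  })
  sm <- concatenate_genes(genes)
  for (g in genes) {
    back <- slice_partition(sm, g$gene_id)
    expect_identical(back$seqs[names(g$seqs)], g$seqs)
  }
})

test_that("fitch_site_rates matches hand cases and the brute-force oracle", {
  tree <- parse_newick("((A,B),(C,D));")
  mk_sm <- function(colsA, colsB, colsC, colsD) {
    g <- gene_alignment("g", c(A = colsA, B = colsB, C = colsC, D = colsD))
    concatenate_genes(list(g))
  }
  sm <- mk_sm("KKKK", "KKRK", "RKK-", "RKR-")
  r <- fitch_site_rates(sm, tree)
  # site 1: one K->R change; site 2: constant; site 3: two changes;
  # site 4: only two observed residues, no change forced
  expect_equal(as.numeric(r), c(1, 0, 2, 0))

  # randomised check against exhaustive internal-state enumeration
  set.seed(51)
  for (rep in 1:10) {
    phy <- ape::rtree(5, tip.label = LETTERS[1:5])
    gt <- parse_newick(ape::write.tree(phy))
    states <- sample(c("K", "R", "D", "-"), 5, replace = TRUE)
    names(states) <- LETTERS[1:5]
    sm1 <- concatenate_genes(list(gene_alignment("g", stats::setNames(
      states, names(states)))))
    got <- as.numeric(fitch_site_rates(sm1, gt))
    tip_states <- ifelse(states == "-", NA, states)
    names(tip_states) <- names(states)
    expect_equal(got, oracle_parsimony(gt$phylo, tip_states))
  }

  expect_error(fitch_site_rates(sm, parse_newick("((A,B),(C,Z));")), "Z")
})

test_that("remove_fastest_sites sorts, nests and re-spans partitions", {
  g <- gene_alignment("g", c(A = "KRD", B = "KRD"))
  sm <- concatenate_genes(list(g))
  out <- remove_fastest_sites(sm, c(3, 1, 2), step = 1, max_removed = 2)
  expect_length(out, 2L)
  expect_equal(unname(out[[1]]$seqs["A"]), "RD")   # drops site 1 (rate 3)
  expect_equal(unname(out[[2]]$seqs["A"]), "R")    # then site 3 (rate 2)

  # 12,000 sites, step 5000, max 10,000 -> lengths 7000 and 2000
  set.seed(61)
  big <- concatenate_genes(list(
    gene_alignment("a", c(A = strrep("K", 6000), B = strrep("R", 6000))),
    gene_alignment("b", c(A = strrep("D", 6000), B = strrep("E", 6000)))))
  rates <- stats::runif(12000)
  stepped <- remove_fastest_sites(big, rates, step = 5000, max_removed = 10000)
  expect_equal(vapply(stepped, function(x) x$width, integer(1)),
               c(7000L, 2000L))

  expect_error(remove_fastest_sites(big, rates, step = 5000,
                                    max_removed = 12000), "empty")
  expect_error(remove_fastest_sites(sm, c(1, 2)), "length")
})

test_that("chi2 scores match the hand-computed 2x2 example and the oracle", {
  sm <- concatenate_genes(list(gene_alignment("g", c(t1 = "AA", t2 = "AC"))))
  scores <- chi2_site_scores(sm)
  expect_equal(scores, c(4 / 3 - 2, 4 / 3), tolerance = 1e-12)

  # identical rows: no heterogeneity anywhere
  same <- concatenate_genes(list(gene_alignment("g", c(t1 = "ARND", t2 = "ARND"))))
  expect_equal(chi2_site_scores(same), rep(0, 4), tolerance = 1e-12)

  # random matrices: incremental equals full recomputation
  set.seed(71)
  for (rep in 1:5) {
    seqs <- random_aa_seqs(sample(4:10, 1), sample(20:60, 1))
    sm_r <- concatenate_genes(list(gene_alignment("r", seqs)))
    expect_equal(chi2_site_scores(sm_r), oracle_chi2_scores(seqs),
                 tolerance = 1e-9)
  }

  # duplicating every column essentially preserves the site ranking; the
  # preservation is not bit-exact because the removal score is nonlinear
  # in the counts (verified against the full-recomputation oracle), so the
  # assertable property is near-perfect rank agreement
  seqs <- random_aa_seqs(5, 30)
  dup <- stats::setNames(vapply(seqs, function(s) {
    paste(rep(strsplit(s, "")[[1]], each = 2), collapse = "")
  }, character(1)), names(seqs))
  s1 <- chi2_site_scores(concatenate_genes(list(gene_alignment("a", seqs))))
  s2 <- chi2_site_scores(concatenate_genes(list(gene_alignment("b", dup))))
  expect_gt(stats::cor(s1, s2[seq(1, 60, by = 2)], method = "spearman"), 0.95)
  expect_gt(stats::cor(s1, s2[seq(2, 60, by = 2)], method = "spearman"), 0.95)
})

test_that("trim_heterogeneous_sites uses the ceiling rule and index ties", {
  g <- gene_alignment("g", c(t1 = "AAAA", t2 = "AAAA"))
  sm <- concatenate_genes(list(g))
  trimmed <- trim_heterogeneous_sites(sm, 0.5)
  expect_equal(trimmed$width, 2L)  # ceil(0.5*4); all-equal scores -> sites 1,2

  expect_equal(ceiling(0.25 * 317), 80)  # the conventional 25% level
  set.seed(81)
  sm317 <- concatenate_genes(list(gene_alignment("g", random_aa_seqs(4, 317))))
  expect_equal(trim_heterogeneous_sites(sm317, 0.25)$width, 317L - 80L)
  expect_error(trim_heterogeneous_sites(sm, 1.2), "fraction")
})

test_that("planted compositional bias is found by the chi2 score", {
  # partial bias (strength 0.8 on 10% of sites): planted sites' median
  # score rank lands in the top 15%
  aln <- simulate_alignment(20, 200, biased_taxa = 5, biased_sites = 0.1,
                            bias_strength = 0.8, seed = 91)
  scores <- chi2_site_scores(concatenate_genes(list(aln)))
  planted <- attr(aln, "biased_sites")
  expect_lte(stats::median(rank(-scores)[planted]), 0.15 * 200)

  # fully confined bias: the top planted-fraction slice recovers >= 90%
  # of the planted sites
  aln2 <- simulate_alignment(20, 200, biased_taxa = 5, biased_sites = 0.1,
                             bias_strength = 1.0, seed = 92)
  scores2 <- chi2_site_scores(concatenate_genes(list(aln2)))
  planted2 <- attr(aln2, "biased_sites")
  top2 <- order(-scores2)[seq_along(planted2)]
  expect_gte(mean(planted2 %in% top2), 0.9)
})

test_that("ef2_signature classifies residue pairs", {
  g <- gene_alignment("EF2", c(
    RedAlga = "XXSAXX", Picozoa = "KKSARR", Green = "KKGSRR",
    Outlier = "KKTARR", Partial = "KKG-RR"))
  sig <- ef2_signature(g, c(3, 4))
  expect_equal(sig$state[sig$taxon == "Picozoa"], "derived")
  expect_equal(sig$state[sig$taxon == "Green"], "ancestral")
  expect_equal(sig$state[sig$taxon == "Outlier"], "other")
  expect_equal(sig$state[sig$taxon == "Partial"], "missing")
  expect_equal(sig$state[sig$taxon == "RedAlga"], "derived")
  expect_error(ef2_signature(g, c(3, 9)), "range")
})

test_that("site-rate tables read with comments and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# per-site rates", "site\trate", "2\t0.5", "1\t1.5", "3\t0.1"),
             path)
  expect_equal(read_site_rates(path), c(1.5, 0.5, 0.1))
  expect_error(read_site_rates(path, n_sites = 5), "expected 5")
})
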