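map2 <- fixture_map(sags = 2, n_cyano = 4, n_photo = 9, n_lacking = 3)
cfg0 <- scan_config()

test_that("cluster eligibility follows the focal/cyano/archaeplastid rule", {
  expect_true(cluster_eligible_egt(c("Picozoa_SAG1@1", "Cyano1", "Red1"), map2))
  expect_false(cluster_eligible_egt(c("Picozoa_SAG1@1", "Red1"), map2))
  expect_false(cluster_eligible_egt(c("Cyano1", "Red1"), map2))
  expect_true(cluster_eligible_hgt(c("Picozoa_SAG1@1", "Bact1"), map2))
  expect_false(cluster_eligible_hgt(c("Picozoa_SAG1@1", "Cyano1"), map2))
  expect_false(cluster_eligible_hgt(c("Bact1", "Bact2"), map2))
})

test_that("a clean two-assembly EGT configuration is accepted", {
  tr <- fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)", "Red1", "Red2"),
                     c("Cyano1", "Cyano2"))
  pair <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a", "Red1", "Red2"),
               side_b = c("Cyano1", "Cyano2"))
  ev <- classify_egt_pair(pair, map2, "Picozoa", cfg0, tree = tr)
  expect_true(is_transfer_event(ev))
  expect_equal(ev$contamination, 0)
  expect_equal(ev$focal_assemblies, c("SAG1", "SAG2"))
  expect_equal(ev$donor_side, c("Cyano1", "Cyano2"))
})

test_that("rule conformance: the four canonical rejections", {
  # single cyanobacterium sister
  tr1 <- fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)", "Red1"), "Cyano1")
  p1 <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a", "Red1"),
             side_b = "Cyano1")
  r1 <- classify_egt_pair(p1, map2, "Picozoa", cfg0, tree = tr1)
  expect_false(is_transfer_event(r1))
  expect_equal(reject_reason(r1), "cyano_too_small")

  # single-assembly focal clade for a multi-assembly species
  tr2 <- fixture_tree(c("Picozoa_SAG1@a", "Red1"), c("Cyano1", "Cyano2"))
  p2 <- list(side_a = c("Picozoa_SAG1@a", "Red1"),
             side_b = c("Cyano1", "Cyano2"))
  r2 <- classify_egt_pair(p2, map2, "Picozoa", cfg0, tree = tr2)
  expect_equal(reject_reason(r2), "assemblies")

  # two assemblies present but not monophyletic
  tr3 <- fixture_tree(c("(Picozoa_SAG1@a,Red1)", "Picozoa_SAG2@a", "Red2"),
                      c("Cyano1", "Cyano2"))
  p3 <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a", "Red1", "Red2"),
             side_b = c("Cyano1", "Cyano2"))
  r3 <- classify_egt_pair(p3, map2, "Picozoa", cfg0, tree = tr3)
  expect_equal(reject_reason(r3), "not_monophyletic")

  # mixed donor clades
  tr4 <- fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)", "Red1"),
                      c("Cyano1", "Bact2"))
  p4 <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a", "Red1"),
             side_b = c("Cyano1", "Bact2"))
  expect_equal(reject_reason(classify_egt_pair(p4, map2, "Picozoa", cfg0,
                                               tree = tr4)), "cyano_impure")
  expect_equal(reject_reason(classify_hgt_pair(p4, map2, "Picozoa", cfg0,
                                               tree = tr4)), "donor_impure")
})

test_that("the 10% contamination threshold is inclusive and sharp", {
  euk_clean <- c("(Picozoa_SAG1@a,Picozoa_SAG2@a)", sprintf("Red%d", 1:7))
  # exactly 10%: 1 contaminant in 10 sequences
  tr_in <- fixture_tree(c(euk_clean, "Hetero2"), c("Cyano1", "Cyano2"),
                        rest = c("Bact1", "Hetero1", "Red8"))
  p_in <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a",
                          sprintf("Red%d", 1:7), "Hetero2"),
               side_b = c("Cyano1", "Cyano2"))
  ev <- classify_egt_pair(p_in, map2, "Picozoa", cfg0, tree = tr_in)
  expect_true(is_transfer_event(ev))
  expect_equal(ev$contamination, 0.10)

  # one more contaminant: 2/11 > 10% -> rejected as contamination
  tr_out <- fixture_tree(c(euk_clean, "Hetero2", "Hetero3"),
                         c("Cyano1", "Cyano2"),
                         rest = c("Bact1", "Hetero1", "Red8"))
  p_out <- list(side_a = c(p_in$side_a, "Hetero3"), side_b = p_in$side_b)
  r <- classify_egt_pair(p_out, map2, "Picozoa", cfg0, tree = tr_out)
  expect_false(is_transfer_event(r))
  expect_equal(reject_reason(r), "contamination")

  # exclusive mode flips the boundary case
  cfg_ex <- scan_config(contamination_inclusive = FALSE)
  expect_equal(reject_reason(classify_egt_pair(p_in, map2, "Picozoa", cfg_ex,
                                               tree = tr_in)),
               "contamination")
})

test_that("HGT rule accepts focal-only and higher-group sides", {
  tr <- fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)"), c("Bact1", "Bact2"),
                     rest = c("Bact3", "Hetero1", "Red3"))
  p <- list(side_a = c("Picozoa_SAG1@a", "Picozoa_SAG2@a"),
            side_b = c("Bact1", "Bact2"))
  expect_true(is_transfer_event(classify_hgt_pair(p, map2, "Picozoa", cfg0)))

  # a same-higher-group companion is allowed when configured, otherwise it
  # counts toward contamination
  map_hg <- fixture_map(sags = 2)
  rec <- map_hg$records
  rec$higher_group[rec$taxon_id == "Hetero1"] <- "Picozoa"
  map_hg <- taxon_map(rec)
  p2 <- list(side_a = c("Picozoa_SAG1@a", "Hetero1"),
             side_b = c("Bact1", "Bact2"))
  cfg_hg <- scan_config(higher_group = "Picozoa")
  ev <- classify_hgt_pair(p2, map_hg, "Picozoa", cfg_hg)
  expect_true(is_transfer_event(ev))
  expect_equal(ev$contamination, 0)
  r <- classify_hgt_pair(p2, map_hg, "Picozoa", cfg0)
  expect_equal(reject_reason(r), "contamination")
})

test_that("each tree counts at most once, details list every configuration", {
  nwk <- paste0(
    "(((((Picozoa_SAG1@x,Picozoa_SAG2@x),Red1),(Cyano1,Cyano2)),",
    "((((Picozoa_SAG1@y,Picozoa_SAG2@y),Red2),(Cyano3,Cyano4)),Hetero1)),",
    "Bact1,Red9);")
  tr <- parse_newick(nwk, tree_id = "double")
  res <- scan_trees(list(tr), map2, focal = "Picozoa", mode = "egt",
                    detail = TRUE)
  expect_equal(res$summary$n_egt, 1L)
  expect_equal(nrow(res$events), 1L)
  expect_equal(nrow(res$details), 2L)
})

test_that("scan handles empty eligibility and strict unknown leaves", {
  t_bg <- parse_newick("(Red1,Red2,(Hetero1,Bact1));", "bg")
  res <- scan_trees(list(t_bg), map2, focal = "Picozoa", mode = "both")
  expect_equal(res$summary$n_egt, 0L)
  expect_equal(nrow(res$events), 0L)
  expect_true(is.na(res$summary$ratio))

  t_bad <- parse_newick("(Picozoa_SAG1@a,Mystery1,(Cyano1,Red1));", "bad")
  expect_error(scan_trees(list(t_bad), map2, focal = "Picozoa"), "Mystery1")
  expect_silent(scan_trees(list(t_bad), map2, focal = "Picozoa",
                           strict = FALSE))
})

test_that("scan output is invariant under newick rotation of inputs", {
  sim <- simulate_dataset(sim_config(seed = 5, n_genes = 15, p_egt = 0.5,
                                     p_hgt = 0.3, p_background = 0.2))
  rotated <- lapply(sim$trees, function(t) {
    parse_newick(ape::write.tree(ape::rotateConstr(
      t$phylo, rev(t$phylo$tip.label))), tree_id = t$tree_id)
  })
  a <- scan_trees(sim$trees, sim$map, focal = "Picozoa", mode = "both")
  b <- scan_trees(rotated, sim$map, focal = "Picozoa", mode = "both")
  expect_equal(a$summary, b$summary)
  expect_setequal(a$events$tree_id, b$events$tree_id)
})

test_that("detection is monotone in the thresholds", {
  sim <- simulate_dataset(sim_config(seed = 13, n_genes = 40, p_egt = 0.6,
                                     p_hgt = 0, p_background = 0.4,
                                     contamination_level = 0.10,
                                     n_plastid_in_clade = 7))
  counts_by_contam <- vapply(c(0, 0.05, 0.10, 0.25), function(cm) {
    scan_trees(sim$trees, sim$map, focal = "Picozoa", mode = "egt",
               cfg = scan_config(contamination_max = cm))$summary$n_egt
  }, integer(1))
  expect_true(all(diff(counts_by_contam) >= 0))

  counts_by_cyano <- vapply(1:3, function(mc) {
    scan_trees(sim$trees, sim$map, focal = "Picozoa", mode = "egt",
               cfg = scan_config(min_cyano = mc))$summary$n_egt
  }, integer(1))
  expect_true(all(diff(counts_by_cyano) <= 0))
})

test_that("classification agrees between adjacent-pair and rerooting enumeration", {
  trees <- list(
    fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)", "Red1"),
                 c("Cyano1", "Cyano2")),
    fixture_tree(c("Picozoa_SAG1@a", "Red1"), c("Cyano1", "Cyano2")),
    fixture_tree(c("(Picozoa_SAG1@a,Picozoa_SAG2@a)"), c("Bact1", "Bact2"),
                 rest = c("Bact3", "Hetero1", "Red3"))
  )
  for (tr in trees) {
    via_pairs <- character(0)
    for (p in sister_pairs(tr)) {
      for (f in list(classify_egt_pair(p, map2, "Picozoa", cfg0, tree = tr),
                     classify_hgt_pair(p, map2, "Picozoa", cfg0, tree = tr))) {
        if (is_transfer_event(f)) {
          via_pairs <- c(via_pairs,
                         paste(f$kind, o_pair_key(f$euk_side, f$donor_side)))
        }
      }
    }
    via_oracle <- character(0)
    for (key in oracle_sister_pairs(tr$phylo)) {
      sides <- strsplit(strsplit(key, " || ", fixed = TRUE)[[1]], ",",
                        fixed = TRUE)
      p <- list(side_a = sides[[1]], side_b = sides[[2]])
      for (f in list(classify_egt_pair(p, map2, "Picozoa", cfg0, tree = tr),
                     classify_hgt_pair(p, map2, "Picozoa", cfg0, tree = tr))) {
        if (is_transfer_event(f)) {
          via_oracle <- c(via_oracle,
                          paste(f$kind, o_pair_key(f$euk_side, f$donor_side)))
        }
      }
    }
    expect_setequal(unique(via_pairs), unique(via_oracle))
  }
})

test_that("ratio contract and error handling", {
  expect_equal(egt_hgt_ratio(4, 2), 2.0)
  expect_equal(egt_hgt_ratio(0, 5), 0.0)
  expect_true(is.na(egt_hgt_ratio(3, 0)))
  expect_error(egt_hgt_ratio(-1, 2), "non-negative")
})
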