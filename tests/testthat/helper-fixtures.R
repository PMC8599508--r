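# Programmatic fixtures: small taxon maps, hand-built trees, random
# alignments. Everything is built in code; nothing is read from disk.

# A small annotated world: Picozoa split over `sags` assemblies (focal,
# plastid-lacking), plus configurable numbers of cyanobacteria, other
# bacteria, photosynthetic algae, a non-photosynthetic plastid lineage and
# plastid-lacking heterotrophs.
fixture_map <- function(sags = 2, n_cyano = 3, n_bact = 3, n_photo = 3,
                        n_nonphoto = 1, n_lacking = 2) {
  rows <- list(
    data.frame(taxon_id = sprintf("Picozoa_SAG%d", seq_len(sags)),
               group = "plastid_lacking", focal = TRUE,
               assembly_id = sprintf("SAG%d", seq_len(sags)),
               higher_group = "Picozoa"),
    data.frame(taxon_id = sprintf("Cyano%d", seq_len(n_cyano)),
               group = "cyanobacteria", focal = FALSE, assembly_id = "",
               higher_group = ""),
    data.frame(taxon_id = sprintf("Bact%d", seq_len(n_bact)),
               group = "other_bacteria", focal = FALSE, assembly_id = "",
               higher_group = ""),
    data.frame(taxon_id = sprintf("Red%d", seq_len(n_photo)),
               group = "plastid_photosynthetic", focal = FALSE,
               assembly_id = "", higher_group = ""),
    data.frame(taxon_id = sprintf("Rhodelphis%d", seq_len(n_nonphoto)),
               group = "plastid_nonphotosynthetic", focal = FALSE,
               assembly_id = "", higher_group = ""),
    data.frame(taxon_id = sprintf("Hetero%d", seq_len(n_lacking)),
               group = "plastid_lacking", focal = FALSE, assembly_id = "",
               higher_group = "")
  )
  taxon_map(do.call(rbind, rows))
}

# Hand-built rule-conformance trees (<= 12 leaves). The planted eukaryote
# side is always sister to the donor clade; the remainder keeps the tree
# eligible without adding qualifying configurations.
fixture_tree <- function(euk, donor, rest = c("Bact1", "Hetero1", "Red3")) {
  grp <- function(x) if (length(x) == 1) x else
    paste0("(", paste(x, collapse = ","), ")")
  nest <- function(x) if (length(x) == 1) x else
    paste0("(", x[1], ",", nest(x[-1]), ")")
  txt <- sprintf("((%s,%s),%s);", nest(euk), grp(donor),
                 paste(rest, collapse = ","))
  parse_newick(txt, tree_id = "fixture")
}

random_aa_seqs <- function(n_taxa, n_sites) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")
  stats::setNames(
    vapply(seq_len(n_taxa), function(i) {
      paste(sample(aa, n_sites, replace = TRUE), collapse = "")
    }, character(1)),
    sprintf("t%02d", seq_len(n_taxa)))
}

random_gene <- function(gene_id, taxa, n_sites) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V","-")
  gene_alignment(gene_id, stats::setNames(
    vapply(taxa, function(t) paste(sample(aa, n_sites, replace = TRUE),
                                   collapse = ""), character(1)),
    taxa))
}
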