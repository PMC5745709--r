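#!/usr/bin/env Rscript
# Stage 6: map the gene-order character onto the species tree by Fitch
# parsimony. Within-species polymorphism (two gene orders segregating in
# one species) is represented by expanding that species into one tip per
# individual.

suppressPackageStartupMessages(library(mitodrl))

species_tree <- ape::read.tree(text = paste0(
  "((Desmognathus,Phaeognathus),(aeneus,(hardii,(lugubris,",
  "(flavipunctatus,(ferreus,vagrans))))));"))

ind_states <- c(hardii_RAC27 = "aneides_order", hardii_RAC28 = "aneides_order",
                hardii_RAC20 = "hardii_duplicated",
                hardii_RAC25 = "hardii_duplicated",
                Desmognathus = "typical_vertebrate",
                Phaeognathus = "typical_vertebrate",
                aeneus = "aneides_order", lugubris = "aneides_order",
                flavipunctatus = "aneides_order", ferreus = "aneides_order",
                vagrans = "aneides_order")
species <- c(hardii_RAC27 = "hardii", hardii_RAC28 = "hardii",
             hardii_RAC20 = "hardii", hardii_RAC25 = "hardii",
             Desmognathus = "Desmognathus", Phaeognathus = "Phaeognathus",
             aeneus = "aeneus", lugubris = "lugubris",
             flavipunctatus = "flavipunctatus", ferreus = "ferreus",
             vagrans = "vagrans")

states <- polymorphic_species_expand(ind_states, species)
# the two haplotypes were sampled from two separate populations; expand the
# species tip into the two populations, then each into its individuals
tree <- expand_tip(species_tree, "hardii", c("hardii_popA", "hardii_popB"))
tree <- expand_tip(tree, "hardii_popA", c("hardii_RAC27", "hardii_RAC28"))
tree <- expand_tip(tree, "hardii_popB", c("hardii_RAC20", "hardii_RAC25"))

fr <- fitch_min_changes(tree, states,
                        outgroup = c("Desmognathus", "Phaeognathus"))
message("minimum rearrangement events: ", fr$min_changes,
        " (", fr$n_mpr, " most-parsimonious reconstruction(s))")
for (i in seq_len(nrow(fr$placements))) {
  p <- fr$placements[i, ]
  message("  event on edge ", p$parent, " -> ", p$child, ": ",
          p$from_state, " => ", p$to_state)
}

write_report(list(min_changes = fr$min_changes, n_mpr = fr$n_mpr,
                  placements = fr$placements),
             "results/events.json",
             inputs = list(tree = "inline species topology"))
message("wrote results/events.json")
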