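#!/usr/bin/env Rscript
# DEC biogeographic analysis with rule-based, time-stratified dispersal
# matrices: builds the six-epoch dispersal matrices (printing the
# Quaternary worked example), simulates ranges on the study tree, fits
# the DEC rates, and reports ancestral range probabilities at the root.

suppressPackageStartupMessages(library(paleoasr))

seed <- 2026
out_dir <- "results/biogeo"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg_file <- system.file("extdata", "paleo_epochs_synthetic.yaml",
                        package = "paleoasr", mustWork = TRUE)
cfg <- read_area_config(cfg_file)

# per-epoch dispersal matrices; the Quaternary worked example first
for (i in seq_along(cfg$epochs)) {
  ep <- cfg$epochs[[i]]
  D <- build_dispersal_matrix(ep)
  utils::write.table(
    data.frame(area = rownames(D), round(D, 4), check.names = FALSE),
    file.path(out_dir, sprintf("dispersal_epoch_%02d.tsv", i)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (i == 1) {
    cat(sprintf(
      "Quaternary North America -> Australia: %.3f via island-hopping (0.1 x 0.5 x 0.5); the direct trans-Pacific route alone would be 0.01\n",
      D["NorthAmerica", "Australia"]))
  }
}

# ranges on the constrained study topology, truncated epochs to its depth
tree <- read_newick_time_tree(file = "results/data/constrained.nwk")
epochs <- Filter(function(e) e$start_Ma < tree$root_age, cfg$epochs)
epochs[[length(epochs)]]$end_Ma <-
  max(epochs[[length(epochs)]]$end_Ma, tree$root_age + 1)

d_sim <- 0.02; e_sim <- 0.01
m_sim <- dec_model(cfg$inhabitable, epochs, d = d_sim, e = e_sim)
rr <- simulate_dec_ranges(tree, m_sim, seed = derive_seed(seed, "ranges"))
keep <- names(rr)[!attr(rr, "extinct")]
tree2 <- if (length(keep) == length(rr)) tree else
  time_tree(ape::keep.tip(tree$phy, keep),
            tip_ages = stats::setNames(
              tree$node_age[match(keep, tree$phy$tip.label)], keep))
rng_tab <- data.frame(
  taxon = keep,
  areas = vapply(rr[keep], function(r)
    paste(cfg$inhabitable[r], collapse = ","), ""))
utils::write.table(rng_tab, file.path(out_dir, "tip_ranges.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

fit <- fit_dec(tree2, rr[keep], epochs, cfg$inhabitable)
cat(sprintf("DEC fit: d-hat = %.4f (simulated %.3f), e-hat = %.4f (simulated %.3f), logL = %.2f\n",
            fit$d, d_sim, fit$e, e_sim, fit$logL))

m_fit <- dec_model(cfg$inhabitable, epochs, d = fit$d, e = fit$e)
root <- length(tree2$phy$tip.label) + 1L
ar <- dec_ancestral_ranges(tree2, rr[keep], m_fit, node = root)
utils::write.table(ar, file.path(out_dir, "root_ranges.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
rngs <- ar[ar$type == "range", ]
cat("ancestral range at the root (relative %):\n")
print(utils::head(rngs[order(-rngs$rel_prob_pct),
                       c("label", "rel_prob_pct")], 5), row.names = FALSE)
cat("wrote", out_dir, "\n")
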