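#!/usr/bin/env Rscript
# Stage 6: coexpression network, modules, subnetwork, enrichment, pairing.
#
# Builds the soft-thresholded (beta = 12) unsigned network with topological
# overlap over the normalized miRNA expression, detects modules with
# eigengene merging, extracts the subnetwork around the differentially
# expressed miRNAs, correlates miRNA and target expression, and runs
# hypergeometric term enrichment of the validated target transcripts.

suppressPackageStartupMessages(library(mirdevel))

out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr_df <- read_tsv("results/expression/expected_log2.tsv")
expr <- as.matrix(expr_df[, -1])
rownames(expr) <- expr_df$mirna
de <- read_tsv("results/expression/de_table.tsv")
targets <- read_tsv("results/degradome/targets.tsv")
annotation <- read_tsv("results/data/reference/annotation.tsv")

keep <- apply(expr, 1, sd) > 0
expr <- expr[keep, ]

ps <- pick_soft_threshold(expr)
write_tsv(ps$fit_table, file.path(out, "soft_threshold.tsv"))
message("soft threshold: beta = ", ps$beta)

net <- build_network(expr, network_params(beta = 12))
mod <- detect_modules(net)
write_tsv(data.frame(mirna = names(mod$module), module = mod$module),
          file.path(out, "modules.tsv"))
write_tsv(cbind(sample = rownames(mod$eigengenes),
                as.data.frame(mod$eigengenes)),
          file.path(out, "eigengenes.tsv"))
message("modules: ", paste(names(table(mod$module)), table(mod$module),
                           sep = "=", collapse = ", "))

seeds <- de$mirna[de$significant]
sub <- extract_subnetwork(net, seeds, floor = 0.1)
write_tsv(sub$edges, file.path(out, "subnetwork_edges.tsv"))
message(nrow(sub$edges), " subnetwork edges around ",
        length(intersect(seeds, rownames(expr))), " DE miRNAs; top hubs: ",
        paste(head(names(sub$degree), 3), collapse = ", "))

# miRNA-target anticorrelation over matched samples
ref <- generate_reference(sim_config(seed = 1))
tgt_expr <- simulate_target_expression(ref, sigma = 0.2, seed = 1)
pairs <- targets[targets$transcript %in% rownames(tgt_expr) &
                   targets$mirna %in% rownames(expr),
                 c("mirna", "transcript")]
if (nrow(pairs) > 0) {
  pc <- correlate_pairs(expr, tgt_expr, pairs)
  write_tsv(pc, file.path(out, "pair_correlations.tsv"))
  message(sum(pc$negative), " of ", nrow(pc),
          " miRNA-target pairs negatively correlated")
}

enr <- enrich(unique(targets$transcript), annotation)
write_tsv(enr, file.path(out, "enrichment.tsv"))
message("top enriched term: ", enr$term[1], " (p = ",
        format(enr$p[1], digits = 3), ")")
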