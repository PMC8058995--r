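#!/usr/bin/env Rscript
# Stage 4: normalization, differential expression, clustering, ddCt.
#
# Builds the miRNA x library count matrix, normalizes it against the median
# reference by per-library regression, calls stage-dependent miRNAs by
# one-way ANOVA (p <= 0.05), clusters the significant profiles into three
# classes, and analyses the RT-qPCR Ct table with 2^-ddCt.

suppressPackageStartupMessages(library(mirdevel))

out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- read_tsv("results/preprocess/tags.tsv")
known <- read_tsv("results/identify/known_mirnas.tsv")
novel <- read_tsv("results/identify/novel_mirnas.tsv")
design <- read_tsv("results/data/design.tsv")

counts <- mirna_count_matrix(tags, known, novel, design$sample)
norm <- normalize_counts(counts)
write_tsv(norm$fits, file.path(out, "normalization_fits.tsv"))
write_tsv(cbind(mirna = rownames(norm$expr), as.data.frame(norm$expr)),
          file.path(out, "expected_log2.tsv"))

de <- anova_de(norm$expr, design$stage)
write_tsv(de, file.path(out, "de_table.tsv"))
message(sum(de$significant), " of ", nrow(de),
        " miRNAs significantly stage-dependent (p <= 0.05)")

sig <- de[de$significant, ]
if (nrow(sig) >= 3) {
  sm <- as.matrix(sig[, grep("^mean_", names(sig))])
  rownames(sm) <- sig$mirna
  cl <- hierarchical_cluster(sm, k = 3)
  write_tsv(data.frame(mirna = names(cl$class), class = cl$class),
            file.path(out, "profile_classes.tsv"))
  message("profile classes: ",
          paste(names(table(cl$class)), table(cl$class), sep = "=",
                collapse = ", "))
}

ct <- read_tsv("results/data/ct_table.tsv")
cal <- ct$sample[ct$stage == design$stage[1]][1]
rel <- ddct(ct, reference_genes = unique(ct$gene[ct$is_reference]),
            calibrator = cal)
write_tsv(rel, file.path(out, "ddct.tsv"))
message("ddCt relative expression written (calibrator ", cal, ")")
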