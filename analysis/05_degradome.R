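#!/usr/bin/env Rscript
# Stage 5: degradome target validation.
#
# Maps degradome tag 5' ends onto the transcriptome, predicts miRNA binding
# sites with the plant penalty scheme (threshold 4, positions 2-13
# doubled), validates cleavage opposite miRNA position 10 and classifies
# sites into categories 0-4; writes the target table and per-transcript
# T-plot tables.

suppressPackageStartupMessages(library(mirdevel))

out <- "results/degradome"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tx <- read_fasta("results/data/reference/transcriptome.fa")
deg <- read_fastq("results/data/degradome.fastq")
matures <- read_fasta("results/data/reference/matures.fa")

prof <- map_degradome(deg$sequence, tx)
message(length(deg$sequence) - prof$unmapped, " of ", length(deg$sequence),
        " degradome tags mapped")

targets <- degradome_targets(matures, tx, prof$profiles)
write_tsv(targets, file.path(out, "targets.tsv"))
message(nrow(targets), " validated cleavage sites; categories: ",
        paste(names(table(targets$category)), table(targets$category),
              sep = "=", collapse = ", "))

tp_dir <- file.path(out, "tplots")
dir.create(tp_dir, showWarnings = FALSE)
for (t in unique(targets$transcript)) {
  tp <- tplot_data(prof$profiles[[t]], targets[targets$transcript == t, ])
  write_tsv(tp, file.path(tp_dir, paste0(t, ".tsv")))
}
message("T-plot tables for ", length(unique(targets$transcript)),
        " transcripts")
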