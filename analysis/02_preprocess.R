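#!/usr/bin/env Rscript
# Stage 2: raw-read triage.
#
# Trims the 3' adapter, filters junk/low-quality reads, applies the
# 18-25 nt length gates, annotates tags against the ncRNA/repeat
# references, and writes the collapsed tag count matrix, the per-library
# statistics table and the valid-read length distribution.

suppressPackageStartupMessages(library(mirdevel))

data_dir <- "results/data"
out <- "results/preprocess"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- read_tsv(file.path(data_dir, "design.tsv"))
libs <- lapply(design$sample, function(nm) {
  read_fastq(file.path(data_dir, paste0(nm, ".fastq")))
})
names(libs) <- design$sample

ncrna_seq <- read_fasta(file.path(data_dir, "reference/ncrna.fa"))
ncrna <- data.frame(id = names(ncrna_seq),
                    class = sub("_.*", "", names(ncrna_seq)),
                    sequence = unname(ncrna_seq))
rep_seq <- read_fasta(file.path(data_dir, "reference/repeats.fa"))
repeats <- data.frame(id = names(rep_seq), sequence = unname(rep_seq))

prep <- preprocess_libraries(libs, ncrna = ncrna, repeats = repeats)
write_tsv(prep$tags, file.path(out, "tags.tsv"))
write_tsv(prep$stats, file.path(out, "stats.tsv"))
ld <- length_distribution(prep$tags)
write_tsv(ld, file.path(out, "length_distribution.tsv"))

valid <- prep$stats[prep$stats$class == "valid", ]
message("valid reads per library: ",
        paste(valid$library, valid$total, collapse = ", "))
message("modal valid-read length: ", ld$length[which.max(ld$total)], " nt")
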