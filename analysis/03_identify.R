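#!/usr/bin/env Rscript
# Stage 3: miRNA cataloguing.
#
# Maps valid tags to the precursor catalogue (3-group classification
# against the transcriptome), counts family membership, and predicts novel
# miRNAs by candidate excision + hairpin-criteria evaluation with RNAfold.

suppressPackageStartupMessages(library(mirdevel))

data_dir <- "results/data"
out <- "results/identify"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- read_tsv("results/preprocess/tags.tsv")
tx <- read_fasta(file.path(data_dir, "reference/transcriptome.fa"))
prec_seq <- read_fasta(file.path(data_dir, "reference/precursors.fa"))
hdr <- names(prec_seq)
prec <- data.frame(
  id = sub(" .*", "", hdr),
  family = sub(".*family=(\\S+).*", "\\1", hdr),
  mature_start = as.integer(sub(".*mature=(\\d+)-(\\d+).*", "\\1", hdr)),
  mature_end = as.integer(sub(".*mature=(\\d+)-(\\d+).*", "\\2", hdr)),
  sequence = unname(prec_seq))
prec$name <- sub("-prec$", "", prec$id)
prec <- prec[!grepl("^(novel|decoy)", prec$name), ]   # catalogue only
prec$mature <- substr(prec$sequence, prec$mature_start, prec$mature_end)

ident <- identify_mirnas(tags, prec, tx)

write_tsv(ident$known, file.path(out, "known_mirnas.tsv"))
write_tsv(ident$families, file.path(out, "families.tsv"))
write_tsv(ident$evaluations[, setdiff(names(ident$evaluations), "sequence")],
          file.path(out, "hairpin_evaluations.tsv"))
write_tsv(ident$novel$records, file.path(out, "novel_mirnas.tsv"))

grp <- table(unique(ident$known[, c("name", "group")])$group)
message("known miRNAs by group: ",
        paste(names(grp), grp, sep = "=", collapse = ", "))
s <- ident$novel$summary
message(s$n, " novel miRNAs; mature ", s$mature_len_range[1], "-",
        s$mature_len_range[2], " nt; hairpins ", s$hairpin_len_range[1], "-",
        s$hairpin_len_range[2], " nt; MFE ", s$mfe_range[1], " to ",
        s$mfe_range[2], " kcal/mol")
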