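#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the reference bundle (transcriptome with planted precursors, miRNA
# catalogue, contaminants, annotation, truth tables) and the 15 small-RNA
# libraries (5 stages x 3 replicates), the degradome tag library and a Ct
# table, and writes everything under results/data/.

suppressPackageStartupMessages(library(mirdevel))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
ref <- generate_reference(cfg)
write_bundle(ref, file.path(out, "reference"))
message("reference bundle: ", length(ref$transcriptome), " transcripts, ",
        nrow(ref$mature_catalogue), " catalogued miRNAs, ",
        nrow(ref$truth$novel), " planted novel + ",
        nrow(ref$truth$decoys), " decoy hairpins")

libs <- simulate_all_libraries(ref, seed = seed)
for (nm in names(libs)) {
  write_fastq(libs[[nm]], file.path(out, paste0(nm, ".fastq")))
}
message("wrote ", length(libs), " libraries of ",
        format(cfg$library_depth, big.mark = ","), " reads each")

deg <- simulate_degradome(ref, background_rate = 0.1, seed = seed)
write_fastq(data.frame(id = deg$id, sequence = deg$sequence,
                       quality = strrep("I", nchar(deg$sequence))),
            file.path(out, "degradome.fastq"))
message("degradome: ", nrow(deg), " tags over ",
        length(unique(deg$transcript)), " transcripts")

ct <- simulate_ct_table(ref, noise_sd = 0.15, seed = seed)
write_tsv(ct, file.path(out, "ct_table.tsv"))
write_tsv(library_design(cfg), file.path(out, "design.tsv"))
message("done")
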