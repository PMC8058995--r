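# End-to-end driver: simulate -> preprocess -> catalogue -> normalize/DE ->
# degradome -> network. Used by the analysis scripts and the acceptance
# checks; each stage is also callable on its own.

#' Build the miRNA x library count matrix from identified miRNAs
#'
#' Sums per-library tag counts over all tags assigned to each miRNA (known
#' catalogue matches and accepted novel records).
#'
#' @param tags collapsed tag table with per-library count columns.
#' @param known [identify_mirnas()] `$known` matches.
#' @param novel_records [catalogue_novel()] `$records` (optional).
#' @param libraries library (sample) column names.
#' @return miRNA x library count matrix.
#' @export
mirna_count_matrix <- function(tags, known, novel_records = NULL, libraries) {
  map <- known[, c("tag", "name")]
  if (!is.null(novel_records) && nrow(novel_records) > 0) {
    map <- rbind(map, data.frame(tag = novel_records$mature,
                                 name = novel_records$name))
  }
  map <- unique(map)
  nm <- unique(map$name)
  counts <- matrix(0L, length(nm), length(libraries),
                   dimnames = list(nm, libraries))
  idx <- match(map$tag, tags$sequence)
  for (i in seq_len(nrow(map))) {
    if (is.na(idx[i])) next
    counts[map$name[i], ] <- counts[map$name[i], ] +
      as.integer(unlist(tags[idx[i], libraries]))
  }
  counts
}

#' Run the full synthetic-study pipeline
#'
#' Generates the reference bundle and libraries, then runs read triage,
#' miRNA cataloguing (known + novel), normalization, ANOVA differential
#' expression, degradome target validation and coexpression network
#' analysis. All randomness derives from `seed`.
#'
#' @param config a [sim_config()]; its `seed` is overridden by `seed`.
#' @param seed integer master seed.
#' @param run_degradome,run_network optional stages (both default TRUE).
#' @return list with every intermediate: `ref`, `prep`, `ident`, `counts`,
#'   `norm`, `de`, `clustering`, `degradome`, `network`.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         run_degradome = TRUE, run_network = TRUE) {
  config$seed <- seed
  ref <- generate_reference(config)
  design <- library_design(config)
  libs <- simulate_all_libraries(ref, seed = seed)
  prep <- preprocess_libraries(libs, ncrna = ref$ncrna, repeats = ref$repeats,
                               params = filter_params(adapter = config$adapter))
  catalogue <- ref$precursors[ref$precursors$source == "catalogue", ]
  ident <- identify_mirnas(prep$tags, catalogue, ref$transcriptome)
  counts <- mirna_count_matrix(prep$tags, ident$known,
                               ident$novel$records, design$sample)
  norm <- normalize_counts(counts)
  de <- anova_de(norm$expr, design$stage)
  sig <- de[de$significant, , drop = FALSE]
  clustering <- if (nrow(sig) >= 3) {
    sm <- as.matrix(sig[, grep("^mean_", names(sig))])
    rownames(sm) <- sig$mirna
    hierarchical_cluster(sm, k = 3)
  } else NULL

  degradome <- NULL
  if (run_degradome) {
    deg_tags <- simulate_degradome(ref, background_rate = 0.1, seed = seed)
    prof <- map_degradome(deg_tags$sequence, ref$transcriptome)
    matures <- setNames(catalogue$mature, catalogue$name)
    degradome <- list(tags = deg_tags, profiles = prof$profiles,
                      unmapped = prof$unmapped,
                      targets = degradome_targets(matures, ref$transcriptome,
                                                  prof$profiles))
  }

  network <- NULL
  if (run_network) {
    keep <- apply(norm$expr, 1, sd) > 0
    net <- build_network(norm$expr[keep, , drop = FALSE])
    network <- list(network = net, modules = detect_modules(net))
  }

  list(ref = ref, design = design, prep = prep, ident = ident,
       counts = counts, norm = norm, de = de, clustering = clustering,
       degradome = degradome, network = network)
}
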