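#' Configuration for the synthetic small-RNA study design
#'
#' Defines the simulated study: five developmental stages (vegetative
#' juvenile through flower differentiation) with three replicate libraries
#' each, a transcriptome hosting planted miRNA precursors, ncRNA
#' contaminants and library composition fractions. Defaults are the study
#' conditions every downstream module is exercised under.
#'
#' @param seed base random seed; all generated artifacts are deterministic
#'   functions of it.
#' @param n_transcripts number of transcripts in the synthetic transcriptome.
#' @param n_known_mirnas catalogued (miRBase-like) miRNAs.
#' @param n_novel_mirnas planted novel miRNAs: criteria-satisfying hairpins
#'   embedded in transcripts but absent from the mature catalogue, so only
#'   hairpin prediction can find them.
#' @param n_decoy_mirnas decoy hairpins, each designed to violate one
#'   hairpin criterion.
#' @param n_contaminant_refs rRNA/tRNA/snoRNA/snRNA reference sequences.
#' @param stages ordered developmental stage labels.
#' @param replicates_per_stage libraries per stage.
#' @param library_depth reads per library.
#' @param adapter 3' sequencing adapter (TruSeq small-RNA).
#' @param read_length raw read length (nt); short inserts read through into
#'   the adapter.
#' @param junk_fraction,contaminant_fraction,lowqual_fraction,adapter_only_fraction
#'   library composition proportions; the remainder is miRNA-derived reads.
#' @param dispersion negative-binomial overdispersion of miRNA counts.
#' @param count_model `"nb"` (gamma-multinomial, NB-like marginals),
#'   `"poisson"` (plain multinomial at the expected proportions) or
#'   `"exact"` (deterministic rounded expectations, for zero-noise oracles).
#' @param n_terms annotation terms available for enrichment.
#' @param n_target_pairs miRNA-target cleavage sites planted in the
#'   transcriptome.
#' @param group2_fraction,group3_fraction fractions of catalogued miRNAs
#'   whose precursors are withheld from the transcriptome (group 2: mature
#'   still embedded in a transcript; group 3: neither).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_transcripts = 120,
                       n_known_mirnas = 40,
                       n_novel_mirnas = 10,
                       n_decoy_mirnas = 10,
                       n_contaminant_refs = 8,
                       stages = c("VJ_I", "VJ_II", "FI_I", "FI_II", "FD"),
                       replicates_per_stage = 3,
                       library_depth = 20000,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50,
                       junk_fraction = 0.02,
                       contaminant_fraction = 0.10,
                       lowqual_fraction = 0.02,
                       adapter_only_fraction = 0.01,
                       dispersion = 0.1,
                       count_model = c("nb", "poisson", "exact"),
                       n_terms = 25,
                       n_target_pairs = 12,
                       group2_fraction = 0.1,
                       group3_fraction = 0.1) {
  count_model <- match.arg(count_model)
  fr <- c(junk_fraction, contaminant_fraction, lowqual_fraction,
          adapter_only_fraction)
  if (any(fr < 0) || sum(fr) >= 1) {
    stop("composition fractions must be non-negative and sum to < 1")
  }
  if (length(stages) == 0) stop("at least one stage is required")
  if (library_depth <= 0) stop("library_depth must be positive")
  if (n_transcripts <= 0) stop("n_transcripts must be positive")
  needed <- ceiling(n_known_mirnas * (1 + group2_fraction)) +
    n_novel_mirnas + n_decoy_mirnas + n_target_pairs
  if (n_transcripts < needed) {
    stop("n_transcripts (", n_transcripts, ") too small to host ",
         needed, " planted loci")
  }
  if (group2_fraction + group3_fraction >= 1) {
    stop("group 2 + group 3 fractions must be < 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# mature length distribution: 21-24 nt dominate, mode 24 (21 nt second),
# matching typical plant small-RNA valid-read length profiles
draw_mature_lengths <- function(n, novel = FALSE) {
  if (novel) {
    lens <- 19:25
    w <- c(0.04, 0.06, 0.26, 0.12, 0.10, 0.38, 0.04)
  } else {
    lens <- 20:24
    w <- c(0.06, 0.26, 0.14, 0.12, 0.42)
  }
  sample(lens, n, replace = TRUE, prob = w)
}
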