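# Simulation of small-RNA FASTQ libraries, the degradome tag library,
# matched target expression and RT-qPCR Ct tables from a reference bundle.

stage_weights <- function(ref, stage) {
  p <- ref$profiles[ref$profiles$stage == stage, ]
  setNames(p$abundance, p$mirna)
}

#' Simulate one small-RNA sequencing library
#'
#' Read composition follows the configured fractions (adapter dimers, poly-N
#' junk, ncRNA contaminants, low-quality reads, remainder miRNA-derived).
#' miRNA read counts follow the stage expectation under the configured count
#' model: the default `"nb"` draws gamma weights (shape 1/dispersion) around
#' the expectations and then a multinomial over the library's miRNA read
#' total, giving negative-binomial-like overdispersed marginals with exact
#' category totals. Each miRNA read is the mature sequence with optional
#' 0-2 nt 3' trimming, followed by the 3' adapter and random fill to the raw
#' read length.
#'
#' @param ref a `ReferenceBundle`.
#' @param stage stage label (must appear in `ref$profiles`).
#' @param depth reads in the library.
#' @param seed random seed for this library.
#' @return data.frame with `id`, `sequence`, `quality` (Phred+33 strings)
#'   and hidden truth columns `origin` (mirna/junk/contaminant/lowqual/
#'   adapter_only) and `source_name`.
#' @export
simulate_srna_library <- function(ref, stage, depth = ref$config$library_depth,
                                  seed = 1) {
  stopifnot(inherits(ref, "ReferenceBundle"))
  cfg <- ref$config
  if (!stage %in% cfg$stages) stop("unknown stage: ", stage)
  if (depth == 0) {
    warning("depth = 0: returning an empty library")
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), origin = character(),
                      source_name = character()))
  }
  set.seed(seed)
  w <- stage_weights(ref, stage)

  p_cat <- c(adapter_only = cfg$adapter_only_fraction,
             junk = cfg$junk_fraction,
             contaminant = cfg$contaminant_fraction,
             lowqual = cfg$lowqual_fraction)
  p_cat <- c(p_cat, mirna = 1 - sum(p_cat))
  n_cat <- if (cfg$count_model == "exact") {
    nc <- round(depth * p_cat)
    nc["mirna"] <- depth - sum(nc[-length(nc)])
    nc
  } else {
    drop(rmultinom(1, depth, p_cat))
  }

  # per-miRNA counts within the miRNA compartment
  n_mir <- n_cat[["mirna"]] + n_cat[["lowqual"]]  # lowqual reads are miRNA-derived
  counts <- switch(cfg$count_model,
    nb = {
      g <- rgamma(length(w), shape = 1 / cfg$dispersion,
                  rate = 1 / (w * cfg$dispersion))
      drop(rmultinom(1, n_mir, g / sum(g)))
    },
    poisson = drop(rmultinom(1, n_mir, w / sum(w))),
    exact = {
      ct <- round(n_mir * w / sum(w))
      ct
    })
  names(counts) <- names(w)

  build_reads <- function(inserts) {
    reads <- paste0(inserts, cfg$adapter)
    short <- nchar(reads) < cfg$read_length
    fill <- vapply(pmax(cfg$read_length - nchar(reads), 0),
                   function(L) if (L > 0) random_dna(1, L) else "", "")
    substr(paste0(reads, fill), 1, cfg$read_length)
  }

  mk_quality <- function(n, low = FALSE) {
    rng <- if (low) 2:12 else 30:40
    vapply(seq_len(n), function(i) {
      phred_to_string(list(sample(rng, cfg$read_length, replace = TRUE)))[1]
    }, "")
  }

  # miRNA-derived reads (including the ones destined for low quality)
  mir_names <- rep(names(counts), counts)
  matures <- setNames(c(ref$precursors$mature), ref$precursors$name)
  ins <- matures[mir_names]
  if (cfg$count_model != "exact" && length(ins) > 0) {
    trim <- sample(0:2, length(ins), replace = TRUE, prob = c(0.8, 0.15, 0.05))
    trim <- pmin(trim, nchar(ins) - 18L)  # keep inserts >= 18 nt
    ins <- substr(ins, 1, nchar(ins) - trim)
  }
  mir_reads <- build_reads(ins)
  low_idx <- if (length(mir_reads) > 0 && n_cat[["lowqual"]] > 0) {
    sample(seq_along(mir_reads), min(n_cat[["lowqual"]], length(mir_reads)))
  } else integer(0)

  # junk: poly-N content above the filter threshold
  n_junk <- n_cat[["junk"]]
  junk_reads <- character(0)
  if (n_junk > 0) {
    junk_reads <- vapply(sample(18:25, n_junk, replace = TRUE), function(L) {
      s <- sample(c(DNA_BASES, "N"), L, replace = TRUE,
                  prob = c(rep(0.1875, 4), 0.25))
      nn <- ceiling(0.12 * L)
      if (sum(s == "N") < nn) s[sample.int(L, nn)] <- "N"
      paste(s, collapse = "")
    }, "")
    junk_reads <- build_reads(junk_reads)
  }

  # contaminants: substrings of ncRNA references
  n_cont <- n_cat[["contaminant"]]
  cont_src <- character(0); cont_reads <- character(0)
  if (n_cont > 0) {
    pick <- sample.int(nrow(ref$ncrna), n_cont, replace = TRUE)
    L <- sample(19:24, n_cont, replace = TRUE)
    cont_src <- ref$ncrna$id[pick]
    cont_reads <- vapply(seq_len(n_cont), function(i) {
      s <- ref$ncrna$sequence[pick[i]]
      st <- sample1(1:(nchar(s) - L[i] + 1))
      substr(s, st, st + L[i] - 1)
    }, "")
    cont_reads <- build_reads(cont_reads)
  }

  n_ao <- n_cat[["adapter_only"]]
  ao_reads <- if (n_ao > 0) build_reads(rep("", n_ao)) else character(0)

  seqs <- c(mir_reads, junk_reads, cont_reads, ao_reads)
  origin <- c(rep("mirna", length(mir_reads)),
              rep("junk", length(junk_reads)),
              rep("contaminant", length(cont_reads)),
              rep("adapter_only", length(ao_reads)))
  src <- c(mir_names, rep(NA_character_, length(junk_reads)), cont_src,
           rep(NA_character_, length(ao_reads)))
  origin[low_idx] <- "lowqual"

  qual <- mk_quality(length(seqs))
  if (length(low_idx) > 0) qual[low_idx] <- mk_quality(length(low_idx), low = TRUE)

  ord <- if (cfg$count_model == "exact") seq_along(seqs) else sample(seq_along(seqs))
  data.frame(id = sprintf("%s_read%06d", stage, seq_along(seqs)),
             sequence = seqs[ord], quality = qual[ord], origin = origin[ord],
             source_name = src[ord], stringsAsFactors = FALSE)
}

#' Simulate all libraries of the design
#'
#' @param ref a `ReferenceBundle`.
#' @param seed base seed; library i uses `seed * 100 + i`.
#' @param depth per-library depth (default from config).
#' @return named list of library data.frames, one per design sample.
#' @export
simulate_all_libraries <- function(ref, seed = 1,
                                   depth = ref$config$library_depth) {
  design <- library_design(ref$config)
  libs <- lapply(seq_len(nrow(design)), function(i) {
    simulate_srna_library(ref, design$stage[i], depth = depth,
                          seed = seed * 100 + i)
  })
  names(libs) <- design$sample
  libs
}

# per-transcript signal layout that produces the intended degradome category
category_signal <- function(cat) {
  switch(as.character(cat),
         "0" = list(site = 60L, decoy = 0L, dense = FALSE, sparse = 0L),
         "1" = list(site = 40L, decoy = 40L, dense = FALSE, sparse = 0L),
         # sparse singletons keep the nonzero median below the site count
         "2" = list(site = 12L, decoy = 80L, dense = FALSE, sparse = 8L),
         "3" = list(site = 3L, decoy = 80L, dense = TRUE, sparse = 0L),
         "4" = list(site = 1L, decoy = 0L, dense = FALSE, sparse = 0L))
}

#' Simulate the degradome (PARE) tag library
#'
#' For every planted target site, 20-21 nt tags whose 5' end sits at the
#' planted cleavage position (opposite miRNA position 10) are generated with
#' an abundance chosen to produce the intended category; transcripts hosting
#' category 1-3 sites additionally receive decoy peaks / dense background so
#' the tie/median structure those categories require exists. Uniform random
#' background tags are added over all transcripts at `background_rate` times
#' the total signal.
#'
#' @param ref a `ReferenceBundle`.
#' @param background_rate background tags as a fraction of signal tags.
#' @param seed random seed.
#' @return data.frame `id`, `sequence`, `transcript`, `position`, `kind`
#'   (site/decoy/dense/background).
#' @export
simulate_degradome <- function(ref, background_rate = 0.1, seed = 1) {
  stopifnot(inherits(ref, "ReferenceBundle"))
  set.seed(seed)
  tg <- ref$truth$targets
  tx <- ref$transcriptome
  bad <- tg$cleavage_pos + 20 > nchar(tx[tg$transcript]) | tg$cleavage_pos < 1
  if (any(bad)) stop("planted site coordinates outside transcript")

  rows <- list()
  tag_at <- function(transcript, pos, n, kind) {
    if (n <= 0) return(NULL)
    L <- sample(20:21, n, replace = TRUE)
    L <- pmin(L, nchar(tx[[transcript]]) - pos + 1L)
    data.frame(transcript = transcript, position = pos,
               sequence = substr(rep(tx[[transcript]], n), pos, pos + L - 1L),
               kind = kind, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(tg))) {
    sig <- category_signal(tg$intended_category[i])
    t <- tg$transcript[i]
    rows[[length(rows) + 1]] <- tag_at(t, tg$cleavage_pos[i], sig$site, "site")
    if (sig$decoy > 0) {
      # a decoy peak well away from the site
      repeat {
        dp <- sample1(30:(nchar(tx[[t]]) - 30))
        if (abs(dp - tg$cleavage_pos[i]) > 10) break
      }
      rows[[length(rows) + 1]] <- tag_at(t, dp, sig$decoy, "decoy")
    }
    if (sig$sparse > 0) {
      spos <- sample(setdiff(30:(nchar(tx[[t]]) - 30),
                             (tg$cleavage_pos[i] - 2):(tg$cleavage_pos[i] + 2)),
                     sig$sparse)
      for (dp in spos) {
        rows[[length(rows) + 1]] <- tag_at(t, dp, 1L, "sparse")
      }
    }
    if (sig$dense) {
      # dense moderate background so the nonzero median exceeds the site count
      dpos <- sample(setdiff(30:(nchar(tx[[t]]) - 30),
                             (tg$cleavage_pos[i] - 2):(tg$cleavage_pos[i] + 2)),
                     30)
      for (dp in dpos) {
        rows[[length(rows) + 1]] <- tag_at(t, dp, 4L + rpois(1, 1), "dense")
      }
    }
  }
  signal <- do.call(rbind, rows)

  n_bg <- round(background_rate * nrow(signal))
  if (n_bg > 0) {
    bt <- sample(names(tx), n_bg, replace = TRUE)
    bp <- vapply(bt, function(t) sample1(1:(nchar(tx[[t]]) - 21L)), 1L)
    rows[[length(rows) + 1]] <- data.frame(
      transcript = bt, position = bp,
      sequence = substr(tx[bt], bp, bp + sample(20:21, n_bg, TRUE) - 1L),
      kind = "background", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("deg_tag%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "sequence", "transcript", "position", "kind")]
}

#' Simulate target-transcript expression matched to the sample design
#'
#' Planted target transcripts receive the sign-inverted stage profile of
#' their guide miRNA (the canonical miRNA-target anticorrelation) on the
#' log2 scale, plus Gaussian noise; everything is returned per sample.
#'
#' @param ref a `ReferenceBundle`.
#' @param sigma replicate noise standard deviation (log2 units).
#' @param seed random seed.
#' @return matrix transcripts x samples of log2 expression.
#' @export
simulate_target_expression <- function(ref, sigma = 0.2, seed = 1) {
  set.seed(seed)
  design <- library_design(ref$config)
  tg <- ref$truth$targets
  prof <- ref$profiles
  out <- matrix(NA_real_, nrow(tg), nrow(design),
                dimnames = list(tg$transcript, design$sample))
  for (i in seq_len(nrow(tg))) {
    p <- prof[prof$mirna == tg$mirna[i], ]
    mu <- log2(p$abundance[match(design$stage, p$stage)])
    # inverted profile around its own mean
    mu <- mean(mu) - (mu - mean(mu)) + 8
    out[i, ] <- mu + rnorm(nrow(design), 0, sigma)
  }
  out
}

#' Simulate an RT-qPCR Ct table
#'
#' Ct values follow `baseline - log2(relative expression) + noise`; reference
#' genes are flat by construction.
#'
#' @param ref a `ReferenceBundle`.
#' @param mirnas miRNA names to include as targets.
#' @param reference_genes names for flat reference genes.
#' @param noise_sd Ct noise standard deviation.
#' @param seed random seed.
#' @return data.frame `sample`, `stage`, `gene`, `ct`, `is_reference`.
#' @export
simulate_ct_table <- function(ref, mirnas = NULL,
                              reference_genes = c("5S", "EF"),
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  design <- library_design(ref$config)
  if (is.null(mirnas)) {
    mirnas <- unique(ref$truth$de$mirna[ref$truth$de$expected_de])[1:4]
  }
  prof <- ref$profiles
  rows <- list()
  for (g in mirnas) {
    p <- prof[prof$mirna == g, ]
    rel <- p$abundance[match(design$stage, p$stage)] /
      p$abundance[p$stage == design$stage[1]][1]
    rows[[g]] <- data.frame(sample = design$sample, stage = design$stage,
                            gene = g,
                            ct = 25 - log2(rel) + rnorm(nrow(design), 0, noise_sd),
                            is_reference = FALSE, stringsAsFactors = FALSE)
  }
  for (g in reference_genes) {
    rows[[g]] <- data.frame(sample = design$sample, stage = design$stage,
                            gene = g,
                            ct = 18 + rnorm(nrow(design), 0, noise_sd),
                            is_reference = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
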