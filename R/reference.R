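# Synthetic reference bundle: transcriptome, miRNA catalogue, planted novel
# and decoy hairpins, contaminant references, annotation and ground truth.

FAMILY_POOL <- c(rep("miR156", 6), rep("miR166", 5), rep("miR169", 4),
                 rep("miR172", 3), rep("miR159", 3), rep("miR164", 2),
                 rep("miR160", 2), rep("miR167", 2), rep("miR171", 2),
                 rep("miR396", 2), "miR162", "miR391", "miR398", "miR397",
                 "miR827", "miR828", "miR5072", "miR2916", "miR5523",
                 "miR11602")

# family labels for n catalogued miRNAs: the named pool (with its family
# sizes) first, then distinct generic singleton families
draw_families <- function(n) {
  if (n <= length(FAMILY_POOL)) return(FAMILY_POOL[seq_len(n)])
  c(FAMILY_POOL, sprintf("miR9%03d", seq_len(n - length(FAMILY_POOL))))
}

# stage-trajectory shapes: the ageing-pathway families trend with
# development (miR156/miR166 down, miR172/miR159 up), everything else is
# overwhelmingly stable, as in real developmental small-RNA surveys
draw_shapes <- function(fam) {
  n <- length(fam)
  shp <- character(n)
  for (i in seq_len(n)) {
    shp[i] <- if (fam[i] %in% c("miR156", "miR166")) {
      sample(c("decreasing", "flat"), 1, prob = c(0.7, 0.3))
    } else if (fam[i] %in% c("miR172", "miR159")) {
      sample(c("increasing", "flat"), 1, prob = c(0.7, 0.3))
    } else if (fam[i] == "miR160") {
      "peaked"
    } else {
      sample(c("decreasing", "increasing", "peaked", "flat"), 1,
             prob = c(0.05, 0.05, 0.02, 0.88))
    }
  }
  shp
}

shape_multipliers <- function(shape, k) {
  g <- seq(-1.5, 1.5, length.out = k)
  switch(shape,
         decreasing = 2^(-g),          # 8-fold drop across stages
         increasing = 2^(g),
         peaked = 2^(1.5 - 2 * abs(g)),
         flat = rep(1, k))
}

#' Generate the synthetic reference bundle
#'
#' Builds, deterministically from `config$seed`: a transcriptome with
#' catalogued miRNA precursors embedded (group 1), matures-only insertions
#' (group 2), catalogue-only precursors (group 3), planted novel hairpins
#' (absent from the mature catalogue), single-violation decoy hairpins,
#' planted miRNA target sites (perfect reverse-complement duplexes),
#' contaminant ncRNA/repeat references, stage abundance profiles and an
#' annotation table — plus truth tables recording every planted entity.
#' All hairpins are verified with [evaluate_hairpin()] before acceptance.
#'
#' @param config a [sim_config()] object.
#' @return a `ReferenceBundle` list: `transcriptome` (named character),
#'   `precursors`, `mature_catalogue`, `ncrna`, `repeats`, `annotation`,
#'   `profiles` data.frames, `truth` list, and `config`.
#' @export
generate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- length(config$stages)

  ## --- catalogued miRNAs -------------------------------------------------
  n_known <- config$n_known_mirnas
  fam <- draw_families(n_known)
  mirna_names <- character(n_known)
  cnt <- integer(0)
  for (i in seq_len(n_known)) {
    cnt[fam[i]] <- (if (is.na(cnt[fam[i]])) 0L else cnt[fam[i]]) + 1L
    mirna_names[i] <- paste0("syn-", fam[i], letters[cnt[fam[i]]])
  }

  known <- design_hairpin_set(rep("none", n_known),
                              mature_lens = draw_mature_lengths(n_known))
  known$id <- paste0(mirna_names, "-prec")
  known$name <- mirna_names
  known$family <- fam

  n2 <- round(n_known * config$group2_fraction)
  n3 <- round(n_known * config$group3_fraction)
  grp <- rep(1L, n_known)
  grp[sample.int(n_known, n2 + n3)] <- c(rep(2L, n2), rep(3L, n3))
  known$group <- grp

  ## --- novel and decoy hairpins -----------------------------------------
  novel <- design_hairpin_set(rep("none", config$n_novel_mirnas),
                              mature_lens = draw_mature_lengths(
                                config$n_novel_mirnas, novel = TRUE))
  novel$id <- sprintf("novel%02d-prec", seq_len(nrow(novel)))
  novel$name <- sprintf("novel%02d", seq_len(nrow(novel)))
  decoy_types <- rep_len(c("stem_bulge", "mature_errors", "mature_bulge"),
                         config$n_decoy_mirnas)
  decoys <- design_hairpin_set(decoy_types,
                               mature_lens = draw_mature_lengths(
                                 config$n_decoy_mirnas, novel = TRUE))
  decoys$id <- sprintf("decoy%02d-prec", seq_len(nrow(decoys)))
  decoys$name <- sprintf("decoy%02d", seq_len(nrow(decoys)))

  ## --- contaminant references -------------------------------------------
  nc_classes <- rep_len(c("rRNA", "tRNA", "snoRNA", "snRNA"),
                        config$n_contaminant_refs)
  ncrna <- data.frame(
    id = sprintf("%s_%02d", nc_classes, seq_len(config$n_contaminant_refs)),
    class = nc_classes,
    sequence = vapply(sample(120:300, config$n_contaminant_refs,
                             replace = TRUE),
                      function(L) random_dna(1, L), ""),
    stringsAsFactors = FALSE)
  repeats <- data.frame(id = c("repeat_01", "repeat_02"),
                        class = "repeat",
                        sequence = c(random_dna(1, 220), random_dna(1, 180)),
                        stringsAsFactors = FALSE)

  ## --- transcriptome with planted loci ----------------------------------
  tx_len <- sample(600:1500, config$n_transcripts, replace = TRUE)
  tx <- vapply(tx_len, function(L) random_dna(1, L), "")
  names(tx) <- sprintf("T%04d", seq_len(config$n_transcripts))

  embed <- function(tx_seq, insert) {
    pos <- sample1(50:(nchar(tx_seq) - 49))
    list(seq = paste0(substr(tx_seq, 1, pos - 1), insert,
                      substr(tx_seq, pos, nchar(tx_seq))),
         pos = pos)
  }

  cursor <- 0L
  place <- function(insert) {
    cursor <<- cursor + 1L
    e <- embed(tx[[cursor]], insert)
    tx[[cursor]] <<- e$seq
    list(tx = names(tx)[cursor], pos = e$pos)
  }

  known$transcript <- NA_character_
  known$tx_pos <- NA_integer_
  for (i in which(known$group == 1L)) {
    p <- place(known$sequence[i])
    known$transcript[i] <- p$tx
    known$tx_pos[i] <- p$pos
  }
  for (i in which(known$group == 2L)) {       # mature only, precursor absent
    p <- place(known$mature[i])
    known$transcript[i] <- p$tx
    known$tx_pos[i] <- p$pos
  }
  novel$transcript <- NA_character_; novel$tx_pos <- NA_integer_
  for (i in seq_len(nrow(novel))) {
    p <- place(novel$sequence[i])
    novel$transcript[i] <- p$tx; novel$tx_pos[i] <- p$pos
  }
  decoys$transcript <- NA_character_; decoys$tx_pos <- NA_integer_
  for (i in seq_len(nrow(decoys))) {
    p <- place(decoys$sequence[i])
    decoys$transcript[i] <- p$tx; decoys$tx_pos[i] <- p$pos
  }

  ## --- planted cleavage targets -----------------------------------------
  # prefer developmentally regulated miRNAs as the guides
  shapes_known <- draw_shapes(fam)
  guide_pool <- order(shapes_known != "flat", decreasing = TRUE)
  guides <- guide_pool[seq_len(min(config$n_target_pairs, n_known))]
  intended <- rep_len(c(0L, 2L, 4L, 2L, 4L, 3L, 4L, 2L, 1L, 4L, 2L, 3L),
                      length(guides))
  targets <- data.frame(mirna = known$name[guides],
                        mature = known$mature[guides],
                        intended_category = intended,
                        stringsAsFactors = FALSE)
  targets$transcript <- NA_character_
  targets$site_start <- NA_integer_
  for (i in seq_len(nrow(targets))) {
    site <- revcomp(targets$mature[i])
    p <- place(site)
    targets$transcript[i] <- p$tx
    targets$site_start[i] <- p$pos
  }
  m <- nchar(targets$mature)
  targets$site_end <- targets$site_start + m - 1L
  # degradome 5' end sits opposite miRNA position 10 (from the miRNA 5' end)
  targets$cleavage_pos <- targets$site_start + m - 10L

  ## --- stage abundance profiles -----------------------------------------
  shapes <- c(shapes_known,
              sample(c("decreasing", "increasing", "flat"), nrow(novel),
                     replace = TRUE, prob = c(0.2, 0.2, 0.6)),
              rep("flat", nrow(decoys)))
  all_names <- c(known$name, novel$name, decoys$name)
  all_mature <- c(known$mature, novel$mature, decoys$mature)
  base <- exp(rnorm(length(all_names), log(300), 0.9))
  base <- pmin(pmax(base, 20), 5000)
  base[all_names %in% decoys$name] <- pmin(base[all_names %in% decoys$name], 200)
  # the libraries' modal insert length must be 24 nt (abundance-weighted,
  # after 3' isomiR trimming); boost 24-nt matures if a draw fell short
  insert_dist <- function(b) {
    L <- nchar(all_mature)
    p <- setNames(numeric(10), 16:25)
    for (tr in 0:2) {
      w <- c(0.8, 0.15, 0.05)[tr + 1]
      tb <- tapply(b * w, L - tr, sum)
      p[names(tb)] <- p[names(tb)] + tb
    }
    p / sum(p)
  }
  mult_mat <- vapply(shapes, shape_multipliers, numeric(k), k = k)
  need <- 1
  for (s in seq_len(k)) {          # the mode must hold in every stage
    pd <- insert_dist(base * mult_mat[s, ])
    if (pd["24"] > 0) {
      need <- max(need, max(pd[names(pd) != "24"]) / pd["24"] * 1.2)
    }
  }
  if (need > 1) {
    base[nchar(all_mature) == 24] <- base[nchar(all_mature) == 24] * need
  }
  prof <- do.call(rbind, lapply(seq_along(all_names), function(i) {
    data.frame(mirna = all_names[i], shape = shapes[i],
               stage = config$stages,
               abundance = base[i] * shape_multipliers(shapes[i], k),
               stringsAsFactors = FALSE)
  }))

  ## --- annotation table --------------------------------------------------
  terms <- sprintf("TERM%03d", seq_len(config$n_terms))
  annotation <- do.call(rbind, lapply(names(tx), function(t) {
    data.frame(transcript = t,
               term = sample(terms, sample1(1:4)),
               stringsAsFactors = FALSE)
  }))
  flower_tx <- targets$transcript[seq_len(ceiling(nrow(targets) * 0.75))]
  annotation <- rbind(annotation,
                      data.frame(transcript = unique(flower_tx),
                                 term = "TERM_FLOWER"))
  annotation <- unique(annotation)

  ## --- assemble ----------------------------------------------------------
  novel$family <- NA_character_
  decoys$family <- NA_character_
  prec_cols <- c("id", "name", "family", "sequence", "structure", "mfe",
                 "mature_start", "mature_end", "mature", "transcript",
                 "tx_pos")
  precursors <- rbind(
    cbind(known[, c(prec_cols, "group")], source = "catalogue"),
    cbind(novel[, prec_cols], group = NA_integer_, source = "novel"),
    cbind(decoys[, prec_cols], group = NA_integer_, source = "decoy"))
  rownames(precursors) <- NULL

  mature_catalogue <- data.frame(name = known$name, family = known$family,
                                 sequence = known$mature,
                                 precursor = known$id,
                                 stringsAsFactors = FALSE)

  # under an unsigned network, anti-correlated decreasing/increasing shapes
  # share one module; peaked profiles form their own; flat are unassigned
  modules <- data.frame(mirna = all_names, shape = shapes,
                        module = ifelse(shapes == "flat", NA_character_,
                                        ifelse(shapes == "peaked",
                                               "module_peaked",
                                               "module_monotone")),
                        stringsAsFactors = FALSE)

  truth <- list(
    known = known[, c("name", "family", "group", "mature", "transcript",
                      "tx_pos", "id", "expected_pass")],
    novel = novel[, c("name", "id", "mature", "transcript", "tx_pos",
                      "expected_pass")],
    decoys = cbind(decoys[, c("name", "id", "mature", "transcript", "tx_pos",
                              "expected_pass")],
                   violation = decoy_types),
    targets = targets,
    modules = modules,
    de = data.frame(mirna = all_names, shape = shapes,
                    expected_de = shapes != "flat",
                    stringsAsFactors = FALSE))

  structure(list(transcriptome = tx,
                 precursors = precursors,
                 mature_catalogue = mature_catalogue,
                 ncrna = ncrna,
                 repeats = repeats,
                 annotation = annotation,
                 profiles = prof,
                 truth = truth,
                 config = config),
            class = "ReferenceBundle")
}

#' Sample design table of a configuration
#'
#' @param config a [sim_config()] object.
#' @return data.frame with `sample`, `stage`, `replicate`.
#' @export
library_design <- function(config) {
  d <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                   stage = config$stages, stringsAsFactors = FALSE)
  d <- d[order(match(d$stage, config$stages), d$replicate), ]
  data.frame(sample = paste0(d$stage, "_r", d$replicate),
             stage = d$stage, replicate = d$replicate,
             stringsAsFactors = FALSE)
}
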