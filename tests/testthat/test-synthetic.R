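# Synthetic-data generator: determinism, planted structure, composition.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_transcripts = 0), "positive")
  expect_error(sim_config(library_depth = 0), "positive")
  expect_error(sim_config(stages = character(0)), "stage")
  expect_error(sim_config(junk_fraction = 0.5, contaminant_fraction = 0.6),
               "sum")
  expect_error(sim_config(n_transcripts = 5), "too small")
})

test_that("the reference bundle is deterministic in the seed, including FASTA bytes", {
  cfg <- small_config()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$transcriptome, r2$transcriptome)
  expect_identical(r1$precursors, r2$precursors)
  expect_identical(r1$truth, r2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(r1$transcriptome, f1); write_fasta(r2$transcriptome, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("planted entities satisfy the bundle invariants", {
  ref <- small_bundle()
  prec <- ref$precursors
  # every mature occurs inside its precursor at the annotated interval
  expect_identical(substr(prec$sequence, prec$mature_start, prec$mature_end),
                   prec$mature)
  # every embedded precursor occurs verbatim in exactly one transcript
  # (group-2 rows embed only the mature, so the precursor itself is absent)
  hay <- ref$transcriptome
  embedded <- prec[!is.na(prec$transcript) &
                     (is.na(prec$group) | prec$group == 1L), ]
  count_hits <- function(needle) {
    sum(vapply(hay, function(t) {
      m <- gregexpr(needle, t, fixed = TRUE)[[1]]
      sum(m > 0)
    }, numeric(1)))
  }
  for (i in seq_len(nrow(embedded))) {
    expect_equal(count_hits(embedded$sequence[i]), 1)
  }
  # group-3 precursors and their matures are absent from the transcriptome
  g3 <- prec[!is.na(prec$group) & prec$group == 3L, ]
  haycat <- paste(hay, collapse = "#")
  expect_false(any(vapply(g3$mature, grepl, logical(1), x = haycat,
                          fixed = TRUE)))
  # truth tables reference only generated entities
  expect_true(all(ref$truth$targets$transcript %in% names(hay)))
  expect_true(all(ref$truth$modules$mirna %in% prec$name))
})

test_that("planted novel hairpins pass and decoys fail the evaluator (truth consistency)", {
  ref <- small_bundle()
  expect_true(all(ref$truth$novel$expected_pass))
  expect_false(any(ref$truth$decoys$expected_pass))
  expect_setequal(unique(ref$truth$decoys$violation),
                  c("stem_bulge", "mature_errors", "mature_bulge"))
})

test_that("libraries are deterministic and FASTQ round-trips through the package reader", {
  ref <- small_bundle()
  l1 <- simulate_srna_library(ref, "VJ_I", depth = 500, seed = 7)
  l2 <- simulate_srna_library(ref, "VJ_I", depth = 500, seed = 7)
  expect_identical(l1, l2)
  fq <- tempfile(fileext = ".fq")
  write_fastq(l1, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, l1$sequence)
  expect_equal(back$quality, l1$quality)
  unlink(fq)
})

test_that("depth 0 warns and returns an empty library", {
  ref <- small_bundle()
  expect_warning(l <- simulate_srna_library(ref, "VJ_I", depth = 0), "empty")
  expect_equal(nrow(l), 0)
})

test_that("with no junk or contaminants every insert maps to a planted precursor", {
  cfg <- clean_config()
  ref <- generate_reference(cfg)
  lib <- simulate_srna_library(ref, "FI_I", depth = 1000, seed = 3)
  params <- filter_params(adapter = cfg$adapter)
  f <- filter_reads(lib$sequence, lib$quality, params)
  kept <- f$insert[f$label == "valid"]
  prec_cat <- paste(ref$precursors$sequence, collapse = "#")
  expect_true(all(vapply(unique(kept), grepl, logical(1), x = prec_cat,
                         fixed = TRUE)))
})

test_that("library composition converges to the configured fractions (3 SE at depth 1e5)", {
  ref <- small_bundle()
  cfg <- ref$config
  depth <- 1e5
  lib <- simulate_srna_library(ref, "VJ_II", depth = depth, seed = 5)
  frac <- table(lib$origin) / depth
  for (cl in c("junk", "contaminant", "adapter_only")) {
    p <- switch(cl, junk = cfg$junk_fraction,
                contaminant = cfg$contaminant_fraction,
                adapter_only = cfg$adapter_only_fraction)
    se <- sqrt(p * (1 - p) / depth)
    expect_lt(abs(frac[[cl]] - p), 3 * se)
  }
})

test_that("24 nt is the modal trimmed read length at depth 1e5", {
  ref <- small_bundle()
  lib <- simulate_srna_library(ref, "VJ_I", depth = 1e5, seed = 9)
  params <- filter_params(adapter = ref$config$adapter)
  f <- filter_reads(lib$sequence, lib$quality, params)
  lens <- nchar(f$insert[f$label == "valid"])
  tab <- table(lens)
  expect_equal(names(which.max(tab)), "24")
})

test_that("junk reads carry >10% N and contaminants are reference substrings", {
  ref <- small_bundle()
  lib <- simulate_srna_library(ref, "FD", depth = 5000, seed = 13)
  params <- filter_params(adapter = ref$config$adapter)
  tr <- trim_adapter(lib$sequence, params)
  junk <- tr$insert[lib$origin == "junk"]
  nfrac <- vapply(gregexpr("N", junk, fixed = TRUE),
                  function(m) sum(m > 0), numeric(1)) / nchar(junk)
  expect_true(all(nfrac > 0.10))
  cont <- tr$insert[lib$origin == "contaminant"]
  nc <- paste(ref$ncrna$sequence, collapse = "#")
  expect_true(all(vapply(unique(cont), grepl, logical(1), x = nc,
                         fixed = TRUE)))
})

test_that("degradome tags are deterministic, sited at the planted cleavage coordinate", {
  ref <- small_bundle()
  d1 <- simulate_degradome(ref, background_rate = 0, seed = 4)
  d2 <- simulate_degradome(ref, background_rate = 0, seed = 4)
  expect_identical(d1, d2)
  site_tags <- d1[d1$kind == "site", ]
  tg <- ref$truth$targets
  for (i in seq_len(nrow(tg))) {
    tt <- site_tags[site_tags$transcript == tg$transcript[i], ]
    expect_true(all(tt$position == tg$cleavage_pos[i]))
    # tag sequences are the transcript suffix at the cleavage position
    tx <- ref$transcriptome[[tg$transcript[i]]]
    expect_identical(tt$sequence,
                     substr(rep(tx, nrow(tt)), tt$position,
                            tt$position + nchar(tt$sequence) - 1))
  }
  # a single-tag site is planted for intended category 4
  expect_true(any(table(site_tags$transcript) == 1))
})

test_that("Ct tables follow the closed form and reference genes stay flat", {
  ref <- small_bundle()
  ct <- simulate_ct_table(ref, noise_sd = 0, seed = 2)
  refs <- ct[ct$is_reference, ]
  expect_equal(length(unique(refs$ct)), 1)
  # a two-fold expression step is a -1 Ct step
  g <- unique(ct$gene[!ct$is_reference])[1]
  prof <- ref$profiles[ref$profiles$mirna == g, ]
  gg <- ct[ct$gene == g, ]
  d_ct <- as.numeric(tapply(gg$ct, gg$stage, unique)[prof$stage])
  expect_equal(d_ct - d_ct[1],
               -log2(prof$abundance / prof$abundance[1]), tolerance = 1e-10)
})
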