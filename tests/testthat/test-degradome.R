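# Degradome mapping, duplex scoring, category classification, target calls.

test_that("tag 5' ends increment profiles at exact match starts", {
  set.seed(61)
  tx <- c(T1 = random_dna(1, 200), T2 = random_dna(1, 200))
  tag <- substr(tx[["T1"]], 100, 119)
  md <- map_degradome(c(tag, tag, "ACGTACGTACGTACGTACGT"), tx)
  expect_equal(md$profiles$T1[100], 2)
  expect_equal(sum(md$profiles$T1), 2)
  expect_equal(md$unmapped, 1L)
})

test_that("whole vs fractional accounting differ exactly by multi-mapping", {
  set.seed(62)
  shared <- random_dna(1, 20)
  tx <- c(A = paste0(random_dna(1, 50), shared, random_dna(1, 50)),
          B = paste0(random_dna(1, 30), shared, random_dna(1, 70)))
  whole <- map_degradome(shared, tx, mode = "whole")
  frac <- map_degradome(shared, tx, mode = "fractional")
  expect_equal(sum(whole$profiles$A) + sum(whole$profiles$B), 2)
  expect_equal(sum(frac$profiles$A) + sum(frac$profiles$B), 1)
})

test_that("duplex scorer reproduces hand-scored examples exactly", {
  mir <- "TGACAGAAGAGAGTGAGCACA"          # 21 nt
  perfect <- revcomp(mir)
  expect_equal(score_duplex(mir, perfect), 0)
  # G:U wobble at miRNA position 5: target base opposite position 5 becomes
  # T where the miRNA has G (here position 5 is A -> make miRNA G there)
  mir2 <- mir
  substr(mir2, 5, 5) <- "G"
  site <- revcomp(mir2)
  p <- nchar(mir2) - 5 + 1               # site position pairing miRNA pos 5
  substr(site, p, p) <- "T"
  expect_equal(score_duplex(mir2, site), 1.0)    # 0.5 wobble, doubled in seed
  # two mismatches at positions 2 and 3: 2 x (1 x 2) = 4
  site2 <- revcomp(mir)
  for (q in c(2, 3)) {
    pp <- nchar(mir) - q + 1
    b <- substr(mir, q, q)
    bad <- switch(b, A = "C", C = "A", G = "A", T = "C")
    substr(site2, pp, pp) <- bad
  }
  expect_equal(score_duplex(mir, site2), 4.0)
})

test_that("duplex scorer matches the brute-force enumeration twin", {
  set.seed(63)
  for (i in 1:25) {
    mir <- random_dna(1, sample(19:22, 1))
    site <- revcomp(mir)
    # random corruption: substitutions and occasional indels
    n_mut <- sample(0:3, 1)
    for (j in seq_len(n_mut)) {
      p <- sample(nchar(site), 1)
      substr(site, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.3) {
      p <- sample(nchar(site) - 1, 1)   # single-nt deletion in the site
      site <- paste0(substr(site, 1, p - 1), substr(site, p + 1, nchar(site)))
    }
    expect_equal(score_duplex(mir, site), brute_force_duplex(mir, site),
                 info = paste(mir, site))
  }
})

test_that("penalty is symmetric when the duplex is read from the opposite end", {
  # reversing both strands and swapping their roles presents the same
  # physical duplex with every pair at the same guide-relative position, so
  # the position-weighted penalty must be identical (note that *complementing*
  # is not a symmetry: the complement of a G:U wobble is a C:A mismatch)
  set.seed(64)
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  for (i in 1:10) {
    mir <- random_dna(1, 21)
    site <- revcomp(mir)
    p <- sample(21, 2)
    for (q in p) substr(site, q, q) <- sample(c("A", "C", "G", "T"), 1)
    expect_equal(score_duplex(mir, site),
                 score_duplex(rev_str(site), rev_str(mir)))
  }
})

test_that("category rules match the spec'd tiers on canonical profiles", {
  prof <- numeric(100); prof[10] <- 50; prof[c(20, 40, 60)] <- c(3, 2, 1)
  expect_equal(classify_category(10, prof), 0L)   # unique maximum
  prof2 <- prof; prof2[80] <- 50
  expect_equal(classify_category(10, prof2), 1L)  # tied maximum
  expect_equal(classify_category(20, prof), 2L)   # > median (2), < max
  expect_equal(classify_category(40, prof), 3L)   # at the median, > 1 read
  expect_equal(classify_category(60, prof), 4L)   # singleton
  expect_true(is.na(classify_category(5, prof)))  # no tag support
})

test_that("category assignment is total, exclusive and matches the oracle exhaustively", {
  # all profiles of length <= 6 with per-position counts <= 3
  got <- integer(0); want <- integer(0)
  for (len in 1:6) {
    grids <- as.matrix(expand.grid(rep(list(0:3), len)))
    for (r in seq_len(nrow(grids))) {
      prof <- as.numeric(grids[r, ])
      for (pos in which(prof > 0)) {
        got <- c(got, classify_category(pos, prof))
        want <- c(want, oracle_category(pos, prof))
      }
    }
  }
  expect_identical(got, want)
  expect_true(all(got %in% 0:4))   # total and exclusive assignment
})

test_that("raising the tag count at a site never increases its category", {
  set.seed(65)
  for (i in 1:200) {
    prof <- rpois(12, 1.5)
    pos <- sample(12, 1)
    prof[pos] <- max(1, prof[pos])
    c1 <- classify_category(pos, prof)
    prof2 <- prof; prof2[pos] <- prof2[pos] + sample(1:5, 1)
    c2 <- classify_category(pos, prof2)
    expect_lte(c2, c1)
  }
})

test_that("cleavage is called opposite miRNA position 10 within the evidence window", {
  set.seed(66)
  mir <- random_dna(1, 21)
  tx <- c(T1 = paste0(random_dna(1, 100), revcomp(mir), random_dna(1, 100)))
  site_start <- 101L
  expected <- site_start + 21L - 10L
  prof <- list(T1 = numeric(nchar(tx[[1]])))
  prof$T1[expected] <- 30
  aln <- data.frame(mirna = "m1", transcript = "T1", start = site_start,
                    end = site_start + 20L, score = 0)
  got <- call_targets(aln, prof, window = 1)
  expect_equal(got$cleavage_pos, expected)
  expect_equal(got$category, 0L)
  # signal only at +3 nt is outside the +-1 window: site rejected
  prof2 <- list(T1 = numeric(nchar(tx[[1]])))
  prof2$T1[expected + 3] <- 30
  expect_equal(nrow(call_targets(aln, prof2, window = 1)), 0)
})

test_that("two miRNAs sharing one site produce two cleavage records at the same coordinate", {
  set.seed(67)
  mirA <- random_dna(1, 21)
  mirB <- mirA
  substr(mirB, 18, 18) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mirA, 18, 18))[1]
  tx <- c(T1 = paste0(random_dna(1, 80), revcomp(mirA), random_dna(1, 80)))
  prof <- list(T1 = numeric(nchar(tx[[1]])))
  prof$T1[81 + 21 - 10] <- 25
  hits <- degradome_targets(c(A = mirA, B = mirB), tx, prof)
  expect_equal(nrow(hits), 2)
  expect_equal(unique(hits$cleavage_pos), 81 + 21 - 10)
  expect_setequal(hits$mirna, c("A", "B"))
})

test_that("T-plot tables are complete and conserve tag totals", {
  prof <- c(0, 3, 0, 7, 1)
  sites <- data.frame(cleavage_pos = 4L)
  tp <- tplot_data(prof, sites)
  expect_equal(nrow(tp), 5)
  expect_equal(sum(tp$count), sum(prof))
  expect_equal(which(tp$site), 4L)
  expect_equal(nrow(tplot_data(numeric(0))), 0)
})

test_that("planted cleavage sites are recovered with their intended categories", {
  pipe <- clean_pipeline()
  tg <- pipe$ref$truth$targets
  called <- pipe$degradome$targets
  m <- merge(tg, called, by = c("mirna", "transcript"),
             suffixes = c(".true", ".called"))
  expect_equal(nrow(m), nrow(tg))
  expect_equal(m$cleavage_pos.called, m$cleavage_pos.true)
  expect_equal(m$category, m$intended_category)
})
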