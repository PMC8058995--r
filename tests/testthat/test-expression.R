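# Median-reference normalization, ANOVA DE, clustering, ddCt.

test_that("the reference profile is the median over common sequences", {
  counts <- rbind(a = c(4, 16, 64), b = c(10, 0, 8), c = c(3, 5, 7))
  ref <- build_reference_profile(counts)
  expect_equal(ref[["a"]], 16)
  expect_false("b" %in% names(ref))       # zero in one sample: excluded
  expect_equal(ref[["c"]], 5)
  # with two samples the median is their mean
  ref2 <- build_reference_profile(rbind(a = c(4, 8)))
  expect_equal(ref2[["a"]], 6)
  expect_error(build_reference_profile(rbind(a = c(0, 5), b = c(2, 0))),
               "common")
})

test_that("normalizing the reference against itself is the identity", {
  set.seed(51)
  ref <- setNames(2^runif(200, 2, 10), paste0("t", 1:200))
  nl <- normalize_library(ref, ref)
  expect_equal(nl$fit$a, 0, tolerance = 1e-12)
  expect_equal(nl$fit$b, 1, tolerance = 1e-12)
  expect_equal(nl$expected, log2(ref), tolerance = 1e-12)
})

test_that("a library at exactly 4x the reference fits a=2, b=1 and recovers the reference", {
  set.seed(52)
  ref <- setNames(round(2^runif(300, 3, 11)), paste0("t", 1:300))
  nl <- normalize_library(4 * ref, ref)
  expect_equal(nl$fit$a, 2, tolerance = 1e-9)
  expect_equal(nl$fit$b, 1, tolerance = 1e-9)
  expect_equal(nl$expected, log2(ref), tolerance = 1e-9)
})

test_that("sequences outside |dLog2| < 2 are excluded from the fit but still corrected", {
  set.seed(53)
  ref <- setNames(round(2^runif(100, 4, 10)), paste0("t", 1:100))
  s <- 2 * ref
  s["t1"] <- ref[["t1"]] * 32          # dLog2 = 5 outlier
  nl <- normalize_library(s, ref)
  expect_equal(nl$fit$n_subset, 99)
  expect_equal(nl$fit$a, 1, tolerance = 1e-9)
  expect_equal(nl$fit$b, 1, tolerance = 1e-9)
  # the outlier is still normalized by the fitted line: its 32x excess
  # shrinks by the library-wide 2x shift, leaving +4 Log2 units
  expect_equal(nl$expected[["t1"]], log2(ref[["t1"]]) + 4, tolerance = 1e-9)
})

test_that("scaling a library by 2^k shifts the intercept by k and leaves output unchanged", {
  set.seed(54)
  ref <- setNames(round(2^runif(150, 4, 10)), paste0("t", 1:150))
  base <- normalize_library(ref, ref)
  for (k in c(1, 3)) {
    nl <- normalize_library(ref * 2^k, ref)
    expect_equal(nl$fit$a - base$fit$a, k, tolerance = 1e-9)
    expect_equal(nl$fit$b, 1, tolerance = 1e-9)
    expect_equal(nl$expected, base$expected, tolerance = 1e-9)
  }
})

test_that("vectorized ANOVA matches stats::oneway.test to 1e-10 on random matrices", {
  set.seed(55)
  stages <- rep(paste0("s", 1:5), each = 3)
  for (rep_i in 1:4) {
    X <- matrix(rnorm(25 * 15), 25, 15,
                dimnames = list(paste0("m", 1:25), NULL))
    de <- anova_de(X, stages)
    for (i in seq_len(nrow(X))) {
      ow <- oneway.test(X[i, ] ~ factor(stages), var.equal = TRUE)
      expect_equal(de$F[i], unname(ow$statistic), tolerance = 1e-10)
      expect_equal(de$p[i], unname(ow$p.value), tolerance = 1e-10)
    }
  }
})

test_that("a planted stage shift is significant and its p matches a permutation oracle", {
  set.seed(56)
  stages <- rep(paste0("s", 1:5), each = 3)
  mu <- rep(seq(0, 2, length.out = 5), each = 3)   # 4-fold Log2 ramp
  x <- mu + rnorm(15, 0, 0.2)
  de <- anova_de(matrix(x, 1), stages)
  expect_true(de$significant)
  # permutation distribution of F
  n_perm <- 10000
  Fs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Fs[b] <- anova_de(matrix(sample(x), 1), stages)$F
  }
  p_perm <- (sum(Fs >= de$F) + 1) / (n_perm + 1)
  # both declare overwhelming significance; permutation granularity bounds
  expect_lt(de$p, 1e-4)
  expect_lt(p_perm, 5 / n_perm)
})

test_that("constant rows get F = 0 and p = 1 by convention", {
  stages <- rep(c("a", "b"), each = 3)
  de <- anova_de(matrix(5, 2, 6), stages)
  expect_equal(de$F, c(0, 0))
  expect_equal(de$p, c(1, 1))
  expect_false(any(de$significant))
})

test_that("null miRNAs are called significant at about the nominal 5% rate", {
  set.seed(57)
  stages <- rep(paste0("s", 1:5), each = 3)
  X <- matrix(rnorm(2000 * 15, 0, 0.2), 2000, 15)
  de <- anova_de(X, stages)
  expect_gt(mean(de$significant), 0.035)
  expect_lt(mean(de$significant), 0.065)
})

test_that("profile clustering separates planted decreasing/increasing/flat trios", {
  dec <- c(4, 3, 2, 1, 0); inc <- rev(dec); pk <- c(0, 2, 4, 2, 0)
  X <- rbind(d1 = dec, d2 = dec + 0.01, d3 = dec * 2,
             i1 = inc, i2 = inc + 0.1, i3 = inc * 1.5,
             p1 = pk, p2 = pk * 2, p3 = pk + 0.05)
  cl <- hierarchical_cluster(X, k = 3)
  expect_equal(length(unique(cl$class[1:3])), 1)
  expect_equal(length(unique(cl$class[4:6])), 1)
  expect_equal(length(unique(cl$class[7:9])), 1)
  expect_equal(length(unique(cl$class)), 3)
  # identical profiles merge at height 0; anticorrelated at distance 2
  d <- 1 - cor(t(X[c("d1", "d3", "i1"), ]))
  expect_equal(d["d1", "d3"], 0, tolerance = 1e-9)
  expect_equal(d["d1", "i1"], 2, tolerance = 1e-9)
})

test_that("ddct returns 1 at the calibrator and 2 for ddCt = -1", {
  ct <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   ct = c(24, 20, 23, 20))
  out <- ddct(ct, reference_genes = "ref", calibrator = "s1")
  expect_equal(out$rel_expr[out$sample == "s1"], 1)
  expect_equal(out$rel_expr[out$sample == "s2"], 2)  # ddCt = -1
})

test_that("averaging Cts of two reference genes equals the geometric-mean normalizer", {
  ct <- data.frame(sample = rep(c("s1", "s2"), each = 3),
                   gene = rep(c("tgt", "r1", "r2"), 2),
                   ct = c(25, 20, 22, 24, 20.5, 21.5))
  out <- ddct(ct, reference_genes = c("r1", "r2"), calibrator = "s1")
  # geometric mean of 2^-Ct normalizers == arithmetic mean of Cts
  norm1 <- sqrt(2^-20 * 2^-22); norm2 <- sqrt(2^-20.5 * 2^-21.5)
  rel <- (2^-24 / norm2) / (2^-25 / norm1)
  expect_equal(out$rel_expr[out$sample == "s2"], rel, tolerance = 1e-12)
})
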