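# Cross-library normalization against a median reference, one-way ANOVA
# differential expression, profile clustering, and the 2^-ddCt utility.
#
# Normalization: a reference profile is the per-sequence median copy number
# over sequences detected in every sample ("common sequences"). Each sample
# is regressed (OLS) on the reference over the subset with |dLog2| < 2 and
# corrected by inverting the fitted line, giving "expected Log2(copy#)".

log2p <- function(x, pseudocount = 1) log2(pmax(x, pseudocount))

#' Build the median reference profile
#'
#' @param counts miRNA x sample matrix of raw copy numbers.
#' @return named numeric vector: per-sequence median copy number over the
#'   common (nonzero in every sample) sequences.
#' @export
build_reference_profile <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("at least 2 samples are required")
  common <- rowSums(counts > 0) == ncol(counts)
  if (!any(common)) stop("no common sequences across samples; cannot build reference")
  apply(counts[common, , drop = FALSE], 1, median)
}

#' Normalize one library against the reference
#'
#' Fits `Log2(sample) = a + b * Log2(reference)` by OLS over the common
#' sequences whose Log2 difference from the reference lies within
#' `delta_max` of the bulk (median) difference, then maps every sequence to
#' its expected Log2 copy number `(Log2(obs) - a) / b`. Centering the
#' subset window on the median difference keeps the rule scale-invariant:
#' a uniformly rescaled library still fits on its full common set, and only
#' sequences deviating from the bulk shift are dropped.
#'
#' @param sample_counts named vector of raw counts.
#' @param reference [build_reference_profile()] output.
#' @param pseudocount floor applied inside the log (zeros only, default 1).
#' @param delta_max subset rule half-width (Log2 units).
#' @param method `"regression"` (invert the OLS line) or `"offset"` (mean
#'   Log2 difference only, slope fixed at 1).
#' @return list `expected` (named vector, expected Log2 copy numbers for all
#'   sequences), `fit` (intercept `a`, slope `b`, `n_subset`, `flagged`).
#' @export
normalize_library <- function(sample_counts, reference, pseudocount = 1,
                              delta_max = 2,
                              method = c("regression", "offset")) {
  method <- match.arg(method)
  common <- intersect(names(sample_counts), names(reference))
  s <- log2p(sample_counts[common], pseudocount)
  r <- log2p(reference[common], pseudocount)
  delta <- s - r
  sub <- abs(delta - median(delta)) < delta_max
  n_sub <- sum(sub)
  flagged <- n_sub < 10
  if (n_sub < 2 || var(r[sub]) == 0) {
    warning("degenerate normalization fit; applying identity correction")
    a <- 0; b <- 1
  } else if (method == "offset") {
    a <- mean(s[sub] - r[sub]); b <- 1
  } else {
    fit <- lm(s[sub] ~ r[sub])
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    if (!is.finite(b) || abs(b) < 1e-8) {
      warning("degenerate normalization fit; applying identity correction")
      a <- 0; b <- 1
    }
  }
  expected <- (log2p(sample_counts, pseudocount) - a) / b
  list(expected = expected,
       fit = list(a = a, b = b, n_subset = n_sub, flagged = flagged))
}

#' Normalize a whole count matrix to expected Log2 copy numbers
#'
#' @param counts miRNA x sample matrix of raw copy numbers.
#' @inheritParams normalize_library
#' @return list `expr` (expected Log2 matrix), `fits` (per-sample a/b table),
#'   `reference`.
#' @export
normalize_counts <- function(counts, pseudocount = 1, delta_max = 2,
                             method = "regression") {
  counts <- as.matrix(counts)
  reference <- build_reference_profile(counts)
  expr <- matrix(NA_real_, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  fits <- data.frame(sample = colnames(counts), a = NA_real_, b = NA_real_,
                     n_subset = NA_integer_, flagged = NA)
  for (j in seq_len(ncol(counts))) {
    nl <- normalize_library(setNames(counts[, j], rownames(counts)),
                            reference, pseudocount, delta_max, method)
    expr[, j] <- nl$expected
    fits$a[j] <- nl$fit$a; fits$b[j] <- nl$fit$b
    fits$n_subset[j] <- nl$fit$n_subset; fits$flagged[j] <- nl$fit$flagged
  }
  list(expr = expr, fits = fits, reference = reference)
}

#' One-way ANOVA differential expression across stages
#'
#' Classic fixed-effects one-way ANOVA per miRNA on expected Log2 values,
#' computed by vectorized sums of squares. Significance follows the raw
#' p <= `alpha` rule; BH-adjusted q-values are reported alongside.
#'
#' @param expr miRNA x sample matrix (expected Log2 scale).
#' @param stages character/factor of stage per sample (length ncol(expr)).
#' @param alpha significance threshold on the raw p-value.
#' @return data.frame: `mirna`, per-stage means, `F`, `p`, `q`,
#'   `significant`.
#' @export
anova_de <- function(expr, stages, alpha = 0.05) {
  expr <- as.matrix(expr)
  stages <- factor(stages, levels = unique(stages))
  if (nlevels(stages) < 2) stop("at least 2 stages are required")
  if (min(table(stages)) < 2) stop("at least 2 replicates per stage are required")
  N <- ncol(expr); k <- nlevels(stages)
  G <- model.matrix(~ 0 + stages)            # samples x stages indicator
  n_g <- colSums(G)
  sums <- expr %*% G
  means <- sweep(sums, 2, n_g, "/")
  grand <- rowMeans(expr)
  ssb <- rowSums(sweep(means - grand, 2, n_g, "*") * (means - grand))
  sst <- rowSums((expr - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(Fst, k - 1, N - k, lower.tail = FALSE)
  # all-equal rows: 0/0 -> no evidence of change
  degenerate <- ssb < 1e-300 & ssw < 1e-300
  Fst[degenerate] <- 0
  p[degenerate] <- 1
  colnames(means) <- paste0("mean_", levels(stages))
  out <- data.frame(mirna = rownames(expr) %||% seq_len(nrow(expr)), means,
                    F = Fst, p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  out
}

#' Cluster differential expression profiles
#'
#' Average-linkage hierarchical clustering of z-scored stage means under
#' correlation distance, cut into `k` profile classes.
#'
#' @param stage_means miRNA x stage matrix (e.g. the mean columns of
#'   [anova_de()] restricted to significant miRNAs).
#' @param k number of profile classes.
#' @return list `class` (named integer vector), `order` (leaf order),
#'   `hclust`.
#' @export
hierarchical_cluster <- function(stage_means, k = 3) {
  stage_means <- as.matrix(stage_means)
  if (nrow(stage_means) < k) k <- nrow(stage_means)
  z <- t(scale(t(stage_means)))
  z[is.na(z)] <- 0                      # constant profiles: zero vector
  d <- 1 - cor(t(z))
  d[is.na(d)] <- 1
  hc <- hclust(as.dist(d), method = "average")
  cls <- cutree(hc, k = k)
  list(class = cls, order = hc$order, hclust = hc)
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct(target) - mean Ct(reference genes); ddCt = dCt(sample) -
#' dCt(calibrator); relative expression = 2^-ddCt, so the calibrator sample
#' is exactly 1.
#'
#' @param ct data.frame with `sample`, `gene`, `ct` (and optionally
#'   `is_reference`).
#' @param reference_genes reference (housekeeping) gene names.
#' @param calibrator sample name whose expression is set to 1.
#' @return data.frame `sample`, `gene`, `dct`, `ddct`, `rel_expr`.
#' @export
ddct <- function(ct, reference_genes, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (!calibrator %in% ct$sample) stop("calibrator sample not found")
  refs <- ct[ct$gene %in% reference_genes, ]
  if (nrow(refs) == 0) stop("no reference gene rows found")
  ref_ct <- tapply(refs$ct, refs$sample, mean)
  tg <- ct[!ct$gene %in% reference_genes, ]
  tg$dct <- tg$ct - ref_ct[tg$sample]
  cal <- tg[tg$sample == calibrator, ]
  tg$ddct <- tg$dct - cal$dct[match(tg$gene, cal$gene)]
  tg$rel_expr <- 2^(-tg$ddct)
  rownames(tg) <- NULL
  tg[, c("sample", "gene", "dct", "ddct", "rel_expr")]
}
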