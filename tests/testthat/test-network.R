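# Coexpression network: adjacency/TOM, soft threshold, modules, subnetwork,
# enrichment.

make_module_expr <- function(n_modules = 3, size = 20, n_samples = 15,
                             sigma = 0.1, seed = 71) {
  set.seed(seed)
  seeds <- matrix(rnorm(n_modules * n_samples), n_modules)
  X <- do.call(rbind, lapply(seq_len(n_modules), function(g) {
    matrix(rep(seeds[g, ], each = size), size) +
      matrix(rnorm(size * n_samples, 0, sigma), size)
  }))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  list(expr = X, truth = rep(seq_len(n_modules), each = size))
}

test_that("miRNA-target correlation flags perfect anticorrelation and planted pairs", {
  set.seed(72)
  prof <- matrix(rnorm(30), 2, 15, dimnames = list(c("m1", "m2"), NULL))
  tgt <- rbind(t1 = -prof["m1", ], t2 = prof["m2", ])
  pairs <- data.frame(mirna = c("m1", "m2"), transcript = c("t1", "t2"))
  pc <- correlate_pairs(prof, tgt, pairs)
  expect_equal(pc$r, c(-1, 1), tolerance = 1e-12)
  expect_equal(pc$negative, c(TRUE, FALSE))
  # planted inverse pairs with noise are flagged negative almost always
  hits <- 0
  for (i in 1:100) {
    x <- rnorm(15)
    y <- -x + rnorm(15, 0, 0.2)
    hits <- hits + (cor(x, y) < 0)
  }
  expect_gte(hits, 95)
})

test_that("TOM matches the brute-force triple loop to 1e-12 on 10-node instances", {
  set.seed(73)
  for (rep_i in 1:3) {
    X <- matrix(rnorm(10 * 12), 10, 12,
                dimnames = list(paste0("n", 1:10), NULL))
    net <- build_network(X, network_params(beta = 6))
    A <- net$adjacency
    n <- nrow(A)
    k <- rowSums(A) - 1
    tom_bf <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l_ij <- 0
      for (u in 1:n) if (u != i && u != j) l_ij <- l_ij + A[i, u] * A[u, j]
      tom_bf[i, j] <- (l_ij + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    expect_equal(net$tom, tom_bf, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("perfectly correlated nodes have adjacency and TOM of 1, uncorrelated near 0", {
  x <- rnorm(12)
  X <- rbind(a = x, b = 2 * x + 3)
  net <- build_network(X, network_params(beta = 12))
  expect_equal(net$adjacency["a", "b"], 1, tolerance = 1e-12)
  expect_equal(net$tom["a", "b"], 1, tolerance = 1e-12)
  set.seed(74)
  Y <- matrix(rnorm(2 * 30), 2, 30, dimnames = list(c("u", "v"), NULL))
  net2 <- build_network(Y, network_params(beta = 12))
  expect_lt(net2$adjacency["u", "v"], 0.01)
})

test_that("soft-threshold selection behaves on degenerate, random and singleton inputs", {
  # exactly block-diagonal correlation (orthogonal module seeds, no noise):
  # every power is trivially at the fit maximum; smallest candidate wins
  set.seed(75)
  seeds <- qr.Q(qr(cbind(1, matrix(rnorm(15 * 3), 15, 3))))[, 2:4]
  X0 <- do.call(rbind, lapply(1:3, function(g) {
    matrix(rep(seeds[, g], each = 20), 20, byrow = FALSE)
  }))
  rownames(X0) <- paste0("g", seq_len(nrow(X0)))
  ps <- pick_soft_threshold(X0, powers = c(2, 4, 6), rsq_target = 0.5)
  expect_equal(ps$beta, 2)
  # pure noise: no power reaches the target; default returned with warning
  set.seed(76)
  Z <- matrix(rnorm(40 * 15), 40, 15)
  expect_warning(ps2 <- pick_soft_threshold(Z, powers = c(1, 2),
                                            rsq_target = 0.999), "default")
  expect_equal(ps2$beta, 12)
  # a single candidate power is returned as-is when it qualifies
  ps3 <- pick_soft_threshold(X0, powers = 12, rsq_target = 0.5)
  expect_equal(ps3$beta, 12)
})

test_that("three planted modules are recovered with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  me <- make_module_expr(n_modules = 3, size = 20, sigma = 0.1)
  net <- build_network(me$expr, network_params(beta = 12))
  mod <- detect_modules(net)
  ari <- mclust::adjustedRandIndex(mod$module, me$truth)
  expect_gte(ari, 0.9)
  expect_equal(length(setdiff(unique(mod$module), "grey")), 3)
})

test_that("identical expression collapses to a single module", {
  x <- rnorm(15)
  X <- matrix(rep(x, each = 12), 12, 15,
              dimnames = list(paste0("g", 1:12), NULL))
  X <- X + matrix(rnorm(12 * 15, 0, 1e-6), 12, 15)
  net <- build_network(X, network_params(beta = 6, min_module_size = 5))
  mod <- detect_modules(net)
  expect_equal(length(setdiff(unique(mod$module), "grey")), 1)
})

test_that("eigengenes explain at least as much variance as any member profile", {
  me <- make_module_expr(n_modules = 1, size = 15, sigma = 0.3, seed = 77)
  net <- build_network(me$expr, network_params(beta = 6))
  mod <- detect_modules(net)
  eg <- mod$eigengenes[, 1]
  Z <- t(scale(t(me$expr)))            # genes x samples, z-scored
  var_expl <- function(v) {
    v <- v / sqrt(sum(v^2))
    sum((Z %*% v)^2)
  }
  best_member <- max(apply(Z, 1, var_expl))
  expect_gte(var_expl(eg) + 1e-9, best_member)
})

test_that("subnetwork extraction respects the edge floor and finds planted hubs", {
  me <- make_module_expr(n_modules = 2, size = 12, sigma = 0.2, seed = 78)
  net <- build_network(me$expr, network_params(beta = 6))
  sub <- extract_subnetwork(net, seeds = "g1", floor = 0.1)
  expect_true(all(sub$edges$weight >= 0.1))
  expect_true(all(sub$edges$node1 == "g1" | sub$edges$node2 == "g1"))
  # floor 1 keeps only perfect edges; empty seeds give an empty list
  expect_equal(nrow(extract_subnetwork(net, "g1", floor = 1)$edges), 0)
  expect_equal(nrow(extract_subnetwork(net, character(0))$edges), 0)
  # the hub with most strong neighbours tops the degree report
  sub2 <- extract_subnetwork(net, seeds = rownames(me$expr), floor = 0.2)
  expect_true(names(sub2$degree)[1] %in% rownames(me$expr))
  expect_gte(sub2$degree[[1]], max(sub2$degree))
})

test_that("hypergeometric enrichment equals the exact tail sum to 1e-12", {
  ann <- data.frame(
    transcript = c(paste0("g", 1:20)),
    term = rep(c("A", "B"), c(6, 14)))
  res <- enrich(paste0("g", 1:6), ann)
  rowA <- res[res$term == "A", ]
  # exact tail sum over the hypergeometric support
  tail_sum <- sum(vapply(rowA$k:min(rowA$n, rowA$K), function(x) {
    choose(rowA$K, x) * choose(rowA$N - rowA$K, rowA$n - x) /
      choose(rowA$N, rowA$n)
  }, numeric(1)))
  expect_equal(rowA$p, tail_sum, tolerance = 1e-12)
  # the all-of-one-term set is maximally enriched
  expect_equal(rowA$k, 6L)
  expect_lt(rowA$p, res$p[res$term == "B"])
  # empty set -> empty result; absent term -> skipped with warning
  expect_equal(nrow(enrich(character(0), ann)), 0)
  expect_warning(enrich("g1", rbind(ann, data.frame(transcript = "zz",
                                                    term = "C")),
                        background = paste0("g", 1:20)), "skipping")
})

test_that("adjacency and TOM stay within bounds and symmetric on pipeline output", {
  pipe <- clean_pipeline()
  net <- pipe$network$network
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_true(all(net$tom >= 0 & net$tom <= 1))
  expect_equal(net$adjacency, t(net$adjacency), tolerance = 1e-12)
  mods <- pipe$network$modules$module
  truth <- pipe$ref$truth$modules
  mono <- truth$mirna[!is.na(truth$module) &
                        truth$module == "module_monotone"]
  mono <- intersect(mono, names(mods))
  # all monotone-profile miRNAs land together in one detected module
  expect_equal(length(unique(mods[mono])), 1)
  expect_true(unique(mods[mono]) != "grey")
})
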