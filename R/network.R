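# Weighted coexpression network over miRNA expression: soft-thresholded
# adjacency |cor|^beta, topological overlap, module detection by
# average-linkage clustering with a static cut and eigengene merging,
# subnetwork extraction and hypergeometric set enrichment.

#' Parameters of the coexpression network
#'
#' @param beta soft-threshold power applied to |correlation|.
#' @param rsq_target scale-free fit R^2 target for [pick_soft_threshold()].
#' @param min_module_size modules smaller than this become unassigned (grey).
#' @param merge_height modules whose eigengenes correlate above
#'   `1 - merge_height` are merged.
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram.
#' @return a `network_params` list.
#' @export
network_params <- function(beta = 12, rsq_target = 0.8, min_module_size = 10,
                           merge_height = 0.25, cut_height = 0.99) {
  stopifnot(beta >= 1)
  structure(list(beta = beta, rsq_target = rsq_target,
                 min_module_size = min_module_size,
                 merge_height = merge_height, cut_height = cut_height),
            class = "network_params")
}

MODULE_COLOURS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue")

#' Correlate miRNA and target expression over matched samples
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param target_expr transcript x sample matrix (same samples).
#' @param pairs data.frame with `mirna`, `transcript`.
#' @param negative_threshold correlations below this are flagged negative.
#' @return `pairs` with `r` and `negative` columns.
#' @export
correlate_pairs <- function(mirna_expr, target_expr, pairs,
                            negative_threshold = 0) {
  stopifnot(ncol(mirna_expr) == ncol(target_expr))
  pairs$r <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna[i]; t <- pairs$transcript[i]
    if (m %in% rownames(mirna_expr) && t %in% rownames(target_expr)) {
      pairs$r[i] <- cor(mirna_expr[m, ], target_expr[t, ])
    }
  }
  pairs$negative <- !is.na(pairs$r) & pairs$r < negative_threshold
  pairs
}

# scale-free topology fit of a connectivity vector: R^2 (and slope) of
# log10 p(k) ~ log10 k over 10 connectivity bins
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) == 0) return(list(rsq = NA_real_, slope = NA_real_))
  # a (near) point-mass connectivity distribution makes the log-log fit
  # vacuous: every power is trivially at the fit's maximum
  if (diff(range(k)) <= 1e-8 * (mean(k) + 1)) {
    return(list(rsq = 1, slope = NA_real_))
  }
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  kmean <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(rsq = NA_real_, slope = NA_real_))
  x <- log10(kmean[ok]); y <- log10(freq[ok] / sum(freq[ok]))
  fit <- lm(y ~ x)
  list(rsq = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Choose the soft-threshold power
#'
#' Evaluates candidate powers and picks the smallest whose scale-free fit
#' R^2 (with negative slope) reaches the target; if none qualifies the
#' default (12) is returned with a warning.
#'
#' @param expr gene x sample matrix.
#' @param powers candidate powers.
#' @param rsq_target required fit R^2.
#' @param default power returned when no candidate reaches the target.
#' @return list `beta`, `fit_table` (power, rsq, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                rsq_target = 0.8, default = 12) {
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  ft <- do.call(rbind, lapply(powers, function(b) {
    k <- rowSums(ac^b)
    sf <- scale_free_fit(k)
    data.frame(power = b, rsq = sf$rsq, slope = sf$slope, mean_k = mean(k))
  }))
  ok <- !is.na(ft$rsq) & ft$rsq >= rsq_target &
    (is.na(ft$slope) | ft$slope < 0)
  if (any(ok)) {
    beta <- ft$power[which(ok)[1]]
  } else {
    warning("no candidate power reaches the scale-free fit target; ",
            "using default ", default)
    beta <- default
  }
  list(beta = beta, fit_table = ft)
}

#' Build the weighted coexpression network
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^beta` (unsigned, unit diagonal) and the
#' topological overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the connectivity (off-diagonal row sums), `TOM_ii = 1`.
#'
#' @param expr gene x sample matrix.
#' @param params [network_params()].
#' @return list `adjacency`, `tom`, `k`, `params`, class
#'   `CoexpressionNetwork`.
#' @export
build_network <- function(expr, params = network_params()) {
  expr <- as.matrix(expr)
  A <- abs(cor(t(expr)))^params$beta
  A[is.na(A)] <- 0
  diag(A) <- 1
  k <- rowSums(A) - 1
  M <- A %*% A
  Lmat <- M - 2 * A          # sum over u != i,j of a_iu a_uj (unit diagonal)
  kmin <- outer(k, k, pmin)
  tom <- (Lmat + A) / (kmin + 1 - A)
  diag(tom) <- 1
  stopifnot(all(tom >= -1e-12), all(tom <= 1 + 1e-12),
            max(abs(tom - t(tom))) < 1e-10)
  tom <- pmin(pmax(tom, 0), 1)
  structure(list(adjacency = A, tom = tom, k = k, expr = expr,
                 params = params), class = "CoexpressionNetwork")
}

module_eigengene <- function(expr_module) {
  # expr_module: genes x samples; eigengene = first PC of the standardized
  # profiles, signed to correlate positively with the mean profile
  X <- t(scale(t(expr_module)))        # z-score each gene
  X[is.na(X)] <- 0
  sv <- svd(t(X), nu = 1, nv = 0)
  e <- sv$u[, 1]
  mp <- colMeans(X)
  if (sum(e * mp) < 0) e <- -e
  e
}

#' Detect coexpression modules
#'
#' Average-linkage clustering of `1 - TOM`, static cut at
#' `params$cut_height`, removal of modules below the minimum size (grey),
#' and iterative merging of modules whose eigengenes correlate above
#' `1 - params$merge_height`. Module colour names are assigned by
#' descending size following the usual coexpression-network palette.
#'
#' @param network a `CoexpressionNetwork`.
#' @param params [network_params()] (defaults to the network's own).
#' @return list `module` (named colour per gene), `eigengenes` (sample x
#'   module matrix), `hclust`.
#' @export
detect_modules <- function(network, params = network$params) {
  tom <- network$tom
  expr <- network$expr
  hc <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < params$min_module_size])] <- 0L

  merge_once <- function(cl) {
    ids <- setdiff(unique(cl), 0L)
    if (length(ids) < 2) return(cl)
    eg <- sapply(ids, function(g) {
      module_eigengene(expr[cl == g, , drop = FALSE])
    })
    cc <- cor(eg)
    diag(cc) <- 0
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) > 1 - params$merge_height) {
      cl[cl == ids[mx[2]]] <- ids[mx[1]]
      return(merge_once(cl))
    }
    cl
  }
  cl <- merge_once(cl)

  ids <- setdiff(unique(cl), 0L)
  ids <- ids[order(-tabulate(match(cl, ids)))]
  colour <- setNames(rep("grey", length(cl)), rownames(expr))
  for (i in seq_along(ids)) {
    colour[cl == ids[i]] <- MODULE_COLOURS[min(i, length(MODULE_COLOURS))]
  }
  mods <- setdiff(unique(colour), "grey")
  eigengenes <- sapply(mods, function(m) {
    module_eigengene(expr[colour == m, , drop = FALSE])
  })
  if (length(mods) > 0) {
    eigengenes <- matrix(eigengenes, ncol = length(mods),
                         dimnames = list(colnames(expr), mods))
  }
  list(module = colour, eigengenes = eigengenes, hclust = hc)
}

#' Extract the subnetwork around seed nodes
#'
#' @param network a `CoexpressionNetwork`.
#' @param seeds node names of interest (e.g. DE miRNAs).
#' @param floor minimum TOM edge weight.
#' @return list `edges` (node1, node2, weight) and `degree` (per-node edge
#'   count, descending — hub report).
#' @export
extract_subnetwork <- function(network, seeds, floor = 0.1) {
  tom <- network$tom
  nodes <- rownames(tom)
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) {
    return(list(edges = data.frame(node1 = character(), node2 = character(),
                                   weight = numeric()),
                degree = integer(0)))
  }
  idx <- which(upper.tri(tom), arr.ind = TRUE)
  w <- tom[idx]
  n1 <- nodes[idx[, 1]]; n2 <- nodes[idx[, 2]]
  keep <- w >= floor & (n1 %in% seeds | n2 %in% seeds)
  edges <- data.frame(node1 = n1[keep], node2 = n2[keep], weight = w[keep],
                      stringsAsFactors = FALSE)
  deg <- sort(table(c(edges$node1, edges$node2)), decreasing = TRUE)
  list(edges = edges, degree = deg)
}

#' Hypergeometric set enrichment against a local annotation table
#'
#' Upper-tail hypergeometric p per term (probability of at least the
#' observed overlap), BH-adjusted across terms.
#'
#' @param gene_set character vector of genes of interest.
#' @param annotation data.frame with `transcript` (gene) and `term`.
#' @param background character vector of background genes (default: all
#'   annotated genes).
#' @return data.frame `term`, `k` (hits), `n` (set size in background),
#'   `K` (term size), `N` (background), `p`, `q`.
#' @export
enrich <- function(gene_set, annotation, background = NULL) {
  if (is.null(background)) background <- unique(annotation$transcript)
  all_terms <- unique(annotation$term)
  annotation <- annotation[annotation$transcript %in% background, ,
                           drop = FALSE]
  dropped <- setdiff(all_terms, unique(annotation$term))
  if (length(dropped) > 0) {
    warning("skipping term(s) with no member in the background: ",
            paste(dropped, collapse = ", "))
  }
  set <- intersect(unique(gene_set), background)
  N <- length(unique(background))
  n <- length(set)
  if (n == 0) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  }
  terms <- unique(annotation$term)
  res <- do.call(rbind, lapply(terms, function(tm) {
    members <- unique(annotation$transcript[annotation$term == tm])
    K <- length(members)
    kk <- length(intersect(set, members))
    p <- phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = kk, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, "BH")
  res[order(res$p), ]
}
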