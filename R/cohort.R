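#' Transformation specification for clustering/PCA
#'
#' The figures' preprocessing recipe: optional log2 with a positive floor
#' (net values at or below the floor map to `log2(floor)`), then per-probe
#' mean centering and optionally scaling by the per-probe standard
#' deviation (Z-scores).
#'
#' @param log2 Apply log2 after flooring.
#' @param floor Floor in signal units (must be > 0 when `log2 = TRUE`;
#'   1 unit by default so floored background maps to 0).
#' @param center,scale Per-probe centering/scaling flags.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(log2 = TRUE, floor = 1, center = TRUE,
                           scale = TRUE) {
  if (log2) .assert(floor > 0, "floor must be > 0 when log2 is applied")
  structure(list(log2 = log2, floor = floor, center = center, scale = scale),
            class = "transform_spec")
}

#' Apply a transformation spec to an expression matrix
#'
#' @param x Numeric matrix (samples x probes) or [expression_matrix()].
#' @param spec A [transform_spec()].
#' @return Transformed numeric matrix; probes with zero variance under
#'   scaling become all-zero columns and are listed in the `zero_sd`
#'   attribute.
#' @export
transform_expression <- function(x, spec = transform_spec()) {
  if (inherits(x, "expression_matrix")) x <- x$values
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  if (spec$log2) x <- log2(pmax(x, spec$floor))
  zero_sd <- character(0)
  if (spec$center) x <- sweep(x, 2, colMeans(x), `-`)
  if (spec$scale) {
    sds <- apply(x, 2, stats::sd)
    zero <- sds == 0 | !is.finite(sds)
    sds[zero] <- 1
    x <- sweep(x, 2, sds, `/`)
    if (any(zero)) {
      x[, zero] <- 0
      zero_sd <- colnames(x)[zero] %||% as.character(which(zero))
    }
  }
  attr(x, "zero_sd") <- zero_sd
  x
}

#' Kendall rank-correlation distance
#'
#' `d = 1 - tau_b` between items (rows for the sample axis, columns for the
#' gene axis); tau-b is the tie-corrected Kendall coefficient, so the
#' distance is invariant under strictly monotone transforms of the
#' features and lies in `[0, 2]`.
#'
#' @param x Numeric matrix (samples x probes) or [expression_matrix()].
#' @param axis `"samples"` or `"genes"`.
#' @return A `stats::dist` object.
#' @export
kendall_distance <- function(x, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  if (inherits(x, "expression_matrix")) x <- x$values
  if (axis == "samples") x <- t(x)   # cor() correlates columns
  .assert(ncol(x) >= 2, "need >= 2 items")
  .assert(nrow(x) >= 2, "feature vectors must have length >= 2")
  tau <- stats::cor(x, method = "kendall")
  tau[!is.finite(tau)] <- 0          # constant feature vectors carry no ranks
  d <- 1 - tau
  diag(d) <- 0
  stats::as.dist(d)
}

#' Agglomerative hierarchical clustering with Ward linkage
#'
#' Lance-Williams agglomeration with the two Ward variants: `ward_d`
#' applies the Ward update to the dissimilarities as given, `ward_d2`
#' applies it to their squares and reports square-root merge heights.
#' Ties in the minimum inter-cluster distance are broken deterministically
#' in favor of the pair containing the smallest original leaf index, so
#' results are invariant to input order.
#'
#' @param d A `stats::dist` object or symmetric numeric matrix with zero
#'   diagonal.
#' @param linkage `"ward_d"` or `"ward_d2"`.
#' @return An object of class `hclust` (merge matrix, nondecreasing
#'   heights, labels, plotting order), usable with [stats::cutree()].
#' @export
hierarchical_cluster <- function(d, linkage = c("ward_d", "ward_d2")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    d <- as.matrix(d)
  } else {
    .assert(is.matrix(d) && nrow(d) == ncol(d), "distance matrix must be square")
    .assert(max(abs(d - t(d))) < 1e-8, "distance matrix must be symmetric")
    labels <- rownames(d)
  }
  n <- nrow(d)
  .assert(n >= 2, "need >= 2 items")
  labels <- labels %||% as.character(seq_len(n))
  D <- if (linkage == "ward_d2") d^2 else d
  diag(D) <- Inf
  size <- rep(1, n)
  minleaf <- seq_len(n)          # smallest original leaf in each cluster
  id <- -seq_len(n)              # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    m <- min(sub)
    hits <- which(sub == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: smallest leaf index of the pair, then the
    # other member's smallest leaf
    pair_key <- cbind(pmin(minleaf[act[hits[, 1]]], minleaf[act[hits[, 2]]]),
                      pmax(minleaf[act[hits[, 1]]], minleaf[act[hits[, 2]]]))
    best <- order(pair_key[, 1], pair_key[, 2])[1]
    i <- act[hits[best, 1]]; j <- act[hits[best, 2]]
    height[step] <- if (linkage == "ward_d2") sqrt(m) else m
    a <- id[i]; b <- id[j]
    merge[step, ] <- if (.merge_before(a, b, minleaf)) c(a, b) else c(b, a)
    # Lance-Williams Ward update against every other active cluster
    others <- setdiff(act, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
                 nk * m) / (ni + nj + nk)
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height,
                 order = .dendrogram_order(merge),
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

# Put singletons before merged clusters and lower leaf indices first, as
# hclust does for its merge matrix.
#' @noRd
.merge_before <- function(a, b, minleaf) {
  if (a < 0 && b < 0) return(-a < -b)
  if (a < 0) return(TRUE)
  if (b < 0) return(FALSE)
  a < b
}

#' @noRd
.dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram and score cluster composition
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param k Number of clusters (1..n).
#' @param labels Group label per leaf, in leaf order.
#' @return List: `assignments` (named cluster vector), `composition`
#'   (cluster x label count table as data.frame) and `purity` per cluster
#'   (largest label fraction).
#' @export
cut_and_score <- function(hc, k, labels) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  .assert(.is_count(k) && k <= n, "k must be in 1..n")
  .assert(length(labels) == n, "one label per leaf required")
  cl <- stats::cutree(hc, k = k)
  tab <- table(cluster = cl, label = labels)
  comp <- as.data.frame.matrix(tab)
  comp <- cbind(cluster = as.integer(rownames(comp)), comp)
  rownames(comp) <- NULL
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  list(assignments = cl, composition = comp, purity = purity)
}

#' Principal components analysis of an expression matrix
#'
#' Thin wrapper over [stats::prcomp()] returning scores, loadings and the
#' fraction of variance per component (summing to 1).
#'
#' @param x Numeric matrix (samples x probes) or [expression_matrix()].
#' @param center,scale Passed to `prcomp`.
#' @return List: `scores`, `loadings`, `var_frac`, `sdev`.
#' @export
pca_expression <- function(x, center = TRUE, scale = FALSE) {
  if (inherits(x, "expression_matrix")) x <- x$values
  .assert(nrow(x) >= 2, "need >= 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all probes are constant; PCA undefined", call. = FALSE)
  if (scale && any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  p <- stats::prcomp(x, center = center, scale. = scale)
  list(scores = p$x, loadings = p$rotation,
       var_frac = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}

#' Write a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
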