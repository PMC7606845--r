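#' Weighted co-expression adjacency
#'
#' Unsigned soft-thresholded adjacency `a_ij = |pcc(i, j)|^beta` over the
#' given samples, with `a_ii = 0` by convention.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-thresholding power, >= 1.
#' @param samples optional sample subset (default all columns).
#' @return symmetric gene x gene matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency <- function(expr, beta = 6, samples = NULL) {
  if (beta < 1) stop("beta must be >= 1")
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  A <- abs_cor(expr)^beta
  diag(A) <- 0
  A
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivities into 10 equal-width bins, regresses
#' `log10(mean frequency)` on `log10(bin-mean connectivity)` over the
#' non-empty bins, and returns `-sign(slope) * R^2`, so power-law-like
#' (decaying) degree distributions score near +1 and rising ones score
#' negatively.
#'
#' @param k numeric vector of connectivities (length >= 10).
#' @return signed fit index in \[-1, 1\].
#' @export
scale_free_fit <- function(k) {
  if (length(k) < 10) stop("need >= 10 connectivities")
  if (any(k < 0)) stop("connectivities must be nonnegative")
  if (diff(range(k)) == 0) {
    warning("all connectivities equal; scale-free fit undefined, returning 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(kmean) & freq > 0 & kmean > 0
  if (sum(keep) < 2) {
    warning("fewer than 2 usable connectivity bins; returning 0")
    return(0)
  }
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  as.numeric(-sign(slope) * r2)
}

#' Soft-threshold scan
#'
#' Computes, for each candidate power, the scale-free fit index of the
#' resulting adjacency's connectivity distribution and the mean
#' connectivity.  The correlation matrix is computed once and re-raised.
#'
#' @inheritParams adjacency
#' @param powers integer vector of candidate powers.
#' @return `data.frame` with columns `power`, `r2`, `mean_k`.
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, samples = NULL) {
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  C <- abs_cor(expr)
  diag(C) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(C^b)
    data.frame(power = b, r2 = suppressWarnings(scale_free_fit(k)),
               mean_k = mean(k))
  })
  do.call(rbind, rows)
}

#' Choose the soft-thresholding power
#'
#' Smallest power whose scale-free fit index reaches `target_r2`; if none
#' does, the power of maximal fit is returned with a warning.
#'
#' @param scan a [soft_threshold_scan()] table.
#' @param target_r2 required fit index (default 0.90).
#' @return selected power (integer).
#' @export
pick_power <- function(scan, target_r2 = 0.90) {
  if (nrow(scan) == 0) stop("empty soft-threshold scan")
  ok <- scan$r2 >= target_r2
  if (any(ok)) return(min(scan$power[ok]))
  warning("no power reaches target r2 = ", target_r2,
          "; falling back to the best fit")
  scan$power[which.max(scan$r2)]
}

#' Topological overlap matrix
#'
#' `omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `omega_ii = 1`, where `k_i` is the node connectivity.
#'
#' @param adj symmetric adjacency with zero diagonal (from [adjacency()]).
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom <- function(adj) {
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric")
  diag(adj) <- 0
  k <- rowSums(adj)
  L <- adj %*% adj
  W <- (L + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(W) <- 1
  W
}

#' Detect co-expression modules by static dendrogram cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height.  Clusters smaller than `min_module_size` are set
#' to `"grey"` (unassigned); the remaining modules are named by the
#' conventional color sequence in order of decreasing size.
#'
#' The default cut sits just below the top of the dendrogram (99% of the
#' maximal merge height).  Because unrelated genes only merge near
#' dissimilarity 1 while co-expressed blocks merge far lower, this cut
#' separates every coherent branch without fragmenting it, whatever the
#' proportion of module genes in the matrix; a fixed or quantile-based cut
#' is available through `cut_height`.
#'
#' @param tom_mat topological overlap matrix from [tom()].
#' @param min_module_size smallest retained module (>= 3).
#' @param cut_height static cut height on `1 - TOM`; default
#'   `0.99 * max(merge heights)`.
#' @return list with `labels` (named character vector gene -> module) and
#'   `modules` (named list of gene vectors, decreasing size, no `"grey"`).
#' @export
cluster_modules <- function(tom_mat, min_module_size = 5, cut_height = NULL) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  d <- stats::as.dist(1 - tom_mat)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  raw <- stats::cutree(hc, h = cut_height)
  genes <- rownames(tom_mat) %||% paste0("g", seq_len(nrow(tom_mat)))
  names(raw) <- genes
  sizes <- sort(table(raw), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  colors <- module_colors(length(keep))
  labels <- stats::setNames(rep("grey", length(genes)), genes)
  modules <- list()
  for (i in seq_along(keep)) {
    mem <- sort(genes[raw == keep[i]])
    labels[mem] <- colors[i]
    modules[[colors[i]]] <- mem
  }
  list(labels = labels, modules = modules, cut_height = unname(cut_height))
}

# Conventional module color sequence; extended deterministically if needed.
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("module", seq_len(n - length(base))))
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix,
#' scaled to unit variance and oriented so its mean correlation with the
#' member gene profiles is positive.
#'
#' @param expr genes x samples matrix.
#' @param genes module gene ids (>= 3).
#' @param samples optional sample subset.
#' @return named numeric vector (one score per sample).
#' @export
module_eigengene <- function(expr, genes, samples = NULL) {
  if (length(genes) < 3) stop("module must have >= 3 genes")
  check_module_genes(expr, genes)
  X <- expr[genes, samples %||% colnames(expr), drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance gene profile in module; eigengene undefined")
  Xs <- (X - rowMeans(X)) / sds
  sv <- svd(Xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, t(Xs))) < 0) e <- -e
  stats::setNames(e, colnames(X))
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a per-sample numeric
#' trait (e.g. the ordinal stage code), with the usual t-transform p-value
#' on n - 2 degrees of freedom; modules are ranked by `|cor|`.
#'
#' @param expr genes x samples matrix.
#' @param assignment result of [cluster_modules()] (or any named list of
#'   gene vectors in its `modules` element).
#' @param trait numeric vector named by (or aligned with) the analysed
#'   samples; must be non-constant.
#' @param samples samples to use; default the names of `trait`.
#' @return `data.frame` sorted by decreasing `|cor|`: `module`, `size`,
#'   `cor`, `p`.
#' @export
module_trait_cor <- function(expr, assignment, trait, samples = NULL) {
  mods <- if (!is.null(assignment$modules)) assignment$modules else assignment
  if (length(mods) == 0) stop("no modules to correlate")
  samples <- samples %||% names(trait)
  if (is.null(samples)) stop("trait must be named by sample or samples given")
  if (stats::sd(trait) == 0) stop("trait is constant")
  n <- length(trait)
  rows <- lapply(names(mods), function(nm) {
    e <- module_eigengene(expr, mods[[nm]], samples = samples)
    r <- stats::cor(e, trait)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(module = nm, size = length(mods[[nm]]), cor = r,
               p = 2 * stats::pt(-abs(tt), n - 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$cor), out$module), , drop = FALSE]
}
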