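#' Pearson correlation coefficient
#'
#' Plain Pearson estimate between two sample vectors, with the degenerate
#' convention used throughout the composite-index code: a zero-variance
#' vector has undefined correlation, which is returned as 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Mean absolute deviation of a module from its reference baseline (SD_in)
#'
#' For each module gene `g` and each case sample `d` of the given stage,
#' the deviation is `|x_gd - xbar_g|` where `xbar_g` is the mean expression
#' of `g` over the reference samples.  The statistic is the mean of these
#' deviations over all (gene, sample) pairs.  With `normalize = TRUE` each
#' gene's deviations are first divided by the gene's reference-sample
#' standard deviation (the classical differential-SD form); the default
#' follows the plain absolute-deviation definition.
#'
#' @param expr genes x samples log2 matrix.
#' @param design stage design (see [read_design()]).
#' @param module character vector of module gene ids.
#' @param stage stage label or ordinal index.
#' @param normalize divide by per-gene reference standard deviation.
#' @return nonnegative scalar (log2 units).
#' @export
sd_in <- function(expr, design, module, stage, normalize = FALSE) {
  check_design_matrix(expr, design)
  check_module_genes(expr, module)
  refs <- reference_samples(design)
  if (length(refs) == 0) stop("design has no reference samples")
  cases <- case_samples(design, stage)
  if (length(cases) == 0) stop("stage has no case samples")
  ref_mean <- rowMeans(expr[module, refs, drop = FALSE])
  dev <- abs(expr[module, cases, drop = FALSE] - ref_mean)
  if (normalize) {
    ref_sd <- apply(expr[module, refs, drop = FALSE], 1, stats::sd)
    if (any(ref_sd == 0)) stop("zero reference variance; cannot normalize")
    dev <- dev / ref_sd
  }
  mean(dev)
}

#' Mean absolute within-module correlation (PCC_in)
#'
#' Mean of `|pcc|` over all m(m-1)/2 unordered within-module gene pairs,
#' computed on the case samples of the given stage only.
#'
#' @inheritParams sd_in
#' @return scalar in \[0, 1\].
#' @export
pcc_in <- function(expr, design, module, stage) {
  check_design_matrix(expr, design)
  check_module_genes(expr, module)
  if (length(module) < 2) stop("module must have >= 2 genes for PCC_in")
  cases <- case_samples(design, stage)
  if (length(cases) < 3) stop("stage must have >= 3 case samples")
  C <- abs_cor(expr[module, cases, drop = FALSE])
  mean(C[upper.tri(C)])
}

#' Mean absolute module-to-background correlation (PCC_out)
#'
#' Mean of `|pcc|` over all module x background gene pairs on the case
#' samples of the given stage.
#'
#' @inheritParams sd_in
#' @param background character vector of background gene ids, disjoint from
#'   the module; default all non-module genes in the matrix.
#' @return scalar in \[0, 1\].
#' @export
pcc_out <- function(expr, design, module, stage, background = NULL) {
  check_design_matrix(expr, design)
  check_module_genes(expr, module)
  if (is.null(background)) background <- setdiff(rownames(expr), module)
  check_module_genes(expr, background)
  if (length(background) == 0) stop("background gene set is empty")
  overlap <- intersect(module, background)
  if (length(overlap) > 0) {
    stop("module and background overlap: ", paste(overlap, collapse = ", "))
  }
  cases <- case_samples(design, stage)
  if (length(cases) < 3) stop("stage must have >= 3 case samples")
  C <- suppressWarnings(stats::cor(t(expr[module, cases, drop = FALSE]),
                                   t(expr[background, cases, drop = FALSE])))
  if (anyNA(C)) {
    warning("zero-variance gene profile: undefined correlations set to 0")
    C[is.na(C)] <- 0
  }
  mean(abs(C))
}

#' Composite index (CI)
#'
#' The scalar DNB score `CI = SD_in * PCC_in / PCC_out`.  A vanishing
#' `PCC_out` is floored at `epsilon` (with a warning) instead of dividing
#' by zero.
#'
#' @param sd_in,pcc_in,pcc_out finite nonnegative component statistics.
#' @param epsilon floor applied to `pcc_out` (default `1e-6`).
#' @return nonnegative scalar.
#' @examples
#' composite_index(2, 0.5, 0.25)  # 4
#' @export
composite_index <- function(sd_in, pcc_in, pcc_out, epsilon = 1e-6) {
  vals <- c(sd_in, pcc_in, pcc_out)
  if (any(!is.finite(vals))) stop("composite index inputs must be finite")
  if (any(vals < 0)) stop("composite index inputs must be nonnegative")
  if (pcc_out < epsilon) {
    warning("pcc_out below epsilon floor (", epsilon, "); flooring denominator")
    pcc_out <- epsilon
  }
  sd_in * pcc_in / pcc_out
}

#' Score a gene module across all stages
#'
#' Computes SD_in, PCC_in, PCC_out (background = all non-module genes) and
#' the composite index for each stage of the design, in stage order.
#'
#' @inheritParams sd_in
#' @param epsilon denominator floor, see [composite_index()].
#' @param sd_normalize passed to [sd_in()] as `normalize`.
#' @return `data.frame` with one row per stage: `stage`, `n_cases`,
#'   `sd_in`, `pcc_in`, `pcc_out`, `ci`.
#' @export
score_module <- function(expr, design, module, epsilon = 1e-6,
                         sd_normalize = FALSE) {
  lv <- stage_levels(design)
  rows <- lapply(lv, function(s) {
    data.frame(stage = s,
               n_cases = length(case_samples(design, s)),
               sd_in = sd_in(expr, design, module, s, normalize = sd_normalize),
               pcc_in = pcc_in(expr, design, module, s),
               pcc_out = pcc_out(expr, design, module, s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ci <- mapply(composite_index, out$sd_in, out$pcc_in, out$pcc_out,
                   MoreArgs = list(epsilon = epsilon))
  out
}

#' Candidate modules at one stage
#'
#' The module search is deliberately simple and deterministic: the gene
#' universe is pre-filtered to the `top_k` genes by mean absolute deviation
#' from the reference mean at this stage, average-linkage hierarchical
#' clustering is run on the dissimilarity `1 - |pcc|` over the stage's case
#' samples, and every internal cluster of the dendrogram whose size lies in
#' `[min_size, max_size]` is returned as a candidate.
#'
#' @inheritParams sd_in
#' @param min_size,max_size candidate size bounds.
#' @param top_k deviation pre-filter size (clamped to the gene universe).
#' @return list of character vectors (sorted gene ids).
#' @export
candidate_modules <- function(expr, design, stage, min_size = 10,
                              max_size = 50, top_k = 200) {
  check_design_matrix(expr, design)
  if (top_k < min_size) stop("top_k must be >= min_size")
  if (min_size < 2) stop("min_size must be >= 2")
  if (max_size < min_size) stop("max_size must be >= min_size")
  refs <- reference_samples(design)
  cases <- case_samples(design, stage)
  if (length(cases) < 3) stop("stage must have >= 3 case samples")
  ref_mean <- rowMeans(expr[, refs, drop = FALSE])
  dev <- rowMeans(abs(expr[, cases, drop = FALSE] - ref_mean))
  k <- min(top_k, nrow(expr))
  top <- names(sort(dev, decreasing = TRUE))[seq_len(k)]
  C <- abs_cor(expr[top, cases, drop = FALSE], warn = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  members <- hclust_clusters(hc, top)
  sizes <- lengths(members)
  members[sizes >= min_size & sizes <= max_size]
}

# All internal-node member sets of an hclust tree, as sorted id vectors.
hclust_clusters <- function(hc, labels) {
  n <- length(labels)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    kids <- hc$merge[i, ]
    get <- function(k) if (k < 0) labels[-k] else out[[k]]
    out[[i]] <- c(get(kids[1]), get(kids[2]))
  }
  lapply(out, sort)
}

#' Fit a dynamic network biomarker model
#'
#' The central estimator: searches for the gene module that behaves like a
#' dynamic network biomarker and locates the critical transition stage.
#' For every stage, candidate modules (see [candidate_modules()]) are
#' scored by the composite index at that stage and the module attaining the
#' global maximum is selected as THE DNB module.  Because nested candidates
#' from the same dendrogram score within sampling noise of one another (a
#' small subcluster trades a higher within-module correlation against a
#' higher out-correlation), ties are resolved at a relative tolerance: among
#' all candidates whose CI is within `ci_tol` of the maximum, the largest
#' module wins, then the higher CI, then lexicographic gene order.
#' `ci_tol = 0` gives the strict argmax.  The winner's full stage
#' trajectory is then rescored with [score_module()] and the critical stage
#' detected with [detect_critical_stage()].
#'
#' @inheritParams sd_in
#' @inheritParams candidate_modules
#' @inheritParams score_module
#' @param ci_tol relative near-tie tolerance of the module selection
#'   (default 0.05).
#' @return object of class `"dnb"`: list with `module` (sorted gene ids),
#'   `scores` (per-stage data frame), `critical_stage` / `critical_label`,
#'   `peak_stage` / `peak_label`, `no_transition`, `selected_at` (stage
#'   where the winning candidate scored highest), `n_candidates`, `params`
#'   and `call`.
#' @examples
#' sim <- simulate_dnb_data(dnb_spec(n_genes = 80, module_size = 8,
#'                                   n_de = 10, trait_module_size = 5,
#'                                   seed = 11))
#' fit <- dnb(sim$expr, sim$design, top_k = 80, min_size = 4, max_size = 20)
#' fit
#' @export
dnb <- function(expr, design, min_size = 10, max_size = 50, top_k = 200,
                epsilon = 1e-6, sd_normalize = FALSE, ci_tol = 0.05) {
  check_design_matrix(expr, design)
  if (ci_tol < 0 || ci_tol >= 1) stop("ci_tol must lie in [0, 1)")
  lv <- stage_levels(design)
  refs <- reference_samples(design)
  ref_mean <- rowMeans(expr[, refs, drop = FALSE])
  n_genes <- nrow(expr)

  pool <- list()
  for (si in seq_along(lv)) {
    cands <- candidate_modules(expr, design, lv[si], min_size = min_size,
                               max_size = max_size, top_k = top_k)
    if (length(cands) == 0) next
    cases <- case_samples(design, lv[si])
    C <- abs_cor(expr[, cases, drop = FALSE], warn = FALSE)
    dev <- abs(expr[, cases, drop = FALSE] - ref_mean)
    if (sd_normalize) {
      ref_sd <- apply(expr[, refs, drop = FALSE], 1, stats::sd)
      dev <- dev / ref_sd
    }
    for (mod in cands) {
      m <- length(mod)
      Cmm <- C[mod, mod]
      p_in <- (sum(Cmm) - m) / (m * (m - 1))
      p_out <- (sum(C[mod, ]) - sum(Cmm)) / (m * (n_genes - m))
      s_in <- mean(dev[mod, ])
      pool[[length(pool) + 1L]] <- list(
        module = mod, m = m, stage = si,
        ci = s_in * p_in / max(p_out, epsilon),
        key = paste(mod, collapse = ","))
    }
  }
  if (length(pool) == 0) stop("no candidate modules found; relax size bounds or top_k")
  n_candidates <- length(pool)
  ci_all <- vapply(pool, `[[`, numeric(1), "ci")
  eligible <- pool[ci_all >= (1 - ci_tol) * max(ci_all)]
  ord <- order(-vapply(eligible, `[[`, numeric(1), "m"),
               -vapply(eligible, `[[`, numeric(1), "ci"),
               vapply(eligible, `[[`, character(1), "key"))
  best <- eligible[[ord[1]]]

  scores <- score_module(expr, design, best$module, epsilon = epsilon,
                         sd_normalize = sd_normalize)
  crit <- detect_critical_stage(scores$ci)
  peak <- which.max(scores$ci)
  structure(list(
    module = best$module,
    scores = scores,
    critical_stage = as.integer(crit),
    critical_label = lv[as.integer(crit)],
    peak_stage = as.integer(peak),
    peak_label = lv[peak],
    no_transition = isTRUE(attr(crit, "no_transition")),
    selected_at = lv[best$stage],
    n_candidates = n_candidates,
    params = list(min_size = min_size, max_size = max_size, top_k = top_k,
                  epsilon = epsilon, sd_normalize = sd_normalize,
                  ci_tol = ci_tol),
    call = match.call()
  ), class = "dnb")
}

#' Detect the critical transition stage from a composite-index trajectory
#'
#' The critical (pre-transition) stage is where the sharp rise of the DNB
#' score begins: the stage `s` maximizing the forward difference
#' `ci(s+1) - ci(s)`, ties broken toward the earliest stage.  When every
#' forward difference is negative the trajectory never rises and the result
#' carries attribute `no_transition = TRUE`.
#'
#' @param ci numeric vector of per-stage composite indices, stage order,
#'   length >= 2; names (stage labels) are preserved on the result.
#' @return integer stage index with attribute `no_transition`.
#' @examples
#' detect_critical_stage(c(0.42378583, 0.14771798, 0.09225563, 0.647891324))
#' @export
detect_critical_stage <- function(ci) {
  if (length(ci) < 2) stop("need a trajectory over >= 2 stages")
  if (any(!is.finite(ci))) stop("trajectory must be finite")
  d <- diff(ci)
  idx <- which.max(d)   # earliest on ties
  out <- as.integer(idx)
  if (!is.null(names(ci))) names(out) <- names(ci)[idx]
  attr(out, "no_transition") <- all(d < 0)
  out
}

# S3 methods -------------------------------------------------------------

#' @export
print.dnb <- function(x, ...) {
  cat("Dynamic network biomarker fit\n")
  cat("  module:", length(x$module), "genes (selected at stage",
      paste0(x$selected_at, ")"), "\n")
  cat("  CI trajectory:",
      paste(sprintf("%s=%.4g", x$scores$stage, x$scores$ci), collapse = ", "), "\n")
  cat("  critical transition stage:", x$critical_label,
      if (x$no_transition) "(no rising transition detected)" else "", "\n")
  cat("  peak stage:", x$peak_label, "\n")
  invisible(x)
}

#' @export
summary.dnb <- function(object, ...) {
  structure(list(fit = object), class = "summary.dnb")
}

#' @export
print.summary.dnb <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-stage scores:\n")
  print(fit$scores, row.names = FALSE, digits = 4)
  cat("\nModule genes:\n")
  cat(strwrap(paste(fit$module, collapse = ", "), width = 76, prefix = "  "),
      sep = "\n")
  invisible(x)
}

#' @export
coef.dnb <- function(object, ...) {
  stats::setNames(object$scores$ci, object$scores$stage)
}

#' Plot a composite-index trajectory
#'
#' Base-graphics line plot of the per-stage composite index with the
#' detected critical stage marked.
#'
#' @param x a `"dnb"` fit.
#' @param ... passed to [plot()].
#' @export
plot.dnb <- function(x, ...) {
  s <- seq_len(nrow(x$scores))
  plot(s, x$scores$ci, type = "b", pch = 19, xaxt = "n",
       xlab = "stage", ylab = "composite index (CI)", ...)
  graphics::axis(1, at = s, labels = x$scores$stage)
  graphics::abline(v = x$critical_stage, lty = 2, col = "red3")
  graphics::mtext(paste("critical stage:", x$critical_label), side = 3,
                  line = 0.2, col = "red3", cex = 0.9)
  invisible(x)
}
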