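#' Welch unequal-variance t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom, written out in
#' closed form so the degenerate cases have the conventions the pipeline
#' relies on: two constant, equal groups give `t = 0, p = 1`; two constant
#' but unequal groups give an infinite statistic with `p` guarded at
#' `1e-300`.
#'
#' @param case,reference numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p`.
#' @export
welch_t <- function(case, reference) {
  n1 <- length(case); n2 <- length(reference)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values")
  m1 <- mean(case); m2 <- mean(reference)
  v1 <- stats::var(case); v2 <- stats::var(reference)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(list(statistic = 0, df = n1 + n2 - 2, p = 1))
    return(list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 1e-300))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- max(2 * stats::pt(-abs(t), df), 1e-300)
  list(statistic = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values (monotone, <= 1), in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Stage-wise differential expression calls
#'
#' Welch t-test of the stage's case samples against the reference pool for
#' every gene, Benjamini-Hochberg correction across genes, and the
#' two-threshold call rule: a gene is `up` iff `fdr < alpha` and
#' `log2fc > lfc`, `down` iff `fdr < alpha` and `log2fc < -lfc`, otherwise
#' `ns`.  `log2fc` is the difference of group means on the log2 scale.
#'
#' @inheritParams sd_in
#' @param alpha FDR threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 2.0, i.e.
#'   4-fold).
#' @return `data.frame` with one row per gene (matrix order): `gene`,
#'   `stage`, `log2fc`, `t`, `p`, `fdr`, `direction`.
#' @export
call_degs <- function(expr, design, stage, alpha = 0.05, lfc = 2.0) {
  check_design_matrix(expr, design)
  refs <- reference_samples(design)
  cases <- case_samples(design, stage)
  if (length(cases) < 2 || length(refs) < 2) stop("each group needs >= 2 samples")
  X1 <- expr[, cases, drop = FALSE]
  X2 <- expr[, refs, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate genes: both groups constant
  zero <- se2 == 0
  if (any(zero)) {
    equal <- zero & (m1 == m2)
    t[equal] <- 0; p[equal] <- 1; df[equal] <- n1 + n2 - 2
    uneq <- zero & (m1 != m2)
    t[uneq] <- sign(m1 - m2)[uneq] * Inf; df[uneq] <- n1 + n2 - 2
  }
  p <- pmax(p, 1e-300)
  fdr <- bh_fdr(p)
  lfc_est <- m1 - m2
  direction <- rep("ns", nrow(expr))
  direction[fdr < alpha & lfc_est > lfc] <- "up"
  direction[fdr < alpha & lfc_est < -lfc] <- "down"
  lv <- stage_levels(design)
  stage_lab <- if (is.numeric(stage)) lv[stage] else stage
  data.frame(gene = rownames(expr), stage = stage_lab, log2fc = lfc_est,
             t = t, p = p, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression calls for every stage
#'
#' @inheritParams call_degs
#' @return named list of per-stage [call_degs()] tables.
#' @export
call_degs_all <- function(expr, design, alpha = 0.05, lfc = 2.0) {
  lv <- stage_levels(design)
  stats::setNames(lapply(lv, function(s)
    call_degs(expr, design, s, alpha = alpha, lfc = lfc)), lv)
}

#' Per-stage up/down summary counts
#'
#' @param deg_tables named list of per-stage tables from [call_degs_all()].
#' @return `data.frame` with columns `stage`, `n_up`, `n_down`.
#' @export
deg_summary <- function(deg_tables) {
  data.frame(stage = names(deg_tables),
             n_up = vapply(deg_tables, function(d) sum(d$direction == "up"), 0L),
             n_down = vapply(deg_tables, function(d) sum(d$direction == "down"), 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-stage overlap of DNB genes, down-regulated genes and tumor suppressors
#'
#' For each stage: `dnb_genes` intersected with the genes called `down` at
#' that stage, intersected with the tumor-suppressor set.  Output gene
#' lists are sorted, so the result is deterministic.
#'
#' @param dnb_genes character vector of DNB module gene ids.
#' @param deg_tables named list of per-stage [call_degs()] tables.
#' @param tsg non-empty character vector of tumor-suppressor gene ids.
#' @return named list (one sorted character vector per stage).
#' @export
suppressor_overlap <- function(dnb_genes, deg_tables, tsg) {
  if (length(tsg) == 0) stop("tumor-suppressor gene set is empty")
  lapply(deg_tables, function(d) {
    down <- d$gene[d$direction == "down"]
    sort(intersect(intersect(dnb_genes, down), tsg))
  })
}
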