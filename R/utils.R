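# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# |cor| matrix across rows of `x` (genes) on the given samples; zero-variance
# rows yield NA correlations, which are defined as 0 (with one warning).
abs_cor <- function(x, warn = TRUE) {
  C <- suppressWarnings(stats::cor(t(x)))
  if (anyNA(C)) {
    if (warn) warning("zero-variance gene profile: undefined correlations set to 0")
    C[is.na(C)] <- 0
  }
  abs(C)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# design accessors -------------------------------------------------------

reference_samples <- function(design) {
  as.character(design$sample_id[design$group == "reference"])
}

case_samples <- function(design, stage) {
  stopifnot(length(stage) == 1L)
  lv <- stage_levels(design)
  if (is.numeric(stage)) stage <- lv[stage]
  if (!stage %in% lv) {
    stop("unknown stage '", stage, "'; allowed stages: ", paste(lv, collapse = ", "))
  }
  as.character(design$sample_id[design$group == "case" & !is.na(design$stage) &
                                  as.character(design$stage) == stage])
}

stage_levels <- function(design) {
  levels(design$stage)
}

# Check that every design sample is a column of the matrix and that the
# design invariants hold against this matrix.
check_design_matrix <- function(expr, design) {
  missing <- setdiff(as.character(design$sample_id), colnames(expr))
  if (length(missing) > 0) {
    stop("design samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

check_module_genes <- function(expr, genes) {
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    stop("module genes absent from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}
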