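#' Specify a synthetic stage-ordered expression study
#'
#' Builds the parameter object for [simulate_dnb_data()].  The generator
#' plants three kinds of structure in an otherwise independent Gaussian
#' background, emulating what dynamic network biomarker (DNB) theory expects
#' of a system approaching a tipping point:
#'
#' * a **DNB module** of `module_size` genes sharing one latent factor in
#'   case samples, with stage-dependent loading `lambda[s]` and noise scale
#'   `tau[s]`, so within-module correlation
#'   \eqn{\lambda^2/(\lambda^2+\tau^2\sigma^2)} and deviation from the
#'   reference mean rise along the stage axis while correlation to
#'   background genes stays 0 in expectation;
#' * **differentially expressed genes** whose case means are shifted by
#'   `de_shift` (half up, half down) in all case samples;
#' * a **trait module** whose genes track the centered ordinal stage code
#'   with coefficient `gamma`, giving an eigengene correlated with stage.
#'
#' The default loading schedule keeps the module quiet through the tipping
#' stage and lets it explode immediately after, so the composite index
#' trajectory mirrors the canonical picture of a pre-transition stage
#' followed by a sharp rise (low scores early, peak at the final stage, rise
#' beginning at `tipping_stage`).
#'
#' @param n_genes total number of genes.
#' @param n_stages number of ordinal case stages.
#' @param cases_per_stage case samples per stage.
#' @param n_reference reference (normal) samples.
#' @param module_size DNB module size (m).
#' @param tipping_stage ordinal index of the planted pre-transition stage.
#' @param lambda per-stage shared-factor loading, nonnegative, nondecreasing
#'   up to `tipping_stage`.
#' @param tau per-stage module noise scale, all >= 1.
#' @param sigma background noise standard deviation (log2 units).
#' @param n_de number of differentially expressed genes (split evenly into
#'   up and down).
#' @param de_shift absolute log2 mean shift of the DE genes in case samples.
#' @param trait_module_size size of the stage-correlated module.
#' @param gamma loading of trait-module genes on the centered stage code.
#' @param stage_labels stage names (default roman numerals).
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return object of class `"dnb_spec"`.
#' @export
dnb_spec <- function(n_genes = 500, n_stages = 4, cases_per_stage = 20,
                     n_reference = 20, module_size = 20, tipping_stage = 3,
                     lambda = c(0.3, 0.5, 0.7, 2.5), tau = rep(1, n_stages),
                     sigma = 1, n_de = 40, de_shift = 3,
                     trait_module_size = 15, gamma = 1,
                     stage_labels = NULL, seed = 1) {
  if (is.null(stage_labels)) {
    stage_labels <- as.character(utils::as.roman(seq_len(n_stages)))
  }
  spec <- list(n_genes = n_genes, n_stages = n_stages,
               cases_per_stage = cases_per_stage, n_reference = n_reference,
               module_size = module_size, tipping_stage = tipping_stage,
               lambda = lambda, tau = tau, sigma = sigma, n_de = n_de,
               de_shift = de_shift, trait_module_size = trait_module_size,
               gamma = gamma, stage_labels = stage_labels, seed = seed)
  sizes <- c(n_genes, n_stages, cases_per_stage, n_reference, module_size,
             trait_module_size)
  if (any(sizes <= 0)) stop("all sizes must be positive")
  if (tipping_stage < 1 || tipping_stage > n_stages) {
    stop("tipping_stage must lie in [1, n_stages]")
  }
  if (length(lambda) != n_stages || length(tau) != n_stages) {
    stop("lambda and tau must have one value per stage")
  }
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (any(tau < 1)) stop("tau must be >= 1")
  if (tipping_stage > 1 && any(diff(lambda[seq_len(tipping_stage)]) < 0)) {
    stop("lambda must be nondecreasing up to the tipping stage")
  }
  if (n_de < 0) stop("n_de must be nonnegative")
  if (module_size + n_de + trait_module_size > n_genes) {
    stop("module, DE and trait gene sets exceed n_genes; they must be disjoint")
  }
  if (length(stage_labels) != n_stages) stop("need one stage label per stage")
  structure(spec, class = "dnb_spec")
}

#' @export
print.dnb_spec <- function(x, ...) {
  cat("Synthetic DNB study spec:", x$n_genes, "genes,", x$n_stages, "stages x",
      x$cases_per_stage, "cases,", x$n_reference, "reference samples\n")
  cat("  DNB module m =", x$module_size, ", tipping stage",
      x$stage_labels[x$tipping_stage], "\n")
  cat("  lambda:", paste(x$lambda, collapse = ", "),
      " tau:", paste(x$tau, collapse = ", "), "\n")
  cat("  DE genes:", x$n_de, "at |shift| =", x$de_shift,
      "; trait module:", x$trait_module_size, "at gamma =", x$gamma, "\n")
  invisible(x)
}

#' Generate stage-ordered expression data with planted ground truth
#'
#' Draws a gene x sample log2 expression matrix, a case/reference stage
#' design, and the planted truth described in [dnb_spec()].  Reference
#' samples are pure background (`mu_g + sigma * eps`); planted structure is
#' confined to case samples.  All randomness comes from `spec$seed`, and the
#' draw order does not depend on the values of `lambda`, `tau`, `de_shift`
#' or `gamma`, so two specs differing only in those parameters share their
#' noise realizations — useful for monotonicity experiments.
#'
#' @param spec a [dnb_spec()] object.
#' @return list with elements `expr` (matrix), `design` (data frame as from
#'   [read_design()]), and `truth` (list: `dnb_genes`, `de_genes` — a named
#'   vector of shifts —, `trait_module`, `tipping_stage`, `tipping_label`).
#' @examples
#' sim <- simulate_dnb_data(dnb_spec(n_genes = 100, seed = 7))
#' dim(sim$expr)
#' @export
simulate_dnb_data <- function(spec) {
  stopifnot(inherits(spec, "dnb_spec"))
  with_seed(spec$seed, {
    n_g <- spec$n_genes
    n_cases <- spec$n_stages * spec$cases_per_stage
    n_s <- n_cases + spec$n_reference
    gene_ids <- sprintf("g%04d", seq_len(n_g))
    ref_ids <- sprintf("REF_%02d", seq_len(spec$n_reference))
    stage_of_case <- rep(seq_len(spec$n_stages), each = spec$cases_per_stage)
    case_ids <- sprintf("S%s_%02d", spec$stage_labels[stage_of_case],
                        sequence(rep(spec$cases_per_stage, spec$n_stages)))
    sample_ids <- c(ref_ids, case_ids)

    # fixed draw order: gene means, gene sets, noise, shared factors
    mu <- stats::runif(n_g, 5, 10)
    idx <- sample.int(n_g)
    dnb_idx <- idx[seq_len(spec$module_size)]
    de_idx <- if (spec$n_de > 0) idx[spec$module_size + seq_len(spec$n_de)] else integer(0)
    trait_idx <- idx[spec$module_size + spec$n_de + seq_len(spec$trait_module_size)]
    eps <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)
    f <- stats::rnorm(n_cases)

    x <- mu + spec$sigma * eps
    ci <- spec$n_reference + seq_len(n_cases)       # case column indices
    lam <- spec$lambda[stage_of_case]
    tau <- spec$tau[stage_of_case]
    # DNB module: shared factor per case sample, stage-scaled noise
    x[dnb_idx, ci] <- mu[dnb_idx] +
      rep(lam * f, each = length(dnb_idx)) +
      rep(tau, each = length(dnb_idx)) * spec$sigma * eps[dnb_idx, ci]
    # DE genes: constant case-sample shift, alternating sign
    de_shift <- numeric(0)
    if (spec$n_de > 0) {
      de_shift <- rep(c(spec$de_shift, -spec$de_shift), length.out = spec$n_de)
      x[de_idx, ci] <- x[de_idx, ci] + de_shift
    }
    # trait module: centered ordinal stage code
    z <- seq_len(spec$n_stages) - mean(seq_len(spec$n_stages))
    x[trait_idx, ci] <- x[trait_idx, ci] +
      rep(spec$gamma * z[stage_of_case], each = length(trait_idx))

    rownames(x) <- gene_ids
    colnames(x) <- sample_ids
    design <- as_design(data.frame(
      sample_id = sample_ids,
      group = c(rep("reference", spec$n_reference), rep("case", n_cases)),
      stage = c(rep(NA_character_, spec$n_reference),
                spec$stage_labels[stage_of_case]),
      stringsAsFactors = FALSE), stage_levels = spec$stage_labels)
    truth <- list(
      dnb_genes = sort(gene_ids[dnb_idx]),
      de_genes = stats::setNames(de_shift, gene_ids[de_idx]),
      trait_module = sort(gene_ids[trait_idx]),
      tipping_stage = spec$tipping_stage,
      tipping_label = spec$stage_labels[spec$tipping_stage])
    list(expr = x, design = design, truth = truth, spec = spec)
  })
}

#' Small deterministic graph fixtures
#'
#' Named [igraph] graphs with documented structure, used as oracle inputs
#' for the centrality code:
#' * `p3`: path a-b-c;
#' * `k3`: triangle;
#' * `s5`: star, center `a` with 5 leaves;
#' * `clique8`: 8 nodes with a planted 4-clique `a,b,c,d`, a path
#'   `e-f-g-h`, and bridge `a-e`;
#' * `hub8`: 8-node triangle-free double star — hub `a` adjacent to
#'   `b..f`, with `b` adjacent to leaves `g,h`; node `a` is the planted
#'   consensus hub.
#'
#' @return named list of igraph objects.
#' @export
fixture_graphs <- function() {
  g <- function(edges) {
    igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                directed = FALSE)
  }
  list(
    p3 = g(c("a","b", "b","c")),
    k3 = g(c("a","b", "b","c", "c","a")),
    s5 = g(c("a","b", "a","c", "a","d", "a","e", "a","f")),
    clique8 = g(c("a","b", "a","c", "a","d", "b","c", "b","d", "c","d",
                  "a","e", "e","f", "f","g", "g","h")),
    hub8 = g(c("a","b", "a","c", "a","d", "a","e", "a","f", "b","g", "b","h"))
  )
}
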