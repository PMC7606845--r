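#' Build a validated pipeline configuration
#'
#' Assembles the declarative configuration consumed by [run_all()].
#' Unknown keys anywhere in the structure are rejected.  Top-level keys:
#'
#' * `seed`: master seed; drives the simulation and edge-percolation RNG.
#' * `simulate`: generate data with [simulate_dnb_data()] (`sim` holds
#'   [dnb_spec()] overrides); otherwise `expr_path` / `design_path` (and
#'   optional `stage_levels`) are read.
#' * `edges_path`: optional interaction network; without it the hub stage
#'   derives a network by thresholding `|pcc|` among the fitted DNB module
#'   genes at `hubs$cor_threshold`.
#' * `tsg_path`: optional tumor-suppressor GMT; for simulated runs a
#'   synthetic stand-in (the planted down-regulated genes) is written and
#'   used when absent.
#' * `deg`, `dnb`, `coexpress`, `hubs`: stage parameter blocks; see
#'   [call_degs()], [dnb()], [soft_threshold_scan()], [cluster_modules()],
#'   [compute_centralities()].
#'
#' @param ... overrides of the defaults, e.g. `seed = 7`,
#'   `dnb = list(top_k = 100)`.
#' @return config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    simulate = TRUE,
    sim = list(),
    expr_path = NULL, design_path = NULL, stage_levels = NULL,
    edges_path = NULL, tsg_path = NULL,
    deg = list(alpha = 0.05, lfc = 2.0),
    dnb = list(min_size = 5, max_size = 50, top_k = 200, epsilon = 1e-6,
               sd_normalize = FALSE),
    coexpress = list(enabled = TRUE, powers = 1:12, target_r2 = 0.90,
                     min_module_size = 10, cut_height = NULL),
    hubs = list(enabled = TRUE, metrics = "all", k = 3, cor_threshold = 0.6,
                epc_trials = 200, epc_p = 0.5)
  )
  out <- merge_config(defaults, list(...), path = "")
  class(out) <- "pipeline_config"
  out
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) {
    out <- defaults
  } else {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) stop("config overrides must be named")
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config key(s)", if (nzchar(path)) paste0(" under '", path, "'"),
           ": ", paste(unknown, collapse = ", "))
    }
    out <- defaults
    for (k in nm) {
      if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
          k != "sim") {
        out[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                 path = if (nzchar(path)) paste0(path, ".", k) else k)
      } else if (k == "sim") {
        bad <- setdiff(names(overrides[[k]]), names(formals(dnb_spec)))
        if (length(bad) > 0) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
        out[[k]] <- overrides[[k]]
      } else {
        out[[k]] <- overrides[[k]]
      }
    }
  }
  out
}

#' Run the whole stage-ordered biomarker pipeline
#'
#' Orchestrates data acquisition (simulation or file load), stage-wise
#' differential expression, the DNB fit, the co-expression stage, hub
#' ranking, and the tumor-suppressor overlap, writing every artifact plus a
#' machine-readable `summary.json` and a `manifest.json` (parameters and
#' md5 of every artifact) into `out_dir`.  Identical config and inputs give
#' byte-identical artifacts and manifest.
#'
#' @param config a [pipeline_config()] list, or the path of a YAML file
#'   holding one.
#' @param out_dir run directory (created, must be empty or absent).
#' @return invisibly, list with `dir`, `summary` and `manifest`.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stop("out_dir exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)
  note <- function(stage, msg) {
    warnings_seen <<- c(warnings_seen, paste0("[", stage, "] ", msg))
  }
  run_stage <- function(stage, code) {
    withCallingHandlers(
      tryCatch(code, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  art <- function(name) file.path(out_dir, name)
  t0 <- proc.time()["elapsed"]
  tick <- function(stage) {
    message(sprintf("[run_all] %-12s done at %.1fs", stage,
                    proc.time()["elapsed"] - t0))
  }

  # --- data -------------------------------------------------------------
  truth <- NULL
  dat <- run_stage("data", {
    if (isTRUE(config$simulate)) {
      spec <- do.call(dnb_spec, c(config$sim,
                                  if (is.null(config$sim$seed)) list(seed = config$seed)))
      sim <- simulate_dnb_data(spec)
      truth <- sim$truth
      write_expression(sim$expr, art("expression.tsv"))
      write_design(sim$design, art("design.csv"))
      jsonlite::write_json(truth, art("truth.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      sim
    } else {
      if (is.null(config$expr_path) || is.null(config$design_path)) {
        stop("expr_path and design_path required when simulate = FALSE")
      }
      expr <- read_expression(config$expr_path)
      design <- read_design(config$design_path,
                            stage_levels = config$stage_levels)
      check_design_matrix(expr, design)
      list(expr = expr, design = design, truth = NULL)
    }
  })
  expr <- dat$expr; design <- dat$design; truth <- dat$truth
  lv <- stage_levels(design)
  tick("data")

  # --- differential expression -----------------------------------------
  degs <- run_stage("deg", {
    d <- call_degs_all(expr, design, alpha = config$deg$alpha,
                       lfc = config$deg$lfc)
    for (s in names(d)) write_table(d[[s]], art(paste0("deg_", s, ".tsv")),
                                    sort_by = "gene")
    write_table(deg_summary(d), art("deg_summary.tsv"), sort_by = "stage")
    d
  })
  tick("deg")

  # --- DNB fit ----------------------------------------------------------
  fit <- run_stage("dnb", {
    f <- dnb(expr, design, min_size = config$dnb$min_size,
             max_size = config$dnb$max_size, top_k = config$dnb$top_k,
             epsilon = config$dnb$epsilon,
             sd_normalize = config$dnb$sd_normalize)
    write_table(f$scores, art("dnb_scores.tsv"), sort_by = "stage")
    writeLines(f$module, art("dnb_module.txt"))
    jsonlite::write_json(
      list(module = f$module, ci = f$scores$ci, stages = f$scores$stage,
           critical_stage = f$critical_label, peak_stage = f$peak_label,
           no_transition = f$no_transition),
      art("dnb.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f
  })
  tick("dnb")

  # --- co-expression ----------------------------------------------------
  coex <- NULL
  if (isTRUE(config$coexpress$enabled)) {
    coex <- run_stage("coexpress", {
      cases <- unlist(lapply(lv, function(s) case_samples(design, s)))
      scan <- soft_threshold_scan(expr, powers = config$coexpress$powers,
                                  samples = cases)
      beta <- pick_power(scan, target_r2 = config$coexpress$target_r2)
      A <- adjacency(expr, beta = beta, samples = cases)
      W <- tom(A)
      cm <- cluster_modules(W, min_module_size = config$coexpress$min_module_size,
                            cut_height = config$coexpress$cut_height)
      trait <- stats::setNames(
        as.integer(design$stage[match(cases, design$sample_id)]), cases)
      mtc <- if (length(cm$modules) > 0) {
        module_trait_cor(expr, cm, trait)
      } else data.frame(module = character(0), size = integer(0),
                        cor = numeric(0), p = numeric(0))
      write_table(scan, art("sft_scan.tsv"), sort_by = "power")
      write_table(data.frame(gene = names(cm$labels), module = unname(cm$labels),
                             stringsAsFactors = FALSE),
                  art("modules.tsv"), sort_by = "gene")
      write_table(mtc, art("module_trait.tsv"), sort_by = "module")
      list(scan = scan, beta = beta, assignment = cm, trait_cor = mtc)
    })
    tick("coexpress")
  }

  # --- hubs -------------------------------------------------------------
  hubs <- NULL
  if (isTRUE(config$hubs$enabled)) {
    hubs <- run_stage("hubs", {
      g <- if (!is.null(config$edges_path)) {
        read_edge_list(config$edges_path)
      } else {
        cases <- unlist(lapply(lv, function(s) case_samples(design, s)))
        dnb_cor_graph(expr, fit$module, cases, config$hubs$cor_threshold)
      }
      if (igraph::ecount(g) == 0) {
        warning("hub network has no edges; skipping hub ranking")
        NULL
      } else {
        metrics <- config$hubs$metrics
        if (identical(metrics, "all")) metrics <- eval(formals(compute_centralities)$metrics)
        hr <- compute_centralities(g, metrics = metrics,
                                   epc_trials = config$hubs$epc_trials,
                                   epc_p = config$hubs$epc_p,
                                   epc_seed = config$seed)
        consensus <- top_k_intersection(hr, config$hubs$k)
        write_table(hr$scores, art("hub_scores.tsv"), sort_by = "node")
        writeLines(consensus, art("hub_consensus.txt"))
        list(ranking = hr, consensus = consensus)
      }
    })
    tick("hubs")
  }

  # --- tumor-suppressor overlap ----------------------------------------
  supp <- run_stage("suppressors", {
    tsg <- NULL
    if (!is.null(config$tsg_path)) {
      tsg <- sort(unique(unlist(read_gmt(config$tsg_path))))
    } else if (!is.null(truth) && any(truth$de_genes < 0)) {
      tsg <- sort(names(truth$de_genes)[truth$de_genes < 0])
      write_gmt(list(TSG_SYNTHETIC = tsg), art("tsg_synthetic.gmt"),
                description = c(TSG_SYNTHETIC = "synthetic stand-in: planted down-regulated genes"))
    }
    if (is.null(tsg)) NULL else {
      ov <- suppressor_overlap(fit$module, degs, tsg)
      write_table(data.frame(stage = names(ov),
                             genes = vapply(ov, paste, character(1), collapse = ","),
                             stringsAsFactors = FALSE),
                  art("suppressors.tsv"), sort_by = "stage")
      ov
    }
  })
  tick("suppressors")

  # --- summary and manifest --------------------------------------------
  summary <- list(
    stages = lv,
    critical_stage = fit$critical_label,
    peak_stage = fit$peak_label,
    no_transition = fit$no_transition,
    ci = stats::setNames(as.list(fit$scores$ci), fit$scores$stage),
    dnb_module = fit$module,
    deg_counts = deg_summary(degs),
    soft_power = if (!is.null(coex)) coex$beta else NULL,
    top_trait_module = if (!is.null(coex) && nrow(coex$trait_cor) > 0)
      coex$trait_cor$module[1] else NULL,
    hub_consensus = if (!is.null(hubs)) hubs$consensus else NULL,
    suppressor_overlap = supp,
    warnings = warnings_seen
  )
  jsonlite::write_json(summary, art("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "dnbr",
    version = as.character(utils::packageVersion("dnbr")),
    config = unclass(config),
    files = as.list(tools::md5sum(file.path(out_dir, files))) |>
      stats::setNames(files)
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(dir = out_dir, summary = summary, manifest = manifest,
                 fit = fit))
}

# Threshold the |pcc| matrix among `genes` (case samples) into a simple graph.
dnb_cor_graph <- function(expr, genes, samples, threshold) {
  C <- abs_cor(expr[genes, samples, drop = FALSE], warn = FALSE)
  diag(C) <- 0
  idx <- which(C >= threshold & upper.tri(C), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, rbind(genes[idx[, 1]], genes[idx[, 2]]))
  }
  g
}

#' Render a human-readable pipeline report
#'
#' Reads a [run_all()] directory and renders deterministic text tables:
#' per-stage DNB scores, per-stage up/down differential-expression counts,
#' and the per-stage tumor-suppressor overlap, plus the co-expression and
#' hub sections when their artifacts are present (they are silently omitted
#' otherwise).
#'
#' @param run_dir a completed run directory.
#' @return invisibly, the report lines; printed to the console.
#' @export
report <- function(run_dir) {
  need <- c("summary.json", "dnb_scores.tsv", "deg_summary.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    stop("incomplete run; missing artifact(s): ", paste(missing, collapse = ", "))
  }
  summ <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                              simplifyVector = TRUE)
  scores <- utils::read.delim(file.path(run_dir, "dnb_scores.tsv"))
  degc <- utils::read.delim(file.path(run_dir, "deg_summary.tsv"))
  lines <- c(
    "== Dynamic network biomarker scores ==",
    sprintf("%-10s %-14s %s", "Stage", "Score", "Genes"),
    sprintf("%-10s %-14.8g %d", scores$stage, scores$ci,
            length(summ$dnb_module)),
    sprintf("Critical transition stage: %s (peak: %s)%s",
            summ$critical_stage, summ$peak_stage,
            if (isTRUE(summ$no_transition)) " [no rising transition]" else ""),
    "",
    "== Differential expression counts ==",
    sprintf("%-10s %-12s %s", "Stage", "Up", "Down"),
    sprintf("%-10s %-12d %d", degc$stage, degc$n_up, degc$n_down)
  )
  mt <- file.path(run_dir, "module_trait.tsv")
  if (file.exists(mt)) {
    m <- utils::read.delim(mt)
    m <- m[order(-abs(m$cor)), , drop = FALSE]
    lines <- c(lines, "", "== Co-expression modules vs stage ==",
               sprintf("%-14s %-6s %-10s %s", "Module", "Size", "Cor", "P"),
               sprintf("%-14s %-6d %-10.3f %.3g", m$module, m$size, m$cor, m$p),
               if (!is.null(summ$soft_power))
                 sprintf("Soft-thresholding power: %s", summ$soft_power))
  }
  hc <- file.path(run_dir, "hub_consensus.txt")
  if (file.exists(hc)) {
    cons <- readLines(hc)
    lines <- c(lines, "", "== Hub consensus ==",
               if (length(cons) > 0) paste("Top-k intersection:",
                                           paste(cons, collapse = ", "))
               else "Top-k intersection: (empty)")
  }
  sp <- file.path(run_dir, "suppressors.tsv")
  if (file.exists(sp)) {
    s <- utils::read.delim(sp, colClasses = "character")
    s$genes[is.na(s$genes) | s$genes == ""] <- "(none)"
    lines <- c(lines, "", "== Tumor suppressor overlap ==",
               sprintf("%-10s %s", "Stage", "Genes"),
               sprintf("%-10s %s", s$stage, s$genes))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
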