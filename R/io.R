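#' Read a gene x sample expression matrix from TSV
#'
#' The file must be tab-separated with the gene identifier in the first
#' column and one header row of sample identifiers.  Values are expected on
#' the log2 scale; use `log2 = TRUE` to apply `log2(x + 1)` at load for raw
#' intensities.  Row and column order are preserved exactly as in the file.
#'
#' Missing values are rejected unless `impute = TRUE`, in which case genes
#' missing in more than 20% of samples are dropped (with a message) and the
#' remaining gaps are filled with the gene's mean over observed samples.
#'
#' @param path path to a TSV file.
#' @param impute replace missing values by the gene mean (default `FALSE`:
#'   any missing value is an error).
#' @param log2 apply `log2(x + 1)` to the loaded values.
#' @return numeric matrix (genes x samples) with unique dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, impute = FALSE, log2 = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample column")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  samples <- colnames(df)[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0) stop("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric expression values in ", path)
  rownames(x) <- genes
  n_missing <- sum(is.na(x))
  if (n_missing > 0) {
    if (!impute) stop(n_missing, " missing value(s) in ", path,
                      "; rerun with impute = TRUE to gene-mean impute")
    frac <- rowMeans(is.na(x))
    drop <- frac > 0.2
    if (any(drop)) {
      message("dropping ", sum(drop), " gene(s) missing in > 20% of samples")
      x <- x[!drop, , drop = FALSE]
    }
    for (i in which(rowSums(is.na(x)) > 0)) {
      x[i, is.na(x[i, ])] <- mean(x[i, ], na.rm = TRUE)
    }
  }
  if (any(!is.finite(x))) stop("non-finite expression values in ", path)
  if (log2) x <- log2(x + 1)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: gene ids in the first column (`gene`),
#' sample ids as the header, row/column order preserved.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' The design maps each sample to a `group` (`"case"` or `"reference"`) and,
#' for case samples, an ordinal `stage` label.  Accepted as CSV or TSV
#' (decided by file extension, `.tsv`/`.txt` = tab) with columns
#' `sample_id`, `group`, `stage`.  Reference samples may leave `stage`
#' empty/NA.
#'
#' Invariants enforced: unique sample ids; at least 3 reference samples; at
#' least 3 case samples in every stage; every case stage label among the
#' allowed levels.
#'
#' @param path path to the design file.
#' @param stage_levels ordered character vector of allowed stage labels.
#'   Default `NULL`: levels are taken in order of first appearance among
#'   case rows.
#' @return `data.frame` with columns `sample_id`, `group`, and `stage` (an
#'   ordered factor; `NA` for reference samples).
#' @export
read_design <- function(path, stage_levels = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "group", "stage")
  if (!all(need %in% colnames(df))) {
    stop("design file must have columns: ", paste(need, collapse = ", "))
  }
  as_design(df[, need], stage_levels = stage_levels)
}

#' Construct and validate a stage design from a data frame
#'
#' @param df data frame with columns `sample_id`, `group`, `stage`.
#' @inheritParams read_design
#' @return validated design `data.frame` (see [read_design()]).
#' @export
as_design <- function(df, stage_levels = NULL) {
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  stage_chr <- as.character(df$stage)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) stop("duplicate sample ids in design: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$group), c("case", "reference"))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                            "; allowed: case, reference")
  case_stage <- stage_chr[df$group == "case"]
  if (anyNA(case_stage)) stop("case samples with missing stage label")
  if (is.null(stage_levels)) {
    stage_levels <- unique(case_stage)
  } else {
    unknown <- setdiff(unique(case_stage), stage_levels)
    if (length(unknown) > 0) {
      stop("unknown stage label(s): ", paste(unknown, collapse = ", "),
           "; allowed labels: ", paste(stage_levels, collapse = ", "))
    }
  }
  n_ref <- sum(df$group == "reference")
  if (n_ref < 3) stop("reference pool has ", n_ref, " samples; >= 3 required")
  tab <- table(factor(case_stage, levels = stage_levels))
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    stop("stage(s) with fewer than 3 case samples: ", paste(small, collapse = ", "))
  }
  out <- data.frame(sample_id = df$sample_id, group = df$group,
                    stage = factor(stage_chr, levels = stage_levels, ordered = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a design table as CSV
#' @param design design data frame from [read_design()] or [as_design()].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  df <- data.frame(sample_id = design$sample_id, group = design$group,
                   stage = as.character(design$stage), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, all tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique gene ids per set); set
#'   descriptions are kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line (need name, description, >= 1 gene): ", ln)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set '", parts[1], "' in ", path)
    sets[[parts[1]]] <- genes
    desc[parts[1]] <- parts[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && !is.na(description[nm])) description[nm] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from a two-column edge list
#'
#' Self-loops are dropped and duplicate edges (in either orientation)
#' collapsed, yielding a simple undirected graph.
#'
#' @param path path to a whitespace/tab-separated two-column file; a header
#'   row is detected when the first line is `from<TAB>to`.
#' @return an [igraph::graph] object.
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1)
  header <- identical(tolower(strsplit(first, "[\t ]+")[[1]])[1:2], c("from", "to"))
  df <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs two id columns")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a result table deterministically
#'
#' TSV writer for result data frames: rows sorted by the primary key
#' column(s), fixed column order, no quoting, so identical inputs produce
#' byte-identical files.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param sort_by column name(s) defining the row order (default: first
#'   column).
#' @export
write_table <- function(df, path, sort_by = colnames(df)[1]) {
  stopifnot(is.data.frame(df))
  if (nrow(df) > 0) {
    ord <- do.call(order, unname(df[, sort_by, drop = FALSE]))
    df <- df[ord, , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
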