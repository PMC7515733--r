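validate_expression <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric genes x cells matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(arg, " must carry gene row names and cell column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene names", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate cell names", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite expression values", call. = FALSE)
  if (any(x < 0)) stop("negative expression values", call. = FALSE)
  invisible(x)
}

#' Read an expression matrix
#'
#' Reads delimited text (genes in rows by default, first column holding gene
#' names, header holding cell names) or MatrixMarket triplets with gene and
#' barcode sidecar files. Always returns a genes x cells matrix whatever the
#' on-disk orientation.
#'
#' @param path file path (the `.mtx` file for MatrixMarket input).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param orientation layout on disk.
#' @param genes_file,barcodes_file sidecar name files for `mtx` (defaults:
#'   `genes.tsv` / `barcodes.tsv` next to `path`); first column is used.
#' @return Numeric genes x cells matrix with dimnames.
#' @export
read_expression <- function(path,
                            format = c("csv", "tsv", "mtx"),
                            orientation = c("genes_by_cells",
                                            "cells_by_genes"),
                            genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_file)) {
      barcodes_file <- file.path(dirname(path), "barcodes.tsv")
    }
    if (!file.exists(genes_file) || !file.exists(barcodes_file)) {
      stop("mtx input needs gene and barcode sidecar files")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.table(genes_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(barcodes_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    if (orientation == "cells_by_genes") m <- t(m)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar name counts (", length(genes), " genes, ",
           length(cells), " cells)")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    delim <- if (format == "csv") "," else "\t"
    tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             progress = FALSE)
    rn <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- rn
    if (orientation == "cells_by_genes") m <- t(m)
  }
  validate_expression(m, "expression input")
  m
}

#' Write an expression matrix
#'
#' @param x genes x cells matrix.
#' @param path output path (`.mtx` writes sidecar `genes.tsv`/`barcodes.tsv`).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  validate_expression(x)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(x), file.path(dirname(path), "barcodes.tsv"))
  } else {
    delim <- if (format == "csv") "," else "\t"
    tab <- tibble::as_tibble(x, rownames = "gene")
    readr::write_delim(tab, path, delim = delim)
  }
  invisible(path)
}

#' Remove low-expressed cells
#'
#' Drops cells expressing (value > 0) fewer than `min_gene_fraction` of the
#' genes in the input matrix.
#'
#' @param x genes x cells matrix.
#' @param min_gene_fraction fraction of genes a cell must express.
#' @return Filtered genes x cells matrix.
#' @export
filter_cells <- function(x, min_gene_fraction = 0.05) {
  validate_expression(x)
  stopifnot(min_gene_fraction >= 0, min_gene_fraction <= 1)
  expressed <- colSums(x > 0)
  keep <- expressed >= min_gene_fraction * nrow(x)
  if (!any(keep)) stop("all cells removed by the cell filter")
  x[, keep, drop = FALSE]
}

#' Remove rare and flat genes
#'
#' Drops genes expressed (value > 0) in fewer than `min_cell_fraction` of
#' cells, and genes whose population variance across all cells falls below
#' `min_variance`.
#'
#' @param x genes x cells matrix.
#' @param min_cell_fraction fraction of cells a gene must be expressed in.
#' @param min_variance variance floor (population variance, i.e. divided
#'   by n).
#' @return Filtered genes x cells matrix.
#' @export
filter_genes <- function(x, min_cell_fraction = 0.10, min_variance = 0.005) {
  validate_expression(x)
  stopifnot(min_cell_fraction >= 0, min_variance >= 0)
  n <- ncol(x)
  expressed <- rowSums(x > 0)
  mu <- rowMeans(x)
  pop_var <- rowMeans((x - mu)^2)
  keep <- expressed >= min_cell_fraction * n & pop_var >= min_variance
  if (!any(keep)) stop("all genes removed by the gene filter")
  x[keep, , drop = FALSE]
}

#' Select informative (bimodally expressed) genes
#'
#' Fits each gene with a three-component univariate Gaussian mixture. Genes
#' dominated by a zero-mean component (weight above `zero_weight_cutoff`) are
#' discarded as rarely expressed. The remaining genes are ranked twice: by
#' the difference of the means of their two heaviest components (descending;
#' well-separated modes first) and by the difference of the weights of those
#' components (ascending; balanced modes first). The two ranks are summed and
#' the `n_top` genes with the smallest aggregate rank are selected.
#'
#' @param x genes x cells matrix, already cell/gene filtered.
#' @param n_top number of genes to select.
#' @param zero_weight_cutoff weight above which a zero-mean-dominated gene is
#'   dropped.
#' @param log_transform apply `log1p` before fitting (off by default; qPCR
#'   style input is typically already on a log-like scale).
#' @param seed integer seed (the mixture fit is deterministic given the data;
#'   kept for interface stability).
#' @return Object of class `feature_selection`: list with `selected_genes`
#'   (ordered) and `report` (per-gene tibble of weights, means and ranks).
#' @export
select_informative_genes <- function(x, n_top = 3000,
                                     zero_weight_cutoff = 0.90,
                                     log_transform = FALSE, seed = 1L) {
  validate_expression(x)
  stopifnot(n_top >= 1, zero_weight_cutoff > 0, zero_weight_cutoff <= 1)
  set.seed(as.integer(seed))
  genes <- rownames(x)
  failed_row <- tibble::tibble(w1 = NA_real_, w2 = NA_real_, w3 = NA_real_,
                               mu1 = NA_real_, mu2 = NA_real_,
                               mu3 = NA_real_, zero_weight = NA_real_,
                               mean_diff = NA_real_, weight_diff = NA_real_)
  try_mclust <- function(y, G) {
    for (mod in c("V", "E")) {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(y, G = G, modelNames = mod,
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit)) return(fit)
    }
    NULL
  }
  fit_one <- function(y) {
    if (log_transform) y <- log1p(y)
    rng <- diff(range(y))
    p0 <- mean(y == 0)
    if (p0 > 0.1) {
      # dropout-heavy gene: the zero observations are a point mass a plain
      # Gaussian mixture cannot represent; treat them as the zero-mean
      # component and fit the two remaining components to the positive part
      pos <- y[y > 0]
      if (length(pos) < 5 || diff(range(pos)) == 0) {
        return(dplyr::mutate(failed_row, zero_weight = p0))
      }
      fit <- try_mclust(pos, 2)
      if (is.null(fit)) return(dplyr::mutate(failed_row, zero_weight = p0))
      w <- c(p0, (1 - p0) * fit$parameters$pro)
      mu <- c(0, as.numeric(fit$parameters$mean))
    } else {
      fit <- try_mclust(y, 3)
      if (is.null(fit)) return(failed_row)
      w <- fit$parameters$pro
      mu <- as.numeric(fit$parameters$mean)
    }
    # component closest to zero counts as the dropout component only when its
    # mean is genuinely near zero relative to the data range
    zi <- which.min(abs(mu))
    zero_w <- if (abs(mu[zi]) < 0.1 * max(rng, 1e-12)) w[zi] else 0
    top <- order(w, decreasing = TRUE)[1:2]
    tibble::tibble(w1 = w[1], w2 = w[2], w3 = w[3],
                   mu1 = mu[1], mu2 = mu[2], mu3 = mu[3],
                   zero_weight = zero_w,
                   mean_diff = abs(mu[top[1]] - mu[top[2]]),
                   weight_diff = abs(w[top[1]] - w[top[2]]))
  }
  report <- purrr::map_dfr(seq_len(nrow(x)), function(i) fit_one(x[i, ]))
  report <- dplyr::mutate(report, gene = genes, .before = 1)
  n_failed <- sum(is.na(report$mean_diff))
  if (n_failed > 0) {
    warning(n_failed, " gene(s) could not be fitted and were excluded ",
            "from selection")
  }
  eligible <- dplyr::filter(report, !is.na(.data$mean_diff),
                            .data$zero_weight <= zero_weight_cutoff)
  eligible <- dplyr::mutate(
    eligible,
    rank_mean_diff = rank(-.data$mean_diff, ties.method = "first"),
    rank_weight_diff = rank(.data$weight_diff, ties.method = "first"),
    aggregate_rank = .data$rank_mean_diff + .data$rank_weight_diff
  )
  eligible <- dplyr::arrange(eligible, .data$aggregate_rank, .data$gene)
  if (nrow(eligible) < n_top) {
    warning("only ", nrow(eligible), " genes survive selection (requested ",
            n_top, "); returning all")
  }
  selected <- utils::head(eligible$gene, n_top)
  report <- dplyr::left_join(
    report,
    dplyr::select(eligible, "gene", "rank_mean_diff", "rank_weight_diff",
                  "aggregate_rank"),
    by = "gene")
  report$selected <- report$gene %in% selected
  structure(list(selected_genes = selected, report = report,
                 n_top = n_top, zero_weight_cutoff = zero_weight_cutoff),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", length(x$selected_genes), " of ",
      nrow(x$report), " genes selected\n", sep = "")
  invisible(x)
}

#' Per-gene feature-selection report
#'
#' @param x a `feature_selection`.
#' @param ... unused.
#' @return Tibble with mixture weights, means, ranks and selection flags.
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) x$report
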