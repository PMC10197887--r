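# Bulk-expression statistics: cytolytic score, score-correlated gene
# ranking, and gene-set mean scores. Expression matrices are genes x
# samples on a TPM-like nonnegative scale, rownames = gene symbols.

check_expr <- function(expr) {
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols")
  if (any(expr < 0)) stop("negative expression values")
  invisible(expr)
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of PRF1 and GZMA expression per sample, with a small
#' pseudo-abundance added to each gene so all-zero samples stay finite:
#' `sqrt((PRF1 + offset) * (GZMA + offset))`.
#'
#' @param expr Genes x samples matrix (TPM scale).
#' @param offset Pseudo-abundance (default 0.01; 0 is allowed when both
#'   genes are positive everywhere).
#' @return Named numeric vector of per-sample scores.
#' @export
cyt_score <- function(expr, offset = 0.01) {
  check_expr(expr)
  for (g in c("PRF1", "GZMA"))
    if (!g %in% rownames(expr)) stop("gene missing from matrix: ", g)
  if (offset < 0) stop("offset must be >= 0")
  sqrt((expr["PRF1", ] + offset) * (expr["GZMA", ] + offset))
}

#' Rank genes by correlation with a per-sample score
#'
#' Computes the rank (Spearman) correlation of every gene's expression with
#' the score, orders genes by descending correlation, optionally drops
#' non-positive correlations, and truncates to the strongest `top_n`. This
#' produces e.g. the top-400 AMS-correlated gene list used as GSEA input.
#'
#' @param expr Genes x samples matrix.
#' @param score Named numeric vector covering all samples of `expr`.
#' @param method Correlation method (only `"spearman"` supported).
#' @param top_n Keep at most this many genes (`Inf` keeps all).
#' @param positive_only Drop genes with correlation <= 0 (default `TRUE`).
#' @return data.frame with `gene` and `rho`, ordered by descending `rho`.
#' @export
score_correlated_genes <- function(expr, score, method = "spearman",
                                   top_n = Inf, positive_only = TRUE) {
  check_expr(expr)
  method <- match.arg(method, "spearman")
  score <- score[colnames(expr)]
  if (any(is.na(score))) stop("score missing for some samples")
  if (length(score) < 3L) stop("need at least 3 samples")
  if (length(unique(score)) < 2L) stop("score is constant")
  rho <- apply(expr, 1, function(x) {
    if (sd(x) == 0) return(NA_real_)
    cor(x, score, method = "spearman")
  })
  out <- data.frame(gene = rownames(expr), rho = unname(rho),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$rho), , drop = FALSE]
  if (positive_only) out <- out[out$rho > 0, , drop = FALSE]
  out <- out[order(-out$rho), , drop = FALSE]
  head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}

#' Mean gene-set score per sample
#'
#' Scores each sample as the mean over the listed genes of (optionally
#' log1p-transformed, gene-wise z-scored) expression. Genes absent from
#' the matrix are dropped with a warning naming them; genes with zero
#' variance contribute 0 after z-scoring.
#'
#' @param expr Genes x samples matrix.
#' @param genes Character vector of gene symbols.
#' @param transform `"log1p_zscore"` (default), `"zscore"` (gene-wise
#'   standardization without the log, invariant to per-gene affine
#'   scaling), or `"none"` (plain mean of raw values).
#' @return Named numeric vector of per-sample scores.
#' @export
geneset_score <- function(expr, genes, transform = c("log1p_zscore",
                                                     "zscore", "none")) {
  check_expr(expr)
  transform <- match.arg(transform)
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, present)
  if (!length(present)) stop("none of the listed genes are in the matrix")
  if (length(missing))
    warning("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  m <- expr[present, , drop = FALSE]
  if (transform != "none") {
    if (transform == "log1p_zscore") m <- log1p(m)
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    sdv[sdv == 0] <- 1  # constant genes contribute 0, not NaN
    m <- (m - mu) / sdv
  }
  colMeans(m)
}
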