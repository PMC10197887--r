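# Single-cell statistics: QC filtering, Ro/e group enrichment,
# reference-gene correlation signatures, and seeded downsampling.
# Cell metadata is a data.frame with columns cell, sample, group,
# cell_type, n_genes, total_counts, pct_mito.

#' Quality-control filter on cell metadata
#'
#' Keeps cells with `gene_range[1] <= n_genes <= gene_range[2]`,
#' `total_counts <= max_counts` and `pct_mito <= max_mito_pct` (all bounds
#' inclusive). Removal reasons are tallied per criterion; a cell failing
#' several criteria counts toward each.
#'
#' @param meta Cell metadata data.frame with `n_genes`, `total_counts`,
#'   `pct_mito`.
#' @param gene_range Inclusive detected-gene bounds (default `c(300,
#'   8000)`).
#' @param max_counts Maximum total counts (default 20000).
#' @param max_mito_pct Maximum mitochondrial percentage (default 10).
#' @return Filtered metadata; per-criterion removal counts in
#'   `attr(, "removed")`.
#' @export
qc_filter <- function(meta, gene_range = c(300, 8000), max_counts = 20000,
                      max_mito_pct = 10) {
  need <- c("n_genes", "total_counts", "pct_mito")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta missing column(s): ",
                         paste(miss, collapse = ", "))
  low <- meta$n_genes < gene_range[1]
  high <- meta$n_genes > gene_range[2]
  cnt <- meta$total_counts > max_counts
  mito <- meta$pct_mito > max_mito_pct
  keep <- !(low | high | cnt | mito)
  if (!any(keep)) warning("QC filter removed every cell")
  out <- meta[keep, , drop = FALSE]
  attr(out, "removed") <- c(genes_low = sum(low), genes_high = sum(high),
                            counts_high = sum(cnt), mito_high = sum(mito),
                            total = sum(!keep))
  out
}

#' Ro/e cell-type enrichment across groups
#'
#' For each (cell type, group) cell the observed count `o` is compared with
#' the chi-square-style expectation
#' `e = row total x column total / grand total`; a cell type is flagged
#' enriched in a group when `o/e > 1`. The expected table conserves the
#' margins, so the totals of `o` and `e` agree exactly.
#'
#' @param meta Cell metadata data.frame.
#' @param group_key,type_key Column names holding group and cell-type
#'   labels (defaults `"group"`, `"cell_type"`).
#' @return data.frame with `cell_type`, `group`, `o`, `e`, `ratio`,
#'   `enriched`.
#' @export
roe_enrichment <- function(meta, group_key = "group",
                           type_key = "cell_type") {
  tab <- table(meta[[type_key]], meta[[group_key]])
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need >= 2 cell types and >= 2 groups")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in cell type x group table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  out <- data.frame(cell_type = rep(rownames(tab), times = ncol(tab)),
                    group = rep(colnames(tab), each = nrow(tab)),
                    o = as.vector(unclass(tab)),
                    e = as.vector(e),
                    stringsAsFactors = FALSE)
  out$ratio <- out$o / out$e
  out$enriched <- out$ratio > 1
  out
}

#' Reference-gene correlation signature
#'
#' Ranks candidate genes by their correlation with a reference gene across
#' cells (Spearman on log1p counts by default, the convention for
#' defining e.g. an exhaustion score around HAVCR2 or a regulation score
#' around IL2RA) and returns the strongest `top_n`. The reference gene is
#' removed from the candidate list if present.
#'
#' @param expr Genes x cells matrix of counts or normalized expression.
#' @param ref_gene Reference gene symbol (must be expressed in >= 3
#'   cells).
#' @param candidate_genes Candidate gene symbols.
#' @param top_n Number of genes to return (default 30).
#' @param method `"spearman"` (default, on log1p values) or `"pearson"`.
#' @return data.frame with `gene` and `rho`, ordered by descending `rho`.
#' @export
refgene_signature <- function(expr, ref_gene, candidate_genes, top_n = 30,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!ref_gene %in% rownames(expr)) stop("reference gene absent: ",
                                          ref_gene)
  x <- as.numeric(expr[ref_gene, ])
  if (sum(x > 0) < 3L) stop("reference gene expressed in < 3 cells")
  candidate_genes <- setdiff(unique(candidate_genes), ref_gene)
  present <- intersect(candidate_genes, rownames(expr))
  if (!length(present)) stop("no candidate genes present in matrix")
  m <- as.matrix(expr[present, , drop = FALSE])
  if (method == "spearman") { m <- log1p(m); x <- log1p(x) }
  rho <- apply(m, 1, function(gv) {
    if (sd(gv) == 0) return(NA_real_)
    cor(gv, x, method = method)
  })
  out <- data.frame(gene = present, rho = unname(rho),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$rho), , drop = FALSE]
  out <- out[order(-out$rho), , drop = FALSE]
  head(out, top_n)
}

#' Seeded per-group downsampling of cells
#'
#' Uniform sampling without replacement within each group; groups at or
#' below `per_group_n` are kept whole. Deterministic for a given seed.
#'
#' @param meta Cell metadata data.frame.
#' @param per_group_n Cells to keep per group (default 1000).
#' @param group_key Grouping column (default `"cell_type"`, the
#'   trajectory-analysis convention).
#' @param seed Integer seed (required).
#' @return Subset of `meta`, original row order preserved.
#' @export
downsample_cells <- function(meta, per_group_n = 1000,
                             group_key = "cell_type", seed) {
  if (missing(seed)) stop("seed is required")
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(meta)), meta[[group_key]]),
                  function(i) {
                    if (length(i) <= per_group_n) i
                    else sample(i, per_group_n)
                  }), use.names = FALSE)
  })
  meta[sort(idx), , drop = FALSE]
}
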