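# Two-stage mutation-pathway enrichment between cohort groups, plus the
# BH adjustment and GMT reading it relies on.

#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, genes... per tab-separated
#'   line).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1], " in ", path)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1L))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotone enforcement, order-preserving with the input
#' (a validating wrapper over [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

count_pathway_muts <- function(genes, sets) {
  vapply(sets, function(g) sum(genes %in% g), integer(1))
}

#' Two-stage mutation-pathway enrichment between groups
#'
#' Stage 1 screens pathways against a gene-count-proportional background:
#' for each pathway the observed split of cohort mutations into pathway vs
#' non-pathway genes is compared (two-sided Fisher) with the split expected
#' if mutations fell on universe genes uniformly. Pathways with
#' `p < stage1_p` and BH FDR `< stage1_fdr` advance. Stage 2 tests each
#' candidate's 2x2 table of mutation counts, pathway vs elsewhere crossed
#' with the two sample groups, again by two-sided Fisher with BH adjustment
#' across candidates. Pathways without any mutation in either group are
#' skipped (recorded in `attr(stage2, "skipped")`).
#'
#' @param records Mutation record data.frame with a `gene` column.
#' @param gene_sets Named list of gene symbol vectors (e.g. [read_gmt()]).
#' @param labels Named vector mapping sample to one of exactly two groups;
#'   the first sorted level is "group1" in the output.
#' @param universe Gene universe for the stage-1 background; defaults to
#'   the union of all set genes and all mutated genes.
#' @param stage1_p,stage1_fdr Stage-1 significance thresholds (defaults
#'   0.05 and 0.25).
#' @return List with `stage1` and `stage2` data.frames (counts `a`-`d`,
#'   `odds_ratio`, `p_fisher`, `fdr`, `significant`).
#' @export
pathway_mutation_enrichment <- function(records, gene_sets, labels,
                                        universe = NULL,
                                        stage1_p = 0.05, stage1_fdr = 0.25) {
  if (!length(gene_sets)) stop("empty gene set list")
  g <- labels[records$sample]
  keep <- !is.na(g) & !is.na(records$gene) & nzchar(records$gene)
  rec <- records[keep, , drop = FALSE]
  g <- g[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must define exactly two groups")
  if (!all(lev %in% g)) stop("both groups need at least one mutation")
  if (is.null(universe))
    universe <- union(unlist(gene_sets), unique(rec$gene))
  sets <- lapply(gene_sets, intersect, universe)
  N <- nrow(rec)
  obs <- count_pathway_muts(rec$gene, sets)
  frac <- vapply(sets, length, integer(1)) / length(universe)
  exp_a <- round(N * frac)
  stage1 <- data.frame(pathway = names(sets),
                       a = obs, b = N - obs,
                       c = as.integer(exp_a), d = as.integer(N - exp_a),
                       stringsAsFactors = FALSE, row.names = NULL)
  ftest <- function(a, b, c, d)
    fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  stage1$odds_ratio <- with(stage1, ifelse(b * c > 0, (a * d) / (b * c),
                                           Inf))
  stage1$p_fisher <- mapply(ftest, stage1$a, stage1$b, stage1$c, stage1$d)
  stage1$fdr <- bh_adjust(stage1$p_fisher)
  stage1$significant <- stage1$p_fisher < stage1_p & stage1$fdr < stage1_fdr
  cand <- stage1$pathway[stage1$significant]
  g1 <- rec$gene[g == lev[1]]
  g2 <- rec$gene[g == lev[2]]
  a <- count_pathway_muts(g1, sets[cand])
  c_ <- count_pathway_muts(g2, sets[cand])
  skipped <- cand[a + c_ == 0]
  use <- a + c_ > 0
  stage2 <- data.frame(pathway = cand[use],
                       a = a[use], b = length(g1) - a[use],
                       c = c_[use], d = length(g2) - c_[use],
                       stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(stage2)) {
    stage2$odds_ratio <- with(stage2, ifelse(b * c > 0, (a * d) / (b * c),
                                             Inf))
    stage2$p_fisher <- mapply(ftest, stage2$a, stage2$b, stage2$c, stage2$d)
    stage2$fdr <- bh_adjust(stage2$p_fisher)
  } else {
    stage2$odds_ratio <- stage2$p_fisher <- stage2$fdr <- numeric(0)
  }
  attr(stage2, "skipped") <- skipped
  attr(stage2, "groups") <- setNames(lev, c("group1", "group2"))
  list(stage1 = stage1, stage2 = stage2)
}
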