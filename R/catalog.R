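# 96-channel catalog construction with pyrimidine strand normalization.

# Vectorized channel assignment for SNV records. Returns a data.frame with
# `channel` (NA when unclassifiable) and `reason` in
# {"ok","not_snv","ref_mismatch","edge","n_context"}.
classify_sbs96 <- function(records, genome) {
  validate_genome(genome)
  n <- nrow(records)
  channel <- rep(NA_character_, n)
  reason <- rep("ok", n)
  reason[records$variant_class != "SNV"] <- "not_snv"
  snv <- which(reason == "ok")
  for (chrom in unique(records$chrom[snv])) {
    i <- snv[records$chrom[snv] == chrom]
    s <- genome[[chrom]]
    if (is.null(s)) { reason[i] <- "ref_mismatch"; next }
    L <- nchar(s)
    pos <- records$pos[i]
    at_edge <- pos < 2L | pos > (L - 1L)
    inside <- pos >= 1L & pos <= L
    base <- rep(NA_character_, length(i))
    base[inside] <- substring(s, pos[inside], pos[inside])
    mism <- !inside | is.na(base) | base != records$ref[i]
    reason[i[mism]] <- "ref_mismatch"
    reason[i[!mism & at_edge]] <- "edge"
    use <- i[!mism & !at_edge]
    if (!length(use)) next
    p <- records$pos[use]
    up <- substring(s, p - 1L, p - 1L)
    dn <- substring(s, p + 1L, p + 1L)
    ref <- records$ref[use]
    alt <- records$alt[use]
    pur <- ref %in% c("A", "G")
    # pyrimidine normalization: flip substitution and flanks for purine refs
    nref <- ifelse(pur, COMPLEMENT[ref], ref)
    nalt <- ifelse(pur, COMPLEMENT[alt], alt)
    nf5 <- ifelse(pur, COMPLEMENT[dn], up)
    nf3 <- ifelse(pur, COMPLEMENT[up], dn)
    hasN <- nf5 == "N" | nf3 == "N" | is.na(nf5) | is.na(nf3)
    reason[use[hasN]] <- "n_context"
    ok <- use[!hasN]
    keep <- !hasN
    channel[ok] <- paste0(nf5[keep], "[", nref[keep], ">", nalt[keep], "]",
                          nf3[keep])
  }
  data.frame(channel = channel, reason = reason, stringsAsFactors = FALSE)
}

#' Pyrimidine-normalized trinucleotide channel of one SNV
#'
#' If the reference base is a purine, the substitution and both flanks are
#' reverse complemented so the returned label always has a C or T center
#' (e.g. a G>A change in a `TGA` context reports as `"T[C>T]A"`).
#' Unclassifiable positions (flanking N, contig edge, reference mismatch)
#' return `NA` with the reason in `attr(, "reason")`.
#'
#' @param genome Named character genome vector.
#' @param chrom,pos,ref,alt SNV description, `pos` 1-based.
#' @return Channel label such as `"T[C>T]A"`, or `NA`.
#' @export
#' @examples
#' g <- c(chr1 = "ATCAT")
#' trinucleotide_context(g, "chr1", 3, "C", "T")  # "T[C>T]A"
trinucleotide_context <- function(genome, chrom, pos, ref, alt) {
  rec <- mutation_records("s", chrom, pos, ref, alt,
                              infer_variant_class(toupper(ref), toupper(alt)),
                              "unknown")
  if (rec$variant_class != "SNV") stop("not an SNV: ", ref, ">", alt)
  cls <- classify_sbs96(rec, genome)
  out <- cls$channel
  attr(out, "reason") <- cls$reason
  out
}

#' Build a samples x 96 mutation catalog
#'
#' Counts classifiable SNVs per sample over the channel order of
#' [sbs96_channels()]. Indels and SNVs with N-containing or truncated
#' contexts are excluded from the matrix; per-sample exclusion tallies are
#' attached as `attr(, "excluded")`.
#'
#' @param records Mutation record data.frame.
#' @param genome Named character genome vector.
#' @param samples Optional sample ordering (defaults to order of first
#'   appearance); samples with zero classifiable SNVs keep an all-zero row.
#' @return Integer matrix (samples x 96) of class `"mutation_catalog"`.
#' @export
build_catalog <- function(records, genome, samples = NULL) {
  cls <- classify_sbs96(records, genome)
  if (is.null(samples)) samples <- unique(records$sample)
  ok <- !is.na(cls$channel)
  if (!any(ok)) stop("no classifiable SNVs in input")
  channels <- sbs96_channels()
  counts <- table(factor(records$sample[ok], levels = samples),
                  factor(cls$channel[ok], levels = channels))
  m <- matrix(as.integer(counts), nrow = length(samples),
              dimnames = list(samples, channels))
  excl <- as.data.frame.matrix(table(
    factor(records$sample, levels = samples),
    factor(cls$reason, levels = c("ok", "not_snv", "ref_mismatch",
                                  "edge", "n_context"))))
  structure(m, excluded = excl, class = c("mutation_catalog", "matrix",
                                          "array"))
}

#' Write / read a mutation catalog as TSV
#'
#' The TSV has one row per sample with a leading `sample` column and the 96
#' channel labels as remaining columns; a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param catalog Catalog matrix from [build_catalog()].
#' @param path TSV path.
#' @return `write_catalog`: `path` invisibly; `read_catalog`: the matrix.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(sample = rownames(catalog), unclass(catalog),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "sample") ||
      !identical(names(df)[-1], sbs96_channels()))
    stop("not a catalog TSV: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$sample
  structure(m, class = c("mutation_catalog", "matrix", "array"))
}

#' Tumor mutation burden per sample
#'
#' TMB is the count of nonsynonymous SNVs plus indels, divided by the
#' target territory in megabases. Variants with `effect == "unknown"` are
#' counted only when `include_unknown = TRUE`; indels count regardless of
#' effect annotation.
#'
#' @param records Mutation record data.frame.
#' @param target_mb Target territory in Mb (must be > 0); default 38 is a
#'   whole-exome-like footprint.
#' @param include_unknown Count effect-unknown SNVs in the numerator.
#' @return data.frame with `sample`, `n_nonsyn_snv`, `n_indel`,
#'   `target_mb`, `tmb`.
#' @export
compute_tmb <- function(records, target_mb = 38, include_unknown = FALSE) {
  if (!is.numeric(target_mb) || length(target_mb) != 1L || target_mb <= 0)
    stop("target_mb must be a single positive number")
  samples <- unique(records$sample)
  eff_ok <- records$effect == "nonsynonymous" |
    (include_unknown & records$effect == "unknown")
  nsnv <- table(factor(records$sample[records$variant_class == "SNV" & eff_ok],
                       levels = samples))
  nind <- table(factor(records$sample[records$variant_class == "indel"],
                       levels = samples))
  data.frame(sample = samples,
             n_nonsyn_snv = as.integer(nsnv),
             n_indel = as.integer(nind),
             target_mb = target_mb,
             tmb = (as.integer(nsnv) + as.integer(nind)) / target_mb,
             stringsAsFactors = FALSE)
}
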