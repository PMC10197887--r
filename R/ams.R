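# APOBEC enrichment score (AMS) and YTCA/RTCA tetranucleotide attribution.
#
# All classification happens on the pyrimidine-normalized strand: a mutated
# G is read through its reverse complement, so "TCW" counts cover TCW on
# the plus strand and WGA occurrences (the reverse-complement image) alike.

TCW_TRIPLETS <- c("TCA", "TCT", "TGA", "AGA")  # TCW plus its WGA image

# Normalized bases at offsets -2, -1, +1 of each SNV (NA when outside the
# contig). Purine references are reverse complemented first.
motif_bases <- function(records, genome) {
  validate_genome(genome)
  n <- nrow(records)
  b_m2 <- b_m1 <- b_p1 <- rep(NA_character_, n)
  snv <- which(records$variant_class == "SNV" &
                 records$ref %in% c("C", "G", "T", "A"))
  for (chrom in unique(records$chrom[snv])) {
    i <- snv[records$chrom[snv] == chrom]
    s <- genome[[chrom]]
    if (is.null(s)) next
    L <- nchar(s)
    p <- records$pos[i]
    at <- function(q) ifelse(q >= 1L & q <= L, substring(s, q, q),
                             NA_character_)
    pur <- records$ref[i] %in% c("A", "G")
    b_m1[i] <- ifelse(pur, unname(COMPLEMENT[at(p + 1L)]), at(p - 1L))
    b_p1[i] <- ifelse(pur, unname(COMPLEMENT[at(p - 1L)]), at(p + 1L))
    b_m2[i] <- ifelse(pur, unname(COMPLEMENT[at(p + 2L)]), at(p - 2L))
  }
  data.frame(b_m2 = b_m2, b_m1 = b_m1, b_p1 = b_p1,
             stringsAsFactors = FALSE)
}

# Eligible AMS mutations: SNVs at a C (or G) whose normalized substitution
# falls in the configured set.
ams_eligible <- function(records, subs = c("ct_cg", "all")) {
  subs <- match.arg(subs)
  is_c <- records$variant_class == "SNV" & records$ref %in% c("C", "G")
  if (subs == "all") return(is_c)
  nalt <- ifelse(records$ref == "G", unname(COMPLEMENT[records$alt]),
                 records$alt)
  is_c & nalt %in% c("T", "G")
}

#' Classify the APOBEC motif of one SNV
#'
#' After pyrimidine normalization, the mutation sits in a TCW motif iff the
#' base 5' of the mutated C is T and the base 3' is A or T. TCW mutations
#' are refined by the base at offset -2: a pyrimidine (Y) marks the
#' APOBEC3A-preferred class, a purine (R) the APOBEC3B-preferred class,
#' split further by whether the 3' base is A (`YTCA`/`RTCA`) or T
#' (`YTCW_nonA`/`RTCW_nonA`). Missing or N bases at offsets -2..+1 give
#' `"none"` with `flagged = TRUE`.
#'
#' @param genome Named character genome vector.
#' @param chrom,pos,ref,alt SNV description, `pos` 1-based.
#' @return List with `is_tcw`, `tetramer_class`, `flagged`.
#' @export
#' @examples
#' g <- c(chr1 = "ACTCAG")
#' classify_apobec_motif(g, "chr1", 4, "C", "T")  # CTCA -> YTCA
classify_apobec_motif <- function(genome, chrom, pos, ref, alt) {
  rec <- mutation_records("s", chrom, pos, toupper(ref), toupper(alt),
                              "SNV", "unknown")
  b <- motif_bases(rec, genome)
  flagged <- is.na(b$b_m2) || is.na(b$b_m1) || is.na(b$b_p1) ||
    any(c(b$b_m2, b$b_m1, b$b_p1) == "N")
  is_tcw <- !is.na(b$b_m1) && !is.na(b$b_p1) &&
    b$b_m1 == "T" && b$b_p1 %in% c("A", "T")
  cls <- "none"
  if (is_tcw && !flagged) {
    y <- b$b_m2 %in% c("C", "T")
    cls <- if (b$b_p1 == "A") {
      if (y) "YTCA" else "RTCA"
    } else {
      if (y) "YTCW_nonA" else "RTCW_nonA"
    }
  }
  list(is_tcw = is_tcw && !is.na(b$b_m1), tetramer_class = cls,
       flagged = flagged)
}

count_tcw_motifs <- function(windows) {
  vapply(windows, function(w) {
    L <- nchar(w)
    if (L < 3L) return(0L)
    sum(substring(w, 1:(L - 2L), 3:L) %in% TCW_TRIPLETS)
  }, integer(1), USE.NAMES = FALSE)
}

# C+G bases at motif-eligible window positions. Two classes of positions
# can never center a fully observable TCW/WGA motif and are excluded from
# the background tally, since counting them biases the context fraction
# low (and hence the enrichment score high) under a motif-free null:
#   - the first and last base of the window (their flank lies outside);
#   - the two bases adjacent to the window center (their required T/W
#     flank is the mutated C/G itself).
count_cg <- function(windows, center) {
  vapply(seq_along(windows), function(i) {
    v <- strsplit(windows[i], "", fixed = TRUE)[[1]]
    keep <- setdiff(2:(length(v) - 1L), c(center[i] - 1L, center[i] + 1L))
    sum(v[keep] %in% c("C", "G"))
  }, integer(1))
}

#' APOBEC mutagenesis enrichment score per sample
#'
#' For every eligible mutated cytosine (or guanine, read on the complement)
#' the numerator tallies whether it falls in a TCW motif; the denominator
#' tallies, over the (2*window + 1)-nucleotide region centered on each
#' eligible mutation, the TCW motifs (both strands) and the C+G bases.
#' The score is
#' \deqn{AMS = (mut_{TCW}/mut_C) / (ctx_{TCW}/ctx_C)}
#' Windows are truncated at contig ends and overlap freely (each mutation
#' contributes its own window); N bases never count. C and G bases are
#' tallied only at window positions that could center a fully observable
#' motif: the outermost window base on each side (flank outside the
#' window) and the two bases adjacent to the mutated center (their
#' required T/W flank is the mutated C/G itself) are skipped. This keeps
#' the motif and base tallies commensurable, so the score is centered at
#' 1 when mutations carry no motif preference.
#'
#' @param records Mutation record data.frame.
#' @param genome Named character genome vector.
#' @param window Half-width of the context window (default 20, i.e. 41 nt).
#' @param subs Eligible substitutions: `"ct_cg"` (C>T and C>G, the Roberts
#'   convention, default) or `"all"` (any mutated C/G).
#' @return data.frame with per-sample `n_mut_tcw`, `n_mut_c`, `n_ctx_tcw`,
#'   `n_ctx_c` and `ams` (`NA` when a denominator is zero).
#' @export
compute_ams <- function(records, genome, window = 20,
                        subs = c("ct_cg", "all")) {
  subs <- match.arg(subs)
  validate_genome(genome)
  stopifnot(window >= 1)
  elig <- ams_eligible(records, subs)
  samples <- unique(records$sample)
  rec <- records[elig, , drop = FALSE]
  b <- motif_bases(rec, genome)
  is_tcw <- !is.na(b$b_m1) & !is.na(b$b_p1) &
    b$b_m1 == "T" & b$b_p1 %in% c("A", "T")
  wins <- rep(NA_character_, nrow(rec))
  centers <- rep(NA_integer_, nrow(rec))
  for (chrom in unique(rec$chrom)) {
    i <- which(rec$chrom == chrom)
    s <- genome[[chrom]]
    if (is.null(s)) stop("contig not in genome: ", chrom)
    L <- nchar(s)
    start <- pmax(1L, rec$pos[i] - window)
    wins[i] <- substring(s, start, pmin(L, rec$pos[i] + window))
    centers[i] <- rec$pos[i] - start + 1L
  }
  ctx_tcw <- count_tcw_motifs(wins)
  ctx_c <- count_cg(wins, centers)
  agg <- function(x) as.numeric(tapply(x, factor(rec$sample,
                                                 levels = samples), sum))
  out <- data.frame(sample = samples,
                    n_mut_tcw = agg(as.integer(is_tcw)),
                    n_mut_c = agg(rep(1L, nrow(rec))),
                    n_ctx_tcw = agg(ctx_tcw),
                    n_ctx_c = agg(ctx_c),
                    stringsAsFactors = FALSE)
  for (cc in c("n_mut_tcw", "n_mut_c", "n_ctx_tcw", "n_ctx_c"))
    out[[cc]][is.na(out[[cc]])] <- 0
  out$ams <- ifelse(out$n_mut_c > 0 & out$n_ctx_tcw > 0 & out$n_ctx_c > 0,
                    (out$n_mut_tcw / out$n_mut_c) /
                      (out$n_ctx_tcw / out$n_ctx_c), NA_real_)
  out
}

#' YTCA / RTCA motif counts per sample
#'
#' Counts, among eligible mutated cytosines falling in TCW motifs, the
#' tetranucleotide classes that separate APOBEC3A-like (pyrimidine at -2,
#' YTCA/YTCW) from APOBEC3B-like (purine at -2, RTCA/RTCW) activity.
#' `ytcw >= ytca` and `rtcw >= rtca` always hold (the TCW classes include
#' the 3'-T cases). Ratios are `NA` when the TCW count is zero and `Inf`
#' when only the R-class count is zero.
#'
#' @inheritParams compute_ams
#' @return data.frame per sample with counts `ytca`, `rtca`, `ytcw`,
#'   `rtcw` and ratios `ratio_ytca_rtca`, `ratio_ytcw_rtcw`. Cohort totals
#'   are attached as `attr(, "cohort")`.
#' @export
ytca_rtca_counts <- function(records, genome, subs = c("ct_cg", "all")) {
  subs <- match.arg(subs)
  elig <- ams_eligible(records, subs)
  samples <- unique(records$sample)
  rec <- records[elig, , drop = FALSE]
  b <- motif_bases(rec, genome)
  known <- !is.na(b$b_m2) & !is.na(b$b_m1) & !is.na(b$b_p1) &
    b$b_m2 != "N" & b$b_m1 != "N" & b$b_p1 != "N"
  tcw <- known & b$b_m1 == "T" & b$b_p1 %in% c("A", "T")
  y <- b$b_m2 %in% c("C", "T")
  f <- factor(rec$sample, levels = samples)
  cnt <- function(sel) {
    x <- tapply(as.integer(sel), f, sum)
    ifelse(is.na(x), 0L, as.integer(x))
  }
  out <- data.frame(sample = samples,
                    ytca = cnt(tcw & y & b$b_p1 == "A"),
                    rtca = cnt(tcw & !y & b$b_p1 == "A"),
                    ytcw = cnt(tcw & y),
                    rtcw = cnt(tcw & !y),
                    stringsAsFactors = FALSE)
  ratio <- function(a, bb) ifelse(a + bb == 0, NA_real_,
                                  ifelse(bb == 0, Inf, a / bb))
  out$ratio_ytca_rtca <- ratio(out$ytca, out$rtca)
  out$ratio_ytcw_rtcw <- ratio(out$ytcw, out$rtcw)
  tot <- colSums(out[, c("ytca", "rtca", "ytcw", "rtcw")])
  cohort <- data.frame(t(tot))
  cohort$ratio_ytca_rtca <- ratio(tot["ytca"], tot["rtca"])
  cohort$ratio_ytcw_rtcw <- ratio(tot["ytcw"], tot["rtcw"])
  attr(out, "cohort") <- cohort
  out
}
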