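# Seeded generators of synthetic cohorts with known truth. Every generator
# runs its whole random stream inside withr::with_seed (no global RNG
# state) and returns a `truth` list recording seed and planted parameters.

#' Write / read a generator truth bundle
#'
#' Truth bundles are plain lists (generator name, seed, planted
#' parameters) serialized as YAML next to the generated data so that
#' recovery tests can close the loop.
#'
#' @param truth Truth list.
#' @param path YAML path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the list.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) yaml::read_yaml(path)

#' Generate a random reference contig
#'
#' I.i.d. bases at the stated GC fraction (split equally between C and G,
#' and between A and T).
#'
#' @param length Contig length (>= 1000).
#' @param gc_fraction GC content in \[0, 1\].
#' @param seed Integer seed.
#' @param contig Contig name (default `"chr1"`).
#' @return List with `genome` (named character vector) and `truth`.
#' @export
gen_reference <- function(length, gc_fraction = 0.4, seed, contig = "chr1") {
  if (length < 1000) stop("length must be >= 1000")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  if (missing(seed)) stop("seed is required")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- withr::with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  list(genome = setNames(seqs, contig),
       truth = list(generator = "gen_reference", seed = seed,
                    length = length, gc_fraction = gc_fraction))
}

#' Build a synthetic signature catalog
#'
#' Produces column-stochastic 96-channel profiles: two APOBEC-analog
#' signatures with their mass on the TCW C>T and C>G channels
#' respectively, plus sparse random (Dirichlet) background signatures.
#' These are synthetic stand-ins with APOBEC-like structure, not the
#' published reference profiles.
#'
#' @param n_signatures Total number of signatures (>= 2).
#' @param seed Integer seed.
#' @param apobec_names Names of the two APOBEC-analog columns.
#' @return 96 x `n_signatures` matrix, columns summing to 1.
#' @export
simulate_signature_catalog <- function(n_signatures, seed,
                                       apobec_names = c("APOBEC.CT",
                                                        "APOBEC.CG")) {
  stopifnot(n_signatures >= 2)
  channels <- sbs96_channels()
  withr::with_seed(seed, {
    m <- matrix(0, 96, n_signatures,
                dimnames = list(channels, c(apobec_names,
                  sprintf("BG%02d", seq_len(n_signatures - 2)))))
    apo <- function(sub) {
      v <- setNames(rep(0.0015, 96), channels)
      v[paste0("T[", sub, "]A")] <- 0.40
      v[paste0("T[", sub, "]T")] <- 0.33
      v[paste0("T[", sub, "]C")] <- 0.07
      v[paste0("T[", sub, "]G")] <- 0.06
      v / sum(v)
    }
    m[, 1] <- apo("C>T")
    m[, 2] <- apo("C>G")
    for (k in seq_len(n_signatures - 2) + 2L) {
      g <- rgamma(96, shape = 0.08)
      m[, k] <- g / sum(g)
    }
    m
  })
}

comp_base <- function(x) unname(COMPLEMENT[x])

# Index every interior genome position by its pyrimidine-normalized
# trinucleotide; TCW contexts are additionally split by the normalized
# -2 base (pyrimidine Y vs purine R) to steer YTCA/RTCA placement.
build_context_index <- function(genome) {
  validate_genome(genome)
  idx <- list()
  for (chrom in names(genome)) {
    ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L < 5L) next
    i <- 3:(L - 2L)
    center <- ch[i]
    pyr <- center %in% c("C", "T")
    pur <- center %in% c("A", "G")
    ctx <- rep(NA_character_, length(i))
    prev2 <- rep(NA_character_, length(i))
    ctx[pyr] <- paste0(ch[i - 1L][pyr], center[pyr], ch[i + 1L][pyr])
    prev2[pyr] <- ch[i - 2L][pyr]
    ctx[pur] <- paste0(comp_base(ch[i + 1L][pur]), comp_base(center[pur]),
                       comp_base(ch[i - 1L][pur]))
    prev2[pur] <- comp_base(ch[i + 2L][pur])
    ok <- !is.na(ctx) & !grepl("N", ctx, fixed = TRUE)
    df <- data.frame(chrom = chrom, pos = i[ok], ctx = ctx[ok],
                     plus = pyr[ok],
                     prev_y = prev2[ok] %in% c("C", "T"),
                     stringsAsFactors = FALSE)
    idx[[chrom]] <- df
  }
  all <- do.call(rbind, idx)
  split(all, all$ctx)
}

channel_parts <- function(channel) {
  data.frame(f5 = substr(channel, 1, 1),
             ref = substr(channel, 3, 3),
             alt = substr(channel, 5, 5),
             f3 = substr(channel, 7, 7), stringsAsFactors = FALSE)
}

APOBEC_CHANNELS <- c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")

#' Simulate a cohort of somatic mutations from signature mixtures
#'
#' For each sample, per-signature mutation counts are drawn (Poisson
#' around the supplied expected activities, or taken exactly), each
#' mutation's 96-channel is drawn from its signature profile, and the
#' mutation is placed at a uniformly chosen genome position whose
#' pyrimidine-normalized trinucleotide matches the channel. For the four
#' APOBEC TCW channels the preceding (-2) base is a pyrimidine with
#' probability `ytca_pyrimidine_prob`, which controls the planted
#' YTCA:RTCA balance. Errors if a required context does not occur in the
#' genome.
#'
#' @param genome Named character genome vector.
#' @param activities n_samples x S matrix of expected mutation counts per
#'   signature (rownames = sample ids, colnames = signature names matching
#'   `signatures`).
#' @param signatures 96 x S column-stochastic signature matrix.
#' @param ytca_pyrimidine_prob Probability that an APOBEC-channel placement
#'   has a pyrimidine at the normalized -2 position (default 0.5).
#' @param seed Integer seed.
#' @param poisson Draw Poisson counts around `activities` (default
#'   `TRUE`); otherwise counts are `round(activities)`.
#' @param nonsyn_prob Probability a simulated SNV is labeled
#'   nonsynonymous (default 0.7; the rest synonymous).
#' @return List with `records` (mutation record data.frame) and `truth`
#'   (drawn per-sample signature counts, APOBEC Y/R placement tallies,
#'   parameters).
#' @export
gen_cohort_mutations <- function(genome, activities, signatures,
                                 ytca_pyrimidine_prob = 0.5, seed,
                                 poisson = TRUE, nonsyn_prob = 0.7) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is.matrix(activities), nrow(signatures) == 96L,
            identical(colnames(activities), colnames(signatures)))
  if (ytca_pyrimidine_prob < 0 || ytca_pyrimidine_prob > 1)
    stop("ytca_pyrimidine_prob must be in [0,1]")
  if (is.null(rownames(activities)))
    rownames(activities) <- sprintf("S%03d", seq_len(nrow(activities)))
  idx <- build_context_index(genome)
  channels <- sbs96_channels()
  parts <- channel_parts(channels)
  ctx_of_channel <- paste0(parts$f5, parts$ref, parts$f3)
  withr::with_seed(seed, {
    drawn <- if (poisson) {
      matrix(rpois(length(activities), as.numeric(activities)),
             nrow(activities), dimnames = dimnames(activities))
    } else round(activities)
    n_y <- n_r <- 0L
    recs <- vector("list", nrow(drawn))
    for (s in seq_len(nrow(drawn))) {
      chan_idx <- unlist(lapply(seq_len(ncol(drawn)), function(k) {
        if (drawn[s, k] == 0) integer(0)
        else sample.int(96L, drawn[s, k], replace = TRUE,
                        prob = signatures[, k])
      }))
      if (!length(chan_idx)) { recs[[s]] <- NULL; next }
      rows <- vector("list", 96L)
      for (ci in sort(unique(chan_idx))) {
        nmut <- sum(chan_idx == ci)
        ctx <- ctx_of_channel[ci]
        pool <- idx[[ctx]]
        if (is.null(pool) || !nrow(pool))
          stop("context absent from genome: ", ctx)
        if (channels[ci] %in% APOBEC_CHANNELS) {
          want_y <- rbinom(nmut, 1, ytca_pyrimidine_prob) == 1
          n_y <- n_y + sum(want_y); n_r <- n_r + sum(!want_y)
          py <- which(pool$prev_y); pr <- which(pool$prev_y == FALSE)
          if ((any(want_y) && !length(py)) || (any(!want_y) && !length(pr)))
            stop("no ", ifelse(any(want_y) && !length(py), "Y", "R"),
                 "-preceded ", ctx, " site in genome")
          take <- integer(nmut)
          take[want_y] <- py[sample.int(length(py), sum(want_y),
                                        replace = TRUE)]
          take[!want_y] <- pr[sample.int(length(pr), sum(!want_y),
                                         replace = TRUE)]
        } else {
          take <- sample.int(nrow(pool), nmut, replace = TRUE)
        }
        hit <- pool[take, , drop = FALSE]
        ref <- ifelse(hit$plus, parts$ref[ci], comp_base(parts$ref[ci]))
        alt <- ifelse(hit$plus, parts$alt[ci], comp_base(parts$alt[ci]))
        rows[[ci]] <- data.frame(chrom = hit$chrom, pos = hit$pos,
                                 ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      eff <- ifelse(runif(nrow(df)) < nonsyn_prob, "nonsynonymous",
                    "synonymous")
      recs[[s]] <- mutation_records(rownames(drawn)[s], df$chrom,
                                        df$pos, df$ref, df$alt, "SNV", eff)
    }
    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    rownames(records) <- NULL
    list(records = records,
         truth = list(generator = "gen_cohort_mutations", seed = seed,
                      ytca_pyrimidine_prob = ytca_pyrimidine_prob,
                      poisson = poisson,
                      signature_counts = drawn,
                      apobec_placements = list(n_y = n_y, n_r = n_r)))
  })
}

#' Place mutations uniformly over cytosines (null model)
#'
#' Every mutation lands at a uniformly chosen interior C or G position
#' with a C>T or C>G change (strand-normalized), i.e. no motif preference
#' at all. Under this null the cohort mean AMS is 1 up to sampling noise.
#'
#' @param genome Named character genome vector.
#' @param n_samples Number of samples.
#' @param per_sample Mutations per sample.
#' @param seed Integer seed.
#' @return List with `records` and `truth`.
#' @export
gen_uniform_mutations <- function(genome, n_samples, per_sample, seed) {
  if (missing(seed)) stop("seed is required")
  idx <- do.call(rbind, build_context_index(genome))
  idx <- idx[substr(idx$ctx, 2, 2) == "C", , drop = FALSE]
  if (!nrow(idx)) stop("genome has no usable cytosines")
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_samples), function(s) {
      take <- idx[sample.int(nrow(idx), per_sample, replace = TRUE), ]
      nalt <- sample(c("T", "G"), per_sample, replace = TRUE)
      ref <- ifelse(take$plus, "C", "G")
      alt <- ifelse(take$plus, nalt, comp_base(nalt))
      mutation_records(sprintf("S%03d", s), take$chrom, take$pos,
                           ref, alt, "SNV", "nonsynonymous")
    })
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(records = records,
         truth = list(generator = "gen_uniform_mutations", seed = seed,
                      n_samples = n_samples, per_sample = per_sample))
  })
}

#' Simulate survival data with a planted threshold effect
#'
#' Event times are exponential with baseline hazard multiplied by `hr` for
#' samples whose score exceeds `cutoff`; censoring is an independent
#' exponential tuned so roughly `censor_rate` of baseline samples are
#' censored. Clinical covariates (age, gender, stage, smoking, drinking)
#' are drawn independently of survival.
#'
#' @param n Number of samples.
#' @param score Numeric vector of length `n`, or a function of `n`
#'   drawing the per-sample score (default lognormal, AMS-like).
#' @param cutoff Planted threshold on the score.
#' @param hr Hazard ratio above vs below the threshold (> 0).
#' @param baseline_hazard Baseline exponential hazard per month (default
#'   0.02).
#' @param censor_rate Target censoring fraction in \[0, 1) (default 0.3).
#' @param seed Integer seed.
#' @return List with `survival` (data.frame: sample, time, event, score,
#'   covariates) and `truth`.
#' @export
gen_survival <- function(n, score = function(n) exp(rnorm(n, 0, 0.5)),
                         cutoff, hr, baseline_hazard = 0.02,
                         censor_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  if (hr <= 0) stop("hr must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  withr::with_seed(seed, {
    sc <- if (is.function(score)) score(n) else score
    stopifnot(length(sc) == n)
    if (missing(cutoff)) cutoff <- median(sc)
    rate <- baseline_hazard * ifelse(sc > cutoff, hr, 1)
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, c_rate)
    } else t_cens <- rep(Inf, n)
    df <- data.frame(
      sample = sprintf("P%04d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      score = sc,
      age = round(rnorm(n, 60, 8)),
      gender = sample(c("male", "female"), n, TRUE, c(0.7, 0.3)),
      stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                     c(0.15, 0.35, 0.35, 0.15)),
      smoking = rbinom(n, 1, 0.5),
      drinking = rbinom(n, 1, 0.5),
      stringsAsFactors = FALSE)
    list(survival = df,
         truth = list(generator = "gen_survival", seed = seed, n = n,
                      cutoff = cutoff, hr = hr,
                      baseline_hazard = baseline_hazard,
                      censor_rate = censor_rate))
  })
}

#' Simulate a bulk expression matrix with planted score correlations
#'
#' Gaussian-copula construction: the score's normal ranks form a latent
#' factor; each specified gene mixes that factor to hit its target
#' Spearman correlation (via the bivariate-normal identity
#' `r = 2 sin(pi rho / 6)`), then values are exponentiated onto a
#' TPM-like scale. Noise genes are independent of the score.
#'
#' @param score Named numeric per-sample score (names become matrix
#'   columns).
#' @param corr_spec Named numeric vector: gene symbol -> target Spearman
#'   correlation in (-1, 1).
#' @param n_noise_genes Number of independent noise genes (named
#'   `NOISE001`...).
#' @param seed Integer seed.
#' @param log_mean,log_sd Location/scale of log-expression (defaults 3, 1).
#' @return List with `expr` (genes x samples matrix) and `truth`.
#' @export
gen_bulk_expression <- function(score, corr_spec, n_noise_genes = 0, seed,
                                log_mean = 3, log_sd = 1) {
  if (missing(seed)) stop("seed is required")
  if (any(abs(corr_spec) >= 1)) stop("target correlations must be in (-1,1)")
  n <- length(score)
  if (is.null(names(score))) names(score) <- sprintf("P%04d", seq_len(n))
  withr::with_seed(seed, {
    z0 <- stats::qnorm((rank(score, ties.method = "average") - 0.5) / n)
    gene_rows <- lapply(names(corr_spec), function(g) {
      r <- 2 * sin(pi * corr_spec[[g]] / 6)
      z <- r * z0 + sqrt(1 - r^2) * rnorm(n)
      exp(log_mean + log_sd * z)
    })
    noise_rows <- lapply(seq_len(n_noise_genes), function(i)
      exp(log_mean + log_sd * rnorm(n)))
    expr <- do.call(rbind, c(gene_rows, noise_rows))
    rownames(expr) <- c(names(corr_spec),
                        if (n_noise_genes > 0)
                          sprintf("NOISE%03d", seq_len(n_noise_genes)))
    colnames(expr) <- names(score)
    list(expr = expr,
         truth = list(generator = "gen_bulk_expression", seed = seed,
                      corr_spec = as.list(corr_spec),
                      n_noise_genes = n_noise_genes))
  })
}

#' Simulate a single-cell cohort with group-dependent composition
#'
#' Cell types are drawn multinomially per group from the given
#' compositions; gene counts are negative binomial with optional planted
#' co-expression modules (module genes share a latent per-cell factor, so
#' a designated reference gene co-varies with its module). A stated
#' fraction of cells is made to violate each QC rule by overwriting the
#' corresponding metadata field.
#'
#' @param groups Named list: group -> named cell-type probability vector
#'   (must sum to 1).
#' @param cells_per_group Cells per group (default 1000).
#' @param n_genes Number of genes (default 120, named `G001`...).
#' @param modules List of planted modules, each `list(genes =, strength =)`
#'   where `genes` indexes into the gene names and `strength` scales the
#'   shared latent factor (log scale).
#' @param qc_violation_rates Named numeric fractions for
#'   `genes_low`, `genes_high`, `counts`, `mito` violations (default all
#'   0).
#' @param seed Integer seed.
#' @return List with `counts` (sparse genes x cells dgCMatrix), `meta`
#'   (cell metadata data.frame) and `truth`.
#' @export
gen_sc_cohort <- function(groups, cells_per_group = 1000, n_genes = 120,
                          modules = list(),
                          qc_violation_rates = c(genes_low = 0,
                                                 genes_high = 0,
                                                 counts = 0, mito = 0),
                          seed) {
  if (missing(seed)) stop("seed is required")
  for (g in names(groups))
    if (abs(sum(groups[[g]]) - 1) > 1e-8)
      stop("composition of group ", g, " does not sum to 1")
  rates <- c(genes_low = 0, genes_high = 0, counts = 0, mito = 0)
  rates[names(qc_violation_rates)] <- qc_violation_rates
  withr::with_seed(seed, {
    gene_names <- sprintf("G%03d", seq_len(n_genes))
    base <- rnorm(n_genes, 0.3, 0.7)
    meta_list <- list()
    cnt_list <- list()
    for (g in names(groups)) {
      comp <- groups[[g]]
      types <- sample(names(comp), cells_per_group, TRUE, prob = comp)
      logmu <- matrix(base, n_genes, cells_per_group)
      for (m in modules) {
        gi <- match(m$genes, gene_names)
        if (any(is.na(gi))) stop("module gene not in gene names")
        f <- rnorm(cells_per_group)
        logmu[gi, ] <- logmu[gi, ] + m$strength *
          matrix(f, length(gi), cells_per_group, byrow = TRUE)
      }
      cnt <- matrix(rnbinom(n_genes * cells_per_group, mu = exp(logmu),
                            size = 2), n_genes, cells_per_group)
      ids <- paste0(g, "_c", seq_len(cells_per_group))
      colnames(cnt) <- ids
      rownames(cnt) <- gene_names
      cnt_list[[g]] <- cnt
      # QC fields are drawn at full-transcriptome scale: the simulated
      # matrix is a scaled-down transcriptome, so detected-gene and
      # count totals from it would sit far below real QC thresholds
      meta_list[[g]] <- data.frame(
        cell = ids, sample = g, group = g, cell_type = types,
        n_genes = sample(1000:7000, cells_per_group, replace = TRUE),
        total_counts = sample(2000:18000, cells_per_group,
                              replace = TRUE),
        pct_mito = runif(cells_per_group, 0, 6),
        stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta_list)
    rownames(meta) <- NULL
    counts <- Matrix::Matrix(do.call(cbind, cnt_list), sparse = TRUE)
    n_cells <- nrow(meta)
    violate <- function(rate) {
      k <- round(rate * n_cells)
      if (k == 0) integer(0) else sample.int(n_cells, k)
    }
    v_low <- violate(rates["genes_low"])
    v_high <- violate(rates["genes_high"])
    v_cnt <- violate(rates["counts"])
    v_mito <- violate(rates["mito"])
    meta$n_genes[v_low] <- sample(0:299, length(v_low), replace = TRUE)
    meta$n_genes[v_high] <- sample(8001:12000, length(v_high),
                                   replace = TRUE)
    meta$total_counts[v_cnt] <- sample(20001:50000, length(v_cnt),
                                       replace = TRUE)
    meta$pct_mito[v_mito] <- runif(length(v_mito), 10.001, 40)
    list(counts = counts, meta = meta,
         truth = list(generator = "gen_sc_cohort", seed = seed,
                      composition = lapply(groups, as.list),
                      cells_per_group = cells_per_group,
                      modules = modules,
                      qc_violations = list(
                        genes_low = length(v_low),
                        genes_high = length(v_high),
                        counts = length(v_cnt),
                        mito = length(v_mito))))
  })
}

#' Write mutation records as a minimal MAF
#'
#' @param records Mutation record data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  eff_to_vc <- c(nonsynonymous = "Missense_Mutation",
                 synonymous = "Silent", other = "RNA", unknown = "")
  maf <- data.frame(
    Hugo_Symbol = ifelse(is.na(records$gene), "Unknown", records$gene),
    Chromosome = records$chrom,
    Start_Position = records$pos,
    Reference_Allele = records$ref,
    Tumor_Seq_Allele2 = records$alt,
    Variant_Classification = unname(eff_to_vc[records$effect]),
    Variant_Type = ifelse(records$variant_class == "SNV", "SNP",
                          ifelse(nchar(records$ref) <
                                   nchar(records$alt), "INS", "DEL")),
    Tumor_Sample_Barcode = records$sample,
    stringsAsFactors = FALSE)
  write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Draw per-sample expected activities with a planted group share
#'
#' Per-sample activity law for cohort simulations: each sample's fraction
#' of mutations attributed to a designated signature group (e.g. the two
#' APOBEC analogs) is Beta-distributed with mean `group_share`, the split
#' inside the group and across the background signatures is symmetric
#' Dirichlet, and everything is scaled to `total_mutations` expected
#' mutations per sample. The expected cohort-wide group share equals
#' `group_share`.
#'
#' @param signatures 96 x S signature matrix (only column names are
#'   used).
#' @param n_samples Number of samples.
#' @param total_mutations Expected mutations per sample.
#' @param group_share Planted mean fraction for the signature group.
#' @param group_cols Names or indices of the grouped signature columns.
#' @param beta_concentration Concentration of the per-sample Beta law
#'   (default 30; larger = less sample-to-sample spread).
#' @param seed Integer seed.
#' @return n_samples x S matrix of expected activities.
#' @export
sample_activity_matrix <- function(signatures, n_samples, total_mutations,
                                   group_share, group_cols = 1:2,
                                   beta_concentration = 30, seed) {
  if (missing(seed)) stop("seed is required")
  if (group_share <= 0 || group_share >= 1)
    stop("group_share must be in (0,1)")
  sn <- colnames(signatures)
  grp <- if (is.numeric(group_cols)) sn[group_cols] else group_cols
  bg <- setdiff(sn, grp)
  if (!length(bg)) stop("need at least one background signature")
  withr::with_seed(seed, {
    f <- rbeta(n_samples, group_share * beta_concentration,
               (1 - group_share) * beta_concentration)
    rdir <- function(k) { g <- rgamma(k, 2); g / sum(g) }
    A <- t(vapply(seq_len(n_samples), function(i) {
      w <- numeric(length(sn)); names(w) <- sn
      w[grp] <- f[i] * rdir(length(grp))
      w[bg] <- (1 - f[i]) * rdir(length(bg))
      total_mutations * w
    }, numeric(length(sn))))
    rownames(A) <- sprintf("S%03d", seq_len(n_samples))
    A
  })
}
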