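# Generator determinism, calibration against binomial/copula oracles,
# and truth-bundle round trips.

test_that("generators are byte-identical under a repeated seed", {
  r1 <- gen_reference(2000, 0.5, seed = 1)
  r2 <- gen_reference(2000, 0.5, seed = 1)
  expect_identical(r1$genome, r2$genome)
  expect_false(identical(r1$genome, gen_reference(2000, 0.5, seed = 2)$genome))

  sigs <- simulate_signature_catalog(4, seed = 17)
  act <- matrix(30, 3, 4, dimnames = list(c("a", "b", "c"),
                                          colnames(sigs)))
  m1 <- gen_cohort_mutations(r1$genome, act, sigs, seed = 5)
  m2 <- gen_cohort_mutations(r1$genome, act, sigs, seed = 5)
  expect_identical(m1$records, m2$records)

  s1 <- gen_survival(50, cutoff = 1, hr = 0.5, seed = 3)
  s2 <- gen_survival(50, cutoff = 1, hr = 0.5, seed = 3)
  expect_identical(s1$survival, s2$survival)

  sc1 <- gen_sc_cohort(list(A = c(T = 0.5, B = 0.5)), 100, seed = 4)
  sc2 <- gen_sc_cohort(list(A = c(T = 0.5, B = 0.5)), 100, seed = 4)
  expect_identical(sc1$meta, sc2$meta)
  expect_identical(as.matrix(sc1$counts), as.matrix(sc2$counts))
})

test_that("truth bundles round-trip through YAML", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  r <- gen_reference(1000, 0.5, seed = 1)
  write_truth(r$truth, tf)
  back <- read_truth(tf)
  expect_equal(back$generator, "gen_reference")
  expect_equal(back$seed, 1)
  expect_equal(back$gc_fraction, 0.5)
})

test_that("reference GC content matches its binomial oracle", {
  r <- gen_reference(1e5, 0.5, seed = 6)
  gc <- sum(strsplit(r$genome[[1]], "")[[1]] %in% c("C", "G")) / 1e5
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(gc - 0.5), 3 * se)
  at_only <- gen_reference(1000, 0, seed = 7)
  expect_false(grepl("[CG]", at_only$genome[[1]]))
  expect_error(gen_reference(500, 0.5, seed = 1), "1000")
  expect_error(gen_reference(2000, 1.5, seed = 1), "gc_fraction")
})

test_that("placed mutations land on their drawn channels", {
  ref <- gen_reference(30000, 0.45, seed = 8)
  # delta signature: all mass on one channel
  delta <- matrix(0, 96, 1, dimnames = list(sbs96_channels(), "DELTA"))
  delta["T[C>T]A", 1] <- 1
  act <- matrix(100, 1, 1, dimnames = list("S1", "DELTA"))
  sim <- gen_cohort_mutations(ref$genome, act, delta, seed = 9,
                              poisson = FALSE)
  cat1 <- build_catalog(sim$records, ref$genome)
  expect_gte(cat1[1, "T[C>T]A"], 95)
  expect_equal(sum(cat1), 100)
  # catalog equals the drawn channel tally exactly (placement is faithful)
  expect_equal(sum(sim$truth$signature_counts), 100)
  # a context the genome cannot supply is an error
  tiny <- c(chr1 = paste(rep("A", 1200), collapse = ""))
  expect_error(gen_cohort_mutations(tiny, act, delta, seed = 9),
               "context absent")
})

test_that("preceding-base control hits its binomial target", {
  ref <- gen_reference(50000, 0.45, seed = 10)
  sigs <- simulate_signature_catalog(2, seed = 17)
  act <- matrix(c(5000, 0), 1, 2, dimnames = list("S1", colnames(sigs)))
  sim <- gen_cohort_mutations(ref$genome, act, sigs,
                              ytca_pyrimidine_prob = 0.7, seed = 11,
                              poisson = FALSE)
  tallies <- sim$truth$apobec_placements
  n <- tallies$n_y + tallies$n_r
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(tallies$n_y / n - 0.7), 3 * se)
  # forced pyrimidine: zero RTCA
  sim2 <- gen_cohort_mutations(ref$genome, act, sigs,
                               ytca_pyrimidine_prob = 1, seed = 12,
                               poisson = FALSE)
  yr <- ytca_rtca_counts(sim2$records, ref$genome)
  expect_equal(sum(yr$rtca), 0L)
})

test_that("survival generator respects censoring and hazard structure", {
  s0 <- gen_survival(300, cutoff = 1, hr = 0.5, censor_rate = 0, seed = 13)
  expect_true(all(s0$survival$event == 1))
  s3 <- gen_survival(2000, cutoff = Inf, hr = 1, censor_rate = 0.3,
                     seed = 14)
  expect_lt(abs(mean(s3$survival$event == 0) - 0.3), 0.04)
  expect_error(gen_survival(10, cutoff = 1, hr = -1, seed = 1), "hr")
  expect_error(gen_survival(10, cutoff = 1, hr = 1, censor_rate = 1,
                            seed = 1), "censor_rate")
})

test_that("hr = 1 cohorts yield uniform log-rank p-values", {
  pvals <- vapply(1:150, function(i) {
    sim <- gen_survival(60, cutoff = 1, hr = 1, censor_rate = 0.2,
                        seed = 5000 + i)
    labels <- setNames(ifelse(sim$survival$score > 1, "high", "low"),
                       sim$survival$sample)
    logrank_test(sim$survival, labels)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("copula expression hits target rank correlations", {
  score <- withr::with_seed(20, setNames(exp(rnorm(200)),
                                         sprintf("P%03d", 1:200)))
  sim <- gen_bulk_expression(score, c(HIT = 0.9), n_noise_genes = 50,
                             seed = 20)
  rho_hit <- cor(sim$expr["HIT", ], score, method = "spearman")
  expect_lt(abs(rho_hit - 0.9), 0.1)
  noise_rho <- apply(sim$expr[-1, ], 1, cor, y = score,
                     method = "spearman")
  expect_lt(max(abs(noise_rho)), 0.3)
  expect_error(gen_bulk_expression(score, c(X = 1), seed = 1), "(-1,1)")
})

test_that("balanced compositions give near-unit Ro/e ratios", {
  sc <- gen_sc_cohort(list(A = c(T = 0.4, B = 0.3, M = 0.3),
                           B = c(T = 0.4, B = 0.3, M = 0.3)),
                      cells_per_group = 2000, seed = 41)
  roe <- roe_enrichment(sc$meta)
  expect_true(all(roe$ratio > 0.8 & roe$ratio < 1.25))
  expect_error(gen_sc_cohort(list(A = c(T = 0.5, B = 0.4)), 10, seed = 1),
               "sum to 1")
  # zero violation rates leave QC untouched
  out <- qc_filter(sc$meta)
  expect_equal(nrow(out), nrow(sc$meta))
})
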