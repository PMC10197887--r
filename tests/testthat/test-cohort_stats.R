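# Survival dichotomization, log-rank / Cox inference, quantile groups,
# and mutation-pathway enrichment.

test_that("log-rank matches the hand risk-table computation", {
  # 6-subject worked fixture
  time <- c(2, 4, 5, 1, 3, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- c("A", "A", "A", "B", "B", "B")
  surv <- data.frame(sample = paste0("s", 1:6), time = time, event = event)
  labels <- setNames(grp, surv$sample)
  lr <- logrank_test(surv, labels)
  expect_equal(lr$statistic, oracle_logrank_stat(time, event, grp),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))

  # label permutation of identical survival: statistic 0, p 1
  surv2 <- data.frame(sample = paste0("s", 1:6),
                      time = rep(c(1, 2, 3), 2), event = rep(1, 6))
  lab2 <- setNames(rep(c("A", "B"), 3)[c(1, 3, 5, 2, 4, 6)], surv2$sample)
  lr2 <- logrank_test(surv2, lab2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1, tolerance = 1e-12)

  expect_error(logrank_test(surv, setNames(rep("A", 6), surv$sample)),
               "two")
})

test_that("a planted strong effect is detected at n = 200", {
  sim <- gen_survival(200, cutoff = 1, hr = 0.25, seed = 5)
  labels <- setNames(ifelse(sim$survival$score > 1, "high", "low"),
                     sim$survival$sample)
  lr <- logrank_test(sim$survival, labels)
  expect_lt(lr$p, 0.001)
})

test_that("optimal cutoff scans midpoints and respects minprop", {
  sim <- gen_survival(200, cutoff = 1.1, hr = 0.3, seed = 5)
  score <- setNames(sim$survival$score, sim$survival$sample)
  res <- optimal_cutoff(score, sim$survival, minprop = 0.1)
  # candidates are midpoints of distinct sorted scores
  s <- sort(unique(score))
  mids <- (s[-1] + s[-length(s)]) / 2
  expect_true(all(res$scanned$candidate %in% mids))
  # both groups satisfy minprop
  expect_gte(sum(res$labels == "high"), 20)
  expect_gte(sum(res$labels == "low"), 20)
  # the returned cutoff attains the scanned minimum
  expect_equal(res$p_logrank, min(res$scanned$p))
  # recovered cutoff within the inter-decile neighborhood of the truth
  ecdf_score <- ecdf(score)
  expect_lt(abs(ecdf_score(res$cutoff) - ecdf_score(sim$truth$cutoff)), 0.1)

  expect_error(optimal_cutoff(setNames(rep(1, 200), names(score)),
                              sim$survival), "feasible|constant")
  two <- sim$survival[1:2, ]
  expect_error(optimal_cutoff(score[1:2], two), "feasible")
})

test_that("min-p scanning is anti-conservative; permutation fixes it", {
  # null: no survival effect at all
  n_rep <- 120
  pmin_null <- vapply(seq_len(n_rep), function(i) {
    sim <- gen_survival(60, cutoff = Inf, hr = 1, censor_rate = 0.2,
                        seed = 1000 + i)
    sc <- setNames(sim$survival$score, sim$survival$sample)
    optimal_cutoff(sc, sim$survival, minprop = 0.15)$p_logrank
  }, numeric(1))
  expect_gt(mean(pmin_null < 0.05), 0.05)  # anti-conservative by design
  # permutation-adjusted p is honest on a planted-null cohort
  sim <- gen_survival(80, cutoff = Inf, hr = 1, seed = 44)
  sc <- setNames(sim$survival$score, sim$survival$sample)
  res <- optimal_cutoff(sc, sim$survival, minprop = 0.15, n_perm = 99,
                        perm_seed = 9)
  expect_gt(res$p_adjusted, res$p_logrank)
})

test_that("Cox recovers a planted hazard ratio with covariates", {
  sim <- gen_survival(1000, cutoff = 1, hr = 0.5, seed = 9)
  labels <- setNames(ifelse(sim$survival$score > 1, "high", "low"),
                     sim$survival$sample)
  cox <- cox_ph(sim$survival, labels,
                covariates = c("age", "gender", "stage", "smoking",
                               "drinking"))
  hr <- cox$hr[cox$term == "grouphigh"]
  expect_true(hr > 0.4 && hr < 0.6)
  expect_true(all(cox$ci_low <= cox$hr & cox$hr <= cox$ci_high))

  # no events
  s0 <- sim$survival; s0$event <- 0
  expect_error(cox_ph(s0, labels), "events")
  # duplicated covariate column -> rank deficiency
  s2 <- sim$survival; s2$age2 <- s2$age
  expect_error(cox_ph(s2, labels, covariates = c("age", "age2")),
               "rank|NA coefficients")
})

test_that("Cox log-HR bias is small across replicate cohorts", {
  bias <- vapply(1:25, function(i) {
    sim <- gen_survival(400, cutoff = 1, hr = 0.5, seed = 200 + i)
    labels <- setNames(ifelse(sim$survival$score > 1, "high", "low"),
                       sim$survival$sample)
    log(cox_ph(sim$survival, labels)$hr[1]) - log(0.5)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.05)
})

test_that("quantile groups follow interpolated quantiles with tie policy", {
  sc <- setNames(as.numeric(1:8), paste0("s", 1:8))
  g <- quantile_groups(sc, q = 0.25)
  expect_equal(names(g)[g == "lower"], c("s1", "s2"))
  expect_equal(names(g)[g == "upper"], c("s7", "s8"))
  expect_equal(sum(g == "middle"), 4L)
  # boundary ties join the extreme groups
  sc2 <- setNames(c(1, 1, 2, 3, 4, 4), paste0("t", 1:6))
  g2 <- quantile_groups(sc2, q = 0.25)
  expect_true(all(g2[c("t1", "t2")] == "lower"))
  expect_true(all(g2[c("t5", "t6")] == "upper"))
  expect_error(quantile_groups(setNames(rep(2, 8), paste0("s", 1:8))),
               "degenerate")
  expect_error(quantile_groups(sc, q = 0.5), "q must")
  expect_error(quantile_groups(sc[1:3]), "4 samples")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  # all 2x2 tables with both row margins <= 8 (acceptance re-runs <= 12)
  for (r1 in 1:8) for (r2 in 1:8) for (a in 0:r1) for (cc in 0:r2) {
    p_pkg <- fisher.test(matrix(c(a, r1 - a, cc, r2 - cc), 2,
                                byrow = TRUE))$p.value
    expect_equal(p_pkg, oracle_fisher_p(a, r1 - a, cc, r2 - cc),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment equals textbook step-up and is permutation-safe", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- withr::with_seed(8, runif(40))
  expect_equal(bh_adjust(p), oracle_bh(p))
  perm <- withr::with_seed(9, sample(40))
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pathway enrichment applies both stages and the thresholds", {
  genes_in <- sprintf("IN%02d", 1:10)
  genes_out <- sprintf("OUT%02d", 1:90)
  sets <- list(pw = genes_in)
  universe <- c(genes_in, genes_out)
  # group1: 30 pathway + 70 background; group2: 10 + 90
  rec <- rbind(
    mutation_records("g1", "c", 1, "C", "T", "SNV", "unknown",
                     gene = c(rep(genes_in, 3), rep(genes_out[1:70], 1))),
    mutation_records("g2", "c", 1, "C", "T", "SNV", "unknown",
                     gene = c(genes_in[1:10], genes_out[1:90])))
  labels <- c(g1 = "HAMS", g2 = "LAMS")
  res <- pathway_mutation_enrichment(rec, sets, labels,
                                     universe = universe)
  s2 <- res$stage2
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$a, s2$b, s2$c, s2$d), c(30L, 70L, 10L, 90L))
  expect_equal(s2$odds_ratio, (30 * 90) / (70 * 10))
  expect_equal(s2$p_fisher, oracle_fisher_p(30, 70, 10, 90),
               tolerance = 1e-9)

  # equal pathway proportions: OR 1, p maximal
  rec_eq <- rbind(
    mutation_records("g1", "c", 1, "C", "T", "SNV", "unknown",
                     gene = c(rep(genes_in, 2), genes_out[1:80])),
    mutation_records("g2", "c", 1, "C", "T", "SNV", "unknown",
                     gene = c(rep(genes_in, 2), genes_out[1:80])))
  res_eq <- pathway_mutation_enrichment(rec_eq, sets, labels,
                                        universe = universe)
  if (nrow(res_eq$stage2)) {
    expect_equal(res_eq$stage2$odds_ratio, 1)
    expect_equal(res_eq$stage2$p_fisher, 1)
  }

  # stage-1 gate: p or FDR beyond threshold blocks stage 2
  res_gate <- pathway_mutation_enrichment(rec, sets, labels,
                                          universe = universe,
                                          stage1_fdr = 1e-30)
  expect_equal(nrow(res_gate$stage2), 0L)
  expect_false(any(res_gate$stage1$significant))
})
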