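# Reference-catalog reading and NNLS activity refitting.

test_that("signature catalog reading validates and reorders", {
  sigs <- read_signature_catalog(extdata("signatures_8_synthetic.tsv"))
  expect_equal(dim(sigs), c(96L, 8L))
  expect_equal(rownames(sigs), sbs96_channels())
  expect_true(all(abs(colSums(sigs) - 1) < 1e-9))

  # shuffled row order reloads to the identical catalog
  df <- read.delim(extdata("signatures_8_synthetic.tsv"),
                   check.names = FALSE)
  shuffled <- withr::with_seed(1, df[sample(nrow(df)), ])
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(shuffled, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_signature_catalog(tf), sigs)

  # column summing to 0.5 is rejected
  bad <- df
  bad[[2]] <- bad[[2]] / 2
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(tf), "sum to 1")

  # wrong row count / unknown labels are rejected
  write.table(df[-1, ], tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(tf), "96")
  df2 <- df; df2$Type[1] <- "X[C>A]A"
  write.table(df2, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(tf), "labels")
})

test_that("refit recovers pure and mixed profiles exactly", {
  sigs <- read_signature_catalog(extdata("signatures_8_synthetic.tsv"))
  # pure profile scaled to 200 mutations
  pure <- matrix(200 * sigs[, "APOBEC.CT"], 1, 96,
                 dimnames = list("P", sbs96_channels()))
  fit <- refit_activities(pure, sigs, prune_frac = 0)
  expect_equal(unname(fit$activities["P", "APOBEC.CT"]), 200,
               tolerance = 1e-6)
  expect_lt(sum(fit$activities["P", colnames(sigs) != "APOBEC.CT"]), 1e-6)

  # noiseless 60/40 two-signature mixture
  mix <- matrix(60 * sigs[, "BG01"] + 40 * sigs[, "BG02"], 1, 96,
                dimnames = list("M", sbs96_channels()))
  fit2 <- refit_activities(mix, sigs[, c("BG01", "BG02")], prune_frac = 0)
  expect_equal(unname(fit2$activities["M", ]), c(60, 40), tolerance = 1e-6)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("Poisson-sampled cohort shares are recovered within 2 points", {
  sigs <- read_signature_catalog(extdata("signatures_8_synthetic.tsv"))
  shares <- c(0.12, 0.10, 0.18, 0.15, 0.13, 0.12, 0.10, 0.10)
  act <- matrix(rep(500 * shares, each = 30), 30,
                dimnames = list(sprintf("S%02d", 1:30), colnames(sigs)))
  counts <- withr::with_seed(3, matrix(
    rpois(length(act) * 0 + 30 * 96, as.numeric(t(sigs %*% t(act)))),
    30, 96, byrow = FALSE, dimnames = list(rownames(act),
                                           sbs96_channels())))
  # counts drawn channel-wise around the expected catalog
  fit <- refit_activities(counts, sigs, prune_frac = 0)
  rec_share <- colSums(fit$activities) / sum(fit$activities)
  expect_true(all(abs(rec_share - shares) < 0.02))
})

test_that("cohort-share pruning reaches a fixed point and is idempotent", {
  sigs <- simulate_signature_catalog(12, seed = 23)
  used <- colnames(sigs)[c(1, 2, 5, 8)]
  # deep (WGS-like) per-sample counts so spurious NNLS absorption stays
  # well under the 1% cohort-share pruning threshold
  act <- matrix(rep(c(600, 600, 500, 500), each = 20), 20,
                dimnames = list(sprintf("S%02d", 1:20), used))
  ref <- gen_reference(40000, 0.45, seed = 24)
  sim <- gen_cohort_mutations(ref$genome, act, sigs[, used], seed = 25)
  cat20 <- build_catalog(sim$records, ref$genome)
  fit <- refit_activities(cat20, sigs, prune_frac = 0.01)
  expect_setequal(colnames(fit$activities), used)
  # refitting on the retained set reproduces identical activities
  fit2 <- refit_activities(cat20, sigs[, colnames(fit$activities)],
                           prune_frac = 0.01)
  expect_equal(fit2$activities, fit$activities)
})

test_that("activities scale linearly with counts and are locally optimal", {
  sigs <- read_signature_catalog(extdata("signatures_8_synthetic.tsv"))
  base <- 30 * sigs[, "BG03"] + 70 * sigs[, "APOBEC.CG"]
  m <- rbind(x1 = base, x3 = 3 * base)
  colnames(m) <- sbs96_channels()
  fit <- refit_activities(m, sigs, prune_frac = 0)
  expect_equal(3 * fit$activities["x1", ], fit$activities["x3", ],
               tolerance = 1e-6)

  # perturbing any retained activity by +/-1% never lowers the residual
  noisy <- withr::with_seed(7, matrix(
    rpois(96, 5 * rowSums(sigs[, 1:4])), 1, 96,
    dimnames = list("N", sbs96_channels())))
  f <- refit_activities(noisy, sigs, prune_frac = 0)
  a <- f$activities["N", ]
  res <- function(av) sqrt(sum((as.numeric(noisy) -
                                  as.numeric(sigs %*% av))^2))
  r0 <- res(a)
  for (k in which(a > 0)) {
    for (d in c(0.99, 1.01)) {
      av <- a; av[k] <- av[k] * d
      expect_gte(res(av) + 1e-10, r0)
    }
  }
})

test_that("etiology fractions partition activity into groups", {
  A <- matrix(c(10, 30, 20, 40), 2, 2,
              dimnames = list(c("a", "b"), c("SBS2", "SBS13")))
  one <- etiology_fractions(A, list(APOBEC = c("SBS2", "SBS13")))
  expect_equal(one$percent, 100)
  two <- etiology_fractions(A, list(X = "SBS2", Y = "SBS13"))
  expect_equal(two$percent[two$group == "X"], 40)
  expect_equal(sum(two$percent), 100)
  # ungrouped signatures fall into Others
  B <- cbind(A, SBS5 = c(25, 25))
  three <- etiology_fractions(B, list(APOBEC = c("SBS2", "SBS13")))
  expect_equal(three$percent[three$group == "Others"], 1 / 3 * 100,
               tolerance = 1e-9)
  expect_error(etiology_fractions(A, list()), "non-empty")
  expect_error(etiology_fractions(A, list(G = "SBS99")), "absent")
})

test_that("all-zero samples refit to zero with a warning", {
  sigs <- read_signature_catalog(extdata("signatures_8_synthetic.tsv"))
  m <- matrix(0L, 1, 96, dimnames = list("Z", sbs96_channels()))
  expect_warning(fit <- refit_activities(m, sigs, prune_frac = 0),
                 "all-zero")
  expect_true(all(fit$activities == 0))
})
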