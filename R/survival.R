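# Survival dichotomization at the minimum log-rank cutpoint, log-rank and
# Cox inference, and quantile grouping of a continuous score.

check_survival <- function(survival) {
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(survival))
  if (length(miss))
    stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  if (any(survival$time < 0)) stop("negative follow-up times")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(survival)
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank chi-square with 1 df, via
#' [survival::survdiff()].
#'
#' @param survival data.frame with `sample`, `time`, `event`.
#' @param labels Named character vector (names = samples) with exactly two
#'   levels.
#' @return List with `statistic` (chi-square) and `p`.
#' @export
logrank_test <- function(survival, labels) {
  check_survival(survival)
  g <- labels[survival$sample]
  if (any(is.na(g))) stop("labels missing for some samples")
  if (length(unique(g)) != 2L) stop("labels must define two non-empty groups")
  if (sum(survival$event) < 1) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(survival$time, survival$event) ~ g)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Survival-optimal cutpoint of a continuous score
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' sorted score values) whose induced high/low split leaves both groups
#' with at least `minprop` of the cohort, and returns the candidate with
#' the minimum two-sided log-rank p-value. Ties within numerical tolerance
#' are broken toward the candidate closest to the median score. Because
#' the minimum over many tests is anti-conservative, a permutation-adjusted
#' p-value is available via `n_perm`.
#'
#' @param score Named numeric vector (names = samples).
#' @param survival data.frame with `sample`, `time`, `event`.
#' @param minprop Minimum fraction of samples per group (default 0.1).
#' @param n_perm If > 0, additionally compute a permutation-adjusted
#'   p-value from this many score permutations (min-p null distribution).
#' @param perm_seed Seed for the permutation stream.
#' @return List of class `"cutoff_result"`: `cutoff`, `labels` (named
#'   "high"/"low"), `p_logrank`, `scanned` (candidate/p table), and
#'   `p_adjusted` when permutations were requested.
#' @export
optimal_cutoff <- function(score, survival, minprop = 0.1,
                           n_perm = 0, perm_seed = 1L) {
  check_survival(survival)
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  score <- score[survival$sample]
  if (any(is.na(score))) stop("score missing for some samples")
  n <- length(score)
  scan_min_p <- function(sc) {
    s <- sort(unique(sc))
    if (length(s) < 2L) return(NULL)
    cand <- (s[-1] + s[-length(s)]) / 2
    n_hi <- vapply(cand, function(ct) sum(sc > ct), integer(1))
    # a valid split needs minprop of the cohort and at least 2 per group
    need <- max(2L, ceiling(minprop * n))
    ok <- n_hi >= need & (n - n_hi) >= need
    cand <- cand[ok]
    if (!length(cand)) return(NULL)
    p <- vapply(cand, function(ct) {
      g <- ifelse(sc > ct, "high", "low")
      sd <- survival::survdiff(
        survival::Surv(survival$time, survival$event) ~ g)
      pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE)
    }, numeric(1))
    list(cand = cand, p = p)
  }
  sc <- scan_min_p(score)
  if (is.null(sc))
    stop("no feasible cutoff: scores constant or minprop unsatisfiable")
  best <- which(sc$p <= min(sc$p) + 1e-12)
  if (length(best) > 1L)
    best <- best[which.min(abs(sc$cand[best] - median(score)))]
  cutoff <- sc$cand[best]
  labels <- setNames(ifelse(score > cutoff, "high", "low"), survival$sample)
  out <- list(cutoff = cutoff, labels = labels, p_logrank = sc$p[best],
              scanned = data.frame(candidate = sc$cand, p = sc$p))
  if (n_perm > 0) {
    obs <- min(sc$p)
    perm_min <- withr::with_seed(perm_seed, vapply(seq_len(n_perm),
      function(i) {
        r <- scan_min_p(sample(score))
        if (is.null(r)) NA_real_ else min(r$p)
      }, numeric(1)))
    perm_min <- perm_min[!is.na(perm_min)]
    out$p_adjusted <- (1 + sum(perm_min <= obs)) / (1 + length(perm_min))
  }
  class(out) <- "cutoff_result"
  out
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Optimal cutoff %.4g (log-rank p = %.3g; %d high / %d low)\n",
              x$cutoff, x$p_logrank, sum(x$labels == "high"),
              sum(x$labels == "low")))
  if (!is.null(x$p_adjusted))
    cat(sprintf("permutation-adjusted p = %.3g\n", x$p_adjusted))
  invisible(x)
}

#' Cox proportional hazards model with covariate adjustment
#'
#' Fits a partial-likelihood Cox model (Efron tie handling) of survival on
#' the group label plus the named covariate columns of `survival`, and
#' reports per-term hazard ratios with Wald 95% confidence intervals.
#' Character/factor covariates are expanded with the first sorted level as
#' reference unless overridden via `ref_levels`. The group term uses
#' `"low"` as reference, so its HR is high-vs-low.
#'
#' @param survival data.frame with `sample`, `time`, `event` and any
#'   covariate columns.
#' @param labels Named "high"/"low" vector, e.g. from [optimal_cutoff()].
#' @param covariates Character vector of covariate column names.
#' @param ref_levels Named list giving the reference level of categorical
#'   covariates.
#' @return data.frame with `term`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
cox_ph <- function(survival, labels, covariates = character(0),
                   ref_levels = list()) {
  check_survival(survival)
  if (sum(survival$event) < 1) stop("no events observed")
  df <- data.frame(time = survival$time, event = survival$event)
  g <- labels[survival$sample]
  if (any(is.na(g))) stop("labels missing for some samples")
  df$group <- stats::relevel(factor(g), ref = "low")
  for (cv in covariates) {
    if (!cv %in% names(survival)) stop("covariate not found: ", cv)
    x <- survival[[cv]]
    if (length(unique(x)) < 2L) stop("covariate is constant: ", cv)
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (!is.null(ref_levels[[cv]]))
        x <- stats::relevel(x, ref = ref_levels[[cv]])
    }
    df[[cv]] <- x
  }
  if (sum(survival$event) < (length(covariates) + 1L))
    stop("fewer events than model terms")
  fit <- survival::coxph(
    survival::Surv(time, event) ~ .,
    data = df, ties = "efron",
    control = survival::coxph.control(iter.max = 50))
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: NA coefficients for ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  if (!is.null(fit$info) && !fit$iter < 50 && fit$iter >= 50)
    stop("Cox model failed to converge after ", fit$iter, " iterations")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = rownames(co),
             hr = unname(co[, "exp(coef)"]),
             ci_low = unname(ci[, 3]),
             ci_high = unname(ci[, 4]),
             p = unname(co[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Upper/lower quantile groups of a score
#'
#' Labels samples `"lower"` when the score is at or below the `q` quantile,
#' `"upper"` when at or above the `1 - q` quantile, `"middle"` otherwise.
#' Quantiles use linear interpolation (type 7); ties at a boundary go to
#' the extreme group. Errors when the two boundaries coincide (e.g. a
#' constant score), since the tails would swallow everything.
#'
#' @param score Named numeric vector.
#' @param q Tail fraction, in (0, 0.5); default 0.25.
#' @return Named character vector over `{"upper", "lower", "middle"}`.
#' @export
quantile_groups <- function(score, q = 0.25) {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (length(score) < 4L) stop("need at least 4 samples")
  lo <- quantile(score, q, type = 7, names = FALSE)
  hi <- quantile(score, 1 - q, type = 7, names = FALSE)
  if (lo >= hi) stop("degenerate quantiles: score ties leave no middle")
  out <- ifelse(score <= lo, "lower", ifelse(score >= hi, "upper", "middle"))
  setNames(out, names(score))
}
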