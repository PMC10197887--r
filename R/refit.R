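# Signature-activity refitting by nonnegative least squares against a
# reference catalog, with cohort-level pruning of minor signatures.

#' Read a COSMIC-style signature catalog
#'
#' Expects a TSV whose first column (`Type`) holds the 96 channel labels
#' (`A[C>A]A`, ...) and each further column one signature profile. Rows are
#' reordered to [sbs96_channels()]; columns whose sum deviates from 1 by at
#' most `1e-3` are renormalized, larger deviations are an error.
#'
#' @param path TSV path.
#' @return 96 x S numeric matrix, rownames = channels, colnames =
#'   signature names; every column sums to 1.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("signature catalog needs >= 1 signature column")
  channels <- sbs96_channels()
  labels <- df[[1]]
  if (nrow(df) != 96L) stop("signature catalog must have 96 context rows, ",
                            "found ", nrow(df))
  if (!setequal(labels, channels) || anyDuplicated(labels))
    stop("unknown or duplicated context labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric signature entries in ", path)
  if (any(m < 0)) stop("negative signature entries in ", path)
  rownames(m) <- labels
  m <- m[channels, , drop = FALSE]
  validate_signature_matrix(m)
}

validate_signature_matrix <- function(m) {
  cs <- colSums(m)
  off <- abs(cs - 1)
  if (any(off > 1e-3))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[off > 1e-3], collapse = ", "))
  sweep(m, 2, cs, "/")
}

nnls_fit <- function(P, y) {
  if (all(y == 0)) return(list(x = rep(0, ncol(P)), resid = 0))
  f <- pracma::lsqnonneg(P, y)
  list(x = as.numeric(f$x), resid = sqrt(max(f$resid.norm, 0)))
}

#' Refit signature activities by nonnegative least squares
#'
#' Each sample's 96-channel counts are decomposed as
#' `counts ~ profiles %*% activities` with `activities >= 0` (least squares
#' on raw counts). Signatures whose cohort-wide share of total activity
#' falls below `prune_frac` are then dropped and the fit repeated, to a
#' fixed point, so that minor spurious attributions do not survive.
#' Deterministic given its inputs.
#'
#' @param catalog Samples x 96 matrix from [build_catalog()] (or any
#'   nonnegative matrix with the canonical channel columns).
#' @param signatures 96 x S signature matrix from
#'   [read_signature_catalog()].
#' @param prune_frac Cohort activity share below which a signature is
#'   pruned (default 0.01); 0 disables pruning.
#' @return List of class `"activity_fit"` with `activities` (samples x
#'   retained signatures, estimated mutation counts), `residual_norm` per
#'   sample, and `pruned` (dropped signature names).
#' @export
refit_activities <- function(catalog, signatures, prune_frac = 0.01) {
  stopifnot(ncol(catalog) == 96L, nrow(signatures) == 96L)
  if (!is.null(colnames(catalog)) &&
      !identical(colnames(catalog), sbs96_channels()))
    stop("catalog columns are not in canonical channel order")
  if (prune_frac < 0 || prune_frac >= 1) stop("prune_frac must be in [0,1)")
  signatures <- validate_signature_matrix(signatures)
  if (any(rowSums(catalog) == 0))
    warning("all-zero sample(s): ",
            paste(rownames(catalog)[rowSums(catalog) == 0], collapse = ", "))
  keep <- colnames(signatures)
  repeat {
    P <- signatures[, keep, drop = FALSE]
    fits <- apply(catalog, 1, function(y) nnls_fit(P, y))
    A <- t(vapply(fits, `[[`, numeric(length(keep)), "x"))
    resid <- vapply(fits, `[[`, numeric(1), "resid")
    colnames(A) <- keep
    rownames(A) <- rownames(catalog)
    share <- colSums(A) / max(sum(A), .Machine$double.eps)
    drop_now <- keep[share < prune_frac]
    if (!length(drop_now) || length(keep) - length(drop_now) < 1L) break
    keep <- setdiff(keep, drop_now)
  }
  structure(list(activities = A, residual_norm = unname(resid),
                 pruned = setdiff(colnames(signatures), keep)),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat("Signature activity fit:", nrow(x$activities), "samples x",
      ncol(x$activities), "signatures\n")
  if (length(x$pruned))
    cat("pruned:", paste(x$pruned, collapse = ", "), "\n")
  cat("cohort shares (%):\n")
  print(round(100 * colSums(x$activities) / sum(x$activities), 2))
  invisible(x)
}

#' Etiology-group fractions of total activity
#'
#' Sums refitted activities over the cohort and reports the percent of the
#' total attributed to each named signature group (e.g. `APOBEC = c("SBS2",
#' "SBS13")`, `Age = c("SBS1", "SBS5")`). Retained signatures not covered
#' by any group are reported as `"Others"`.
#'
#' @param fit `"activity_fit"` from [refit_activities()], or a bare
#'   activity matrix.
#' @param groups Named list mapping group label to signature names; every
#'   listed signature must be present in the fit.
#' @return data.frame with `group` and `percent` (sums to 100).
#' @export
etiology_fractions <- function(fit, groups) {
  A <- if (inherits(fit, "activity_fit")) fit$activities else fit
  if (!length(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a non-empty named list")
  miss <- setdiff(unlist(groups), colnames(A))
  if (length(miss))
    stop("grouped signature(s) absent from activities: ",
         paste(miss, collapse = ", "))
  tot <- colSums(A)
  denom <- sum(tot)
  if (denom <= 0) stop("total activity is zero")
  pct <- vapply(groups, function(g) 100 * sum(tot[g]) / denom, numeric(1))
  rest <- setdiff(colnames(A), unlist(groups))
  out <- data.frame(group = names(groups), percent = unname(pct),
                    stringsAsFactors = FALSE)
  if (length(rest))
    out <- rbind(out, data.frame(group = "Others",
                                 percent = 100 * sum(tot[rest]) / denom))
  out
}

#' Write signature activities as TSV
#'
#' @param fit `"activity_fit"` object.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_activities <- function(fit, path) {
  df <- data.frame(sample = rownames(fit$activities), fit$activities,
                   residual_norm = fit$residual_norm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
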