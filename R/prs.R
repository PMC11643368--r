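#' Fit a polygenic risk score model
#'
#' Multivariate ordinary least squares of the binary case/control label on
#' the dosage matrix (the risk score is then the weighted count of alternate
#' alleles plus an intercept). A rank-deficient design falls back to a
#' lightly regularised ridge solve (lambda = 1e-6) with a message. A
#' logistic fit is available behind `method = "logistic"` for comparison.
#'
#' @param dosages numeric matrix, individuals x SNPs, columns named by
#'   snp_id; dosages in 0..2.
#' @param labels 0/1 case status.
#' @param method `"linear"` (default) or `"logistic"`.
#' @param seed recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return an object of class `prs_model`: snp_ids, weights, intercept,
#'   training allele frequencies (for mean-dosage imputation), metadata.
#' @export
prs_fit <- function(dosages, labels, method = c("linear", "logistic"),
                    seed = NA_integer_) {
  method <- match.arg(method)
  X <- as.matrix(dosages)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- sprintf("snp_%d", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X))
    warning("fewer individuals (", nrow(X), ") than SNPs + 1 (", ncol(X) + 1,
            "); coefficients will be unstable")
  if (method == "logistic") {
    fit <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
    coefs <- fit$coefficients
  } else {
    fit <- stats::lm.fit(cbind(1, X), y)
    coefs <- fit$coefficients
    if (anyNA(coefs)) {
      message("rank-deficient design; using ridge fallback (lambda = 1e-6)")
      Xc <- cbind(1, X)
      A <- crossprod(Xc)
      diag(A) <- diag(A) + 1e-6
      coefs <- drop(solve(A, crossprod(Xc, y)))
    }
  }
  structure(list(snp_ids = colnames(X),
                 weights = setNames(coefs[-1], colnames(X)),
                 intercept = unname(coefs[1]),
                 af = colMeans(X) / 2,
                 meta = list(method = method, n = nrow(X), seed = seed)),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat("PRS model:", length(x$snp_ids), "SNPs,", x$meta$method,
      "fit on", x$meta$n, "individuals\n")
  invisible(x)
}

#' Score genotypes with a fitted PRS model
#'
#' `PRS_i = intercept + sum_j w_j dosage_ij` over the model's SNPs. SNPs
#' missing from the input are imputed at their mean training dosage
#' (2 x allele frequency) and flagged in the `imputed_snps` attribute;
#' individual missing entries (NA) are imputed the same way.
#'
#' @param model a [prs_fit()] model.
#' @param dosages individuals x SNPs matrix with column names.
#' @return numeric PRS per individual (named by rownames when present).
#' @export
prs_score <- function(model, dosages) {
  X <- as.matrix(dosages)
  missing_snps <- setdiff(model$snp_ids, colnames(X))
  if (length(missing_snps)) {
    add <- matrix(rep(2 * model$af[missing_snps], each = nrow(X)),
                  nrow = nrow(X),
                  dimnames = list(rownames(X), missing_snps))
    X <- cbind(X, add)
  }
  X <- X[, model$snp_ids, drop = FALSE]
  for (j in which(colSums(is.na(X)) > 0L))
    X[is.na(X[, j]), j] <- 2 * model$af[model$snp_ids[j]]
  out <- drop(model$intercept + X %*% model$weights)
  attr(out, "imputed_snps") <- missing_snps
  out
}

#' Case enrichment in control-defined PRS quantiles
#'
#' Partitions the control PRS distribution into `n_bins` quantile bins and
#' reports the percentage of cases scoring strictly above the top-bin edge
#' and strictly below the bottom-bin edge (ties fall to the lower bin).
#' Under exchangeability both percentages are near `100 / n_bins`.
#'
#' @param scores_cases,scores_controls numeric PRS vectors.
#' @param n_bins number of control quantile bins (default 5).
#' @return one-row data.frame: top_pct, bottom_pct, n_cases, n_controls,
#'   degenerate (TRUE when control quantile edges collide).
#' @export
quantile_enrichment <- function(scores_cases, scores_controls, n_bins = 5L) {
  stopifnot(length(scores_cases) > 0L, length(scores_controls) > 0L,
            n_bins >= 2L)
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- stats::quantile(scores_controls, probs = probs, names = FALSE)
  data.frame(top_pct = 100 * mean(scores_cases > edges[n_bins - 1L]),
             bottom_pct = 100 * mean(scores_cases < edges[1L]),
             n_cases = length(scores_cases),
             n_controls = length(scores_controls),
             degenerate = anyDuplicated(edges) > 0L)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Cross-validated PRS quantile enrichment
#'
#' Stratified k-fold cross-validation: the model is fitted on k-1 folds and
#' the held-out fold's cases and controls are scored; case enrichment in the
#' held-out control quantiles is reported per fold with mean and s.d.
#'
#' @param dosages,labels as in [prs_fit()].
#' @param k number of folds (default 10; `k = n` gives leave-one-out, where
#'   folds lacking one class yield NA rows, flagged).
#' @param n_bins forwarded to [quantile_enrichment()].
#' @param method forwarded to [prs_fit()].
#' @param seed controls the fold assignment.
#' @return list: `folds` (per-fold data.frame), `mean_top`, `sd_top`,
#'   `mean_bottom`, `sd_bottom`.
#' @export
prs_cv <- function(dosages, labels, k = 10L, n_bins = 5L,
                   method = "linear", seed = 1L) {
  X <- as.matrix(dosages)
  y <- as.numeric(labels)
  fold <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2L)
      return(data.frame(fold = f, top_pct = NA_real_, bottom_pct = NA_real_,
                        n_cases = sum(y[te] == 1), n_controls = sum(y[te] == 0),
                        degenerate = NA))
    model <- prs_fit(X[tr, , drop = FALSE], y[tr], method = method, seed = seed)
    sc <- prs_score(model, X[te, , drop = FALSE])
    yt <- y[te]
    if (!any(yt == 1) || !any(yt == 0))
      return(data.frame(fold = f, top_pct = NA_real_, bottom_pct = NA_real_,
                        n_cases = sum(yt == 1), n_controls = sum(yt == 0),
                        degenerate = NA))
    qe <- quantile_enrichment(sc[yt == 1], sc[yt == 0], n_bins = n_bins)
    cbind(fold = f, qe)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_top = mean(folds$top_pct, na.rm = TRUE),
       sd_top = sd(folds$top_pct, na.rm = TRUE),
       mean_bottom = mean(folds$bottom_pct, na.rm = TRUE),
       sd_bottom = sd(folds$bottom_pct, na.rm = TRUE))
}

#' Cross-cohort PRS evaluation with bootstrap subsampling
#'
#' Scores a second cohort with a model trained on the first, repeatedly
#' subsampling a fraction of its individuals, and reports the mean and s.d.
#' of the top/bottom quantile case percentages across subsamples.
#'
#' @param model a [prs_fit()] model (trained on cohort A).
#' @param dosages,labels cohort B genotypes and case status.
#' @param n_boot number of subsamples (default 10).
#' @param frac fraction of cohort B per subsample (default 0.9).
#' @param n_bins forwarded to [quantile_enrichment()].
#' @param seed subsampling seed.
#' @return list: `boots` (per-replicate data.frame), `mean_top`, `sd_top`,
#'   `mean_bottom`, `sd_bottom`.
#' @export
prs_transfer <- function(model, dosages, labels, n_boot = 10L, frac = 0.9,
                         n_bins = 5L, seed = 1L) {
  X <- as.matrix(dosages)
  y <- as.numeric(labels)
  if (nrow(X) == 0L) stop("cohort B is empty")
  stopifnot(frac > 0, frac <= 1, n_boot >= 1L)
  set.seed(seed)
  rows <- lapply(seq_len(n_boot), function(bidx) {
    ix <- if (frac < 1) sample.int(nrow(X), round(frac * nrow(X))) else
      seq_len(nrow(X))
    sc <- prs_score(model, X[ix, , drop = FALSE])
    yt <- y[ix]
    if (!any(yt == 1) || !any(yt == 0))
      return(data.frame(boot = bidx, top_pct = NA_real_,
                        bottom_pct = NA_real_, n_cases = sum(yt == 1),
                        n_controls = sum(yt == 0), degenerate = NA))
    cbind(boot = bidx,
          quantile_enrichment(sc[yt == 1], sc[yt == 0], n_bins = n_bins))
  })
  boots <- do.call(rbind, rows)
  list(boots = boots,
       mean_top = mean(boots$top_pct, na.rm = TRUE),
       sd_top = sd(boots$top_pct, na.rm = TRUE),
       mean_bottom = mean(boots$bottom_pct, na.rm = TRUE),
       sd_bottom = sd(boots$bottom_pct, na.rm = TRUE))
}
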