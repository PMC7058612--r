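#' Estimate mtDNA copy number from mean sequencing depths
#'
#' Per autosome c, `mtCN_c = mt_depth / autosomal_depth_c * 2`; the
#' returned value is the mean over autosomes (two nuclear copies per
#' cell versus the per-cell mtDNA pool). Chromosomes with zero depth
#' are excluded with a warning; the estimate is invariant to rescaling
#' all depths by a common factor.
#'
#' @param mtDepth mean mitochondrial depth (scalar or per-sample
#'   vector).
#' @param autosomalDepths numeric vector (one sample) or matrix
#'   (samples x chromosomes) of mean autosomal depths.
#' @return numeric copy number per sample.
#' @examples
#' estimateMtcn(1500, c(30, 25))   # mean(100, 120) = 110
#' @export
estimateMtcn <- function(mtDepth, autosomalDepths) {
  auto <- if (is.matrix(autosomalDepths)) autosomalDepths
          else matrix(autosomalDepths, nrow = 1)
  if (any(auto < 0) || any(mtDepth < 0)) stop("depths must be >= 0")
  auto[auto == 0] <- NA_real_
  if (anyNA(auto)) {
    if (all(is.na(auto))) stop("all autosomal depths are zero")
    warning("chromosomes with zero depth excluded")
  }
  rowMeans(mtDepth / auto * 2, na.rm = TRUE)
}

#' Estimate mtDNA copy number from a depth summary table
#'
#' @param depths data.frame from [readDepthTable()] /
#'   [simulateDepthsAndPhenotypes()]: `sample_id`, `mt_depth`, `chr*`.
#' @return data.frame: `sample_id`, `mtcn`.
#' @export
estimateMtcnTable <- function(depths) {
  chrcols <- grep("^chr", names(depths), value = TRUE)
  if (!length(chrcols)) stop("no autosomal depth columns (chr*)")
  data.frame(sample_id = depths$sample_id,
             mtcn = estimateMtcn(depths$mt_depth,
                                 as.matrix(depths[chrcols])))
}

#' Bonferroni-style significance threshold
#'
#' `base_alpha / product(divisors)`, the multiple-comparison threshold
#' used in the genome-wide and phenome-wide scans (e.g.
#' 5.0e-8 / 86 mtDNA variants, or 0.05 / 206 variants / 99 phenotypes).
#'
#' @param baseAlpha base significance level.
#' @param divisors vector of test counts (all >= 1).
#' @return the corrected threshold.
#' @examples
#' bonferroniThreshold(5.0e-8, 86)        # 5.8e-10
#' bonferroniThreshold(0.05, c(206, 99))  # 2.5e-6
#' @export
bonferroniThreshold <- function(baseAlpha, divisors) {
  if (baseAlpha <= 0) stop("baseAlpha must be positive")
  if (any(divisors < 1)) stop("divisors must be >= 1")
  baseAlpha / prod(divisors)
}

#' Flag variants within a window of annotated genes
#'
#' A variant is flagged iff its position falls within
#' `[start - window, end + window]` (inclusive) of any listed gene,
#' e.g. +/- 10 kbp around nuclear-encoded mitochondrial genes.
#'
#' @param positions variant coordinates.
#' @param genes data.frame with columns `start`, `end` (1-based
#'   inclusive); an empty table flags nothing.
#' @param window flank in bp (default 10,000).
#' @return logical vector.
#' @export
geneWindowSubset <- function(positions, genes, window = 10000) {
  flag <- rep(FALSE, length(positions))
  for (k in seq_len(nrow(genes)))
    flag <- flag | (positions >= genes$start[k] - window &
                    positions <= genes$end[k] + window)
  flag
}

#' QQ quantiles and genomic-inflation lambda
#'
#' Lambda is the median observed chi-square(1) statistic over its null
#' median (0.4549): 1 under the null, above 1 under inflation.
#'
#' @param p vector of p-values in (0, 1] (at least 10).
#' @return list with `lambda` and `qq` (sorted observed vs expected
#'   -log10 p).
#' @export
qqLambda <- function(p) {
  if (length(p) < 10) stop("at least 10 p-values required")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(1 - p, df = 1)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(sort(p)))
  list(lambda = lambda, qq = qq)
}

## Logistic fit with Wald statistics for the second column of X
## (the genotype/dosage); separation and non-convergence are flagged.
.fastLogistic <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y,
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(is.na(fit$coefficients)))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                flag = TRUE))
  mu <- fit$fitted.values
  sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  ## covariance from the weighted QR of the final IRLS step
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                flag = TRUE))
  beta <- fit$coefficients[2]
  se <- sqrt(cov[2, 2])
  if (sep || se > 100)
    return(list(beta = beta, se = se, p = NA_real_, flag = TRUE))
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)),
       flag = FALSE)
}

.covariateMatrix <- function(covariates, n) {
  if (is.null(covariates) || !NCOL(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  keep <- vapply(cv, function(x)
    length(unique(x[!is.na(x)])) > 1, logical(1))
  cv <- cv[keep]
  if (!ncol(cv)) return(NULL)
  mf <- stats::model.frame(~ ., data = cv,
                           na.action = stats::na.pass)
  stats::model.matrix(~ ., mf)[, -1, drop = FALSE]
}

#' Genome-wide mtDNA-nDNA genotype association scan
#'
#' For each (common mtDNA variant, nuclear variant) pair, a logistic
#' regression with the haploid mtDNA allele (0/1) as the response and
#' the nuclear dosage plus covariates as predictors; Wald p-values are
#' reported. Non-convergent or separated fits are flagged with the
#' p-value omitted rather than dropped silently.
#'
#' @param mt a [HaploidGenotypeMatrix-class]; variants are filtered to
#'   MAF >= `mtMafMin`.
#' @param ndna numeric matrix of nuclear dosages (samples x variants),
#'   sample-aligned with `mt`.
#' @param covariates optional data.frame of covariates (e.g. top PCs
#'   and run batches).
#' @param mtMafMin mtDNA common-variant threshold (default 0.05).
#' @return data.frame: `mt_variant`, `ndna_variant`, `beta`, `se`,
#'   `p`, `flag`.
#' @export
mtNdnaScan <- function(mt, ndna, covariates = NULL, mtMafMin = 0.05) {
  calls <- genotypeCalls(mt)
  if (nrow(calls) != nrow(ndna))
    stop("mt and ndna must cover the same samples")
  keep <- .commonIdx(altFreqs(mt), mtMafMin)
  if (!length(keep)) stop("no common mtDNA variants")
  ids <- variantInfo(mt)$id[keep]
  C <- .covariateMatrix(covariates, nrow(ndna))
  nv <- colnames(ndna) %||% as.character(seq_len(ncol(ndna)))
  out <- vector("list", length(keep) * ncol(ndna)); k <- 0L
  for (a in seq_along(keep)) {
    y <- calls[, keep[a]]
    ok <- !is.na(y)
    for (b in seq_len(ncol(ndna))) {
      X <- cbind(1, ndna[ok, b], C[ok, , drop = FALSE])
      f <- .fastLogistic(X, y[ok])
      k <- k + 1L
      out[[k]] <- data.frame(mt_variant = ids[a], ndna_variant = nv[b],
                             beta = f$beta, se = f$se, p = f$p,
                             flag = f$flag)
    }
  }
  do.call(rbind, out)
}

#' Genome-wide mtCN-nDNA association scan
#'
#' Linear regression of the per-sample mtDNA copy number on each
#' nuclear dosage with covariates; exact OLS t-test p-values via
#' covariate residualization (numerically identical to `lm()` on the
#' full model).
#'
#' @param mtcn numeric per-sample copy numbers.
#' @param ndna numeric dosage matrix (samples x variants).
#' @param covariates optional covariate data.frame.
#' @return data.frame: `ndna_variant`, `beta`, `se`, `p`, `flag`.
#' @export
mtcnNdnaScan <- function(mtcn, ndna, covariates = NULL) {
  if (length(mtcn) != nrow(ndna))
    stop("mtcn and ndna must cover the same samples")
  if (stats::sd(mtcn, na.rm = TRUE) == 0)
    stop("mtCN is constant; association undefined")
  ok <- !is.na(mtcn)
  y <- mtcn[ok]
  G <- ndna[ok, , drop = FALSE]
  C <- .covariateMatrix(covariates, length(mtcn))
  Z <- if (is.null(C)) matrix(1, length(y), 1)
       else cbind(1, C[ok, , drop = FALSE])
  qz <- qr(Z)
  ry <- stats::resid(stats::lm.fit(Z, y))
  RG <- G - Z %*% qr.coef(qz, G)
  dfres <- length(y) - ncol(Z) - 1L
  sxx <- colSums(RG^2)
  beta <- colSums(RG * ry) / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(rss / dfres / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), dfres)
  flag <- !is.finite(p)
  data.frame(ndna_variant = colnames(ndna) %||%
               as.character(seq_len(ncol(ndna))),
             beta = beta, se = se, p = ifelse(flag, NA_real_, p),
             flag = flag)
}

#' Minimum association p-value per nuclear variant
#'
#' Collapses a scan table to the per-nuclear-variant minimum p over all
#' mtDNA variants, the quantity plotted in Manhattan panels.
#'
#' @param scan result of [mtNdnaScan()].
#' @return data.frame: `ndna_variant`, `min_p`.
#' @export
manhattanMinP <- function(scan) {
  sp <- split(scan$p, scan$ndna_variant)
  data.frame(ndna_variant = names(sp),
             min_p = vapply(sp, function(p)
               if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE),
               numeric(1)))
}
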