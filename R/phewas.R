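#' Rank-based inverse-normal transform of covariate-adjusted residuals
#'
#' Regresses the quantitative phenotype on the covariates, ranks the
#' residuals (average ranks for ties) and maps them through the normal
#' quantile function with the Blom offset `(r - 3/8) / (n + 1/4)`.
#' The output has mean ~0, variance ~1, preserves the residual rank
#' order, and is invariant under monotone transforms of the input when
#' no covariates are supplied.
#'
#' @param values numeric phenotype (at least 3 non-missing values).
#' @param covariates optional data.frame of adjustment covariates.
#' @return numeric vector (NA where the input was missing).
#' @examples
#' rankNormalizeResiduals(c(3, 1, 2))  # 0.87, -0.87, 0.00
#' @export
rankNormalizeResiduals <- function(values, covariates = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("at least 3 non-missing values required")
  if (stats::sd(values[ok]) == 0) stop("phenotype is constant")
  res <- values
  if (!is.null(covariates) && NCOL(covariates)) {
    cm <- .covariateMatrix(covariates, length(values))
    fit <- stats::lm.fit(cbind(1, cm[ok, , drop = FALSE]), values[ok])
    res[ok] <- fit$residuals
  }
  r <- rank(res[ok], ties.method = "average")
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Phenome-wide association of imputed mtDNA dosages
#'
#' For each (variant, phenotype) pair: binary traits are tested by
#' logistic regression of the raw phenotype on the dosage with all
#' covariates (controls are all samples not affected by the trait
#' under scope); quantitative traits are first covariate-adjusted and
#' rank-normalized ([rankNormalizeResiduals()]) and then tested by
#' linear regression on the dosage with the stratification covariates
#' (`region`, `platform`) additionally included. The dosage enters as
#' a continuous predictor. Non-convergent or separated logistic fits
#' are flagged; traits with no case or no control are skipped with a
#' warning.
#'
#' @param dosages an [ImputedDosage-class] (or samples x variants
#'   dosage matrix).
#' @param pheno data.frame with one row per sample, aligned with the
#'   dosage rows.
#' @param traits data.frame declaring the phenotypes: columns `trait`
#'   (column name in `pheno`), `type` ("binary" or "quantitative") and
#'   optionally `covariates` (comma-separated trait-specific covariate
#'   names for quantitative traits).
#' @param covariates character vector of shared covariate column names
#'   (default: age, sex, region, platform and any `PC*` columns found).
#' @return data.frame: `variant`, `trait`, `type`, `effect` (log-odds
#'   or beta), `se`, `or`, `ci_low`, `ci_high` (binary only), `p`,
#'   `n`, `n_case`, `n_control`, `flag`.
#' @export
runPhewas <- function(dosages, pheno, traits, covariates = NULL) {
  D <- if (is(dosages, "ImputedDosage")) dosageMatrix(dosages)
       else as.matrix(dosages)
  if (nrow(D) != nrow(pheno))
    stop("dosages and pheno must cover the same samples")
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", "region", "platform",
                              grep("^PC[0-9]+$", names(pheno),
                                   value = TRUE)), names(pheno))
  vids <- colnames(D) %||% as.character(seq_len(ncol(D)))
  out <- list()
  for (ti in seq_len(nrow(traits))) {
    trait <- traits$trait[ti]; type <- traits$type[ti]
    y <- pheno[[trait]]
    if (is.null(y)) stop("trait column not found: ", trait)
    if (type == "binary") {
      if (sum(y == 1, na.rm = TRUE) == 0 ||
          sum(y == 0, na.rm = TRUE) == 0) {
        warning("trait '", trait, "' has no case or no control; skipped")
        next
      }
      C <- .covariateMatrix(pheno[covariates], nrow(pheno))
      for (v in seq_len(ncol(D))) {
        ok <- !is.na(y) & !is.na(D[, v]) &
          stats::complete.cases(C)
        X <- cbind(1, D[ok, v], C[ok, , drop = FALSE])
        f <- .fastLogistic(X, y[ok])
        ci <- f$beta + c(-1, 1) * stats::qnorm(0.975) * f$se
        out[[length(out) + 1L]] <- data.frame(
          variant = vids[v], trait = trait, type = type,
          effect = f$beta, se = f$se, or = exp(f$beta),
          ci_low = exp(ci[1]), ci_high = exp(ci[2]), p = f$p,
          n = sum(ok), n_case = sum(y[ok] == 1),
          n_control = sum(y[ok] == 0), flag = f$flag)
      }
    } else {
      tsc <- character()
      if (!is.null(traits$covariates) && !is.na(traits$covariates[ti]) &&
          nzchar(traits$covariates[ti]))
        tsc <- trimws(strsplit(traits$covariates[ti], ",")[[1]])
      adjCov <- intersect(c(setdiff(covariates,
                                    c("region", "platform")), tsc),
                          names(pheno))
      yrn <- rankNormalizeResiduals(y, pheno[adjCov])
      strat <- intersect(c("region", "platform"), names(pheno))
      C <- .covariateMatrix(pheno[strat], nrow(pheno))
      for (v in seq_len(ncol(D))) {
        ok <- !is.na(yrn) & !is.na(D[, v])
        if (!is.null(C)) ok <- ok & stats::complete.cases(C)
        X <- if (is.null(C)) cbind(1, D[ok, v])
             else cbind(1, D[ok, v], C[ok, , drop = FALSE])
        fit <- stats::lm.fit(X, yrn[ok])
        dfres <- sum(ok) - ncol(X)
        sigma2 <- sum(fit$residuals^2) / dfres
        XtX <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
        if (is.null(XtX) || dfres < 1) {
          out[[length(out) + 1L]] <- data.frame(
            variant = vids[v], trait = trait, type = type,
            effect = NA_real_, se = NA_real_, or = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
            n = sum(ok), n_case = NA_integer_,
            n_control = NA_integer_, flag = TRUE)
          next
        }
        beta <- fit$coefficients[2]
        se <- sqrt(sigma2 * XtX[2, 2])
        p <- 2 * stats::pt(-abs(beta / se), dfres)
        out[[length(out) + 1L]] <- data.frame(
          variant = vids[v], trait = trait, type = type,
          effect = beta, se = se, or = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = p, n = sum(ok),
          n_case = NA_integer_, n_control = NA_integer_,
          flag = !is.finite(p))
      }
    }
  }
  do.call(rbind, out)
}

#' Study-wide and variant-wide significance flags
#'
#' `passes_study_wide` iff `p < 0.05 / (V * P)` and
#' `passes_variant_wide` iff `p < 0.05 / V` (strict inequalities),
#' with V variants and P phenotypes tested.
#'
#' @param results a [runPhewas()] table (column `p`).
#' @param nVariants,nPhenotypes test counts (>= 1).
#' @return `results` with the two logical flag columns appended.
#' @export
applyThresholdFlags <- function(results, nVariants, nPhenotypes) {
  if (nVariants < 1 || nPhenotypes < 1) stop("counts must be >= 1")
  sw <- bonferroniThreshold(0.05, c(nVariants, nPhenotypes))
  vw <- bonferroniThreshold(0.05, nVariants)
  results$passes_study_wide <- !is.na(results$p) & results$p < sw
  results$passes_variant_wide <- !is.na(results$p) & results$p < vw
  results
}

#' Array genotype quality control against reference calls
#'
#' Applies, in order: removal of samples with call rate < 0.9, removal
#' of variants with call rate < 0.99, and removal of variants whose
#' concordance with reference (e.g. WGS) calls over overlapping
#' samples is < 0.99. With no overlap the concordance filter is
#' skipped with a warning.
#'
#' @param calls samples x variants 0/1/NA array genotype matrix with
#'   rownames/colnames.
#' @param referenceCalls optional matrix of reference calls for a
#'   subset of samples (matched by row/column names).
#' @param sampleCallRateMin,variantCallRateMin,concordanceMin the
#'   three thresholds.
#' @return list with `calls` (the filtered matrix) and `report`
#'   (removed counts per filter).
#' @export
arrayQc <- function(calls, referenceCalls = NULL,
                    sampleCallRateMin = 0.9, variantCallRateMin = 0.99,
                    concordanceMin = 0.99) {
  scr <- rowMeans(!is.na(calls))
  dropS <- scr < sampleCallRateMin
  calls <- calls[!dropS, , drop = FALSE]
  vcr <- colMeans(!is.na(calls))
  dropV <- vcr < variantCallRateMin
  calls <- calls[, !dropV, drop = FALSE]
  dropC <- 0L
  overlap <- if (is.null(referenceCalls)) character()
             else intersect(rownames(calls), rownames(referenceCalls))
  if (!is.null(referenceCalls) && length(overlap)) {
    shared <- intersect(colnames(calls), colnames(referenceCalls))
    conc <- vapply(shared, function(v) {
      a <- calls[overlap, v]; b <- referenceCalls[overlap, v]
      ok <- !is.na(a) & !is.na(b)
      if (!sum(ok)) return(NA_real_)
      mean(a[ok] == b[ok])
    }, numeric(1))
    bad <- shared[!is.na(conc) & conc < concordanceMin]
    dropC <- length(bad)
    calls <- calls[, setdiff(colnames(calls), bad), drop = FALSE]
  } else if (!is.null(referenceCalls)) {
    warning("no overlapping samples; concordance filter skipped")
  } else if (is.null(referenceCalls)) {
    warning("no reference calls supplied; concordance filter skipped")
  }
  list(calls = calls,
       report = data.frame(samples_removed = sum(dropS),
                           variants_removed_callrate = sum(dropV),
                           variants_removed_concordance = dropC))
}
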