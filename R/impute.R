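#' Haploid genotype imputation by a haplotype-copying model
#'
#' Imputes untyped mtDNA variants of each target sample from a complete
#' haploid reference panel with a Li-Stephens-style copying hidden
#' Markov model: the hidden state is the reference haplotype being
#' copied, switching between adjacent typed sites with probability
#' `switchRate` (default 1e-8 — effectively a single copying state, the
#' zero-recombination expectation for mtDNA) and emitting the observed
#' allele with mismatch probability `errorRate` (default 1e-3). Untyped
#' doses are posterior-weighted averages of reference alleles.
#'
#' @param panel reference panel: a [HaploidGenotypeMatrix-class] with
#'   complete calls (or a complete 0/1 matrix, haplotypes in rows).
#' @param target a [HaploidGenotypeMatrix-class] typed on a subset of
#'   the panel variants (matched by variant id; `NA` calls count as
#'   untyped), or a 0/1/NA matrix over the full panel variant set.
#' @param switchRate per-adjacent-typed-site copying switch probability.
#' @param errorRate emission mismatch probability.
#' @return An [ImputedDosage-class] over the panel variants: typed
#'   variants keep their observed 0/1 calls (info 1 where complete),
#'   untyped ones carry posterior doses and model-based info scores.
#' @export
haploidImpute <- function(panel, target, switchRate = 1e-8,
                          errorRate = 1e-3) {
  pm <- if (is(panel, "HaploidGenotypeMatrix")) genotypeCalls(panel)
        else as.matrix(panel)
  if (!nrow(pm) || !ncol(pm)) stop("empty reference panel")
  if (anyNA(pm)) stop("reference panel must have complete calls")
  pv <- if (is(panel, "HaploidGenotypeMatrix")) variantInfo(panel)
        else data.frame(id = colnames(pm) %||%
                          as.character(seq_len(ncol(pm))))
  if (is(target, "HaploidGenotypeMatrix")) {
    tid <- variantInfo(target)$id
    missing <- setdiff(tid, pv$id)
    if (length(missing))
      stop("target variants absent from panel: ",
           paste(missing, collapse = ", "))
    tm <- matrix(NA_integer_, nrow(genotypeCalls(target)), ncol(pm),
                 dimnames = list(sampleIds(target), pv$id))
    tm[, match(tid, pv$id)] <- genotypeCalls(target)
  } else {
    tm <- as.matrix(target)
    if (ncol(tm) != ncol(pm))
      stop("matrix target must cover the full panel variant set")
  }
  if (!nrow(tm)) stop("empty target")
  storage.mode(pm) <- "integer"; storage.mode(tm) <- "integer"
  doses <- .lsImputeCpp(pm, tm, switchRate, errorRate,
                        leaveOneOut = FALSE)
  dimnames(doses) <- list(rownames(tm), pv$id)
  typedAnywhere <- colSums(!is.na(tm)) > 0
  info <- apply(doses, 2, infoScore)
  ImputedDosage(doses, info, imputed = !typedAnywhere, variants = pv)
}

#' Imputation info score of a dosage vector
#'
#' `1 - mean(d (1 - d)) / (p (1 - p))` with `p` the mean dose: the
#' haploid form of the ratio of posterior dosage uncertainty to the
#' binomial variance at the estimated frequency. 1 when every dose is
#' a hard 0/1 call; 0 when all doses sit at the frequency itself.
#' Undefined (`NA`) for monomorphic estimated frequency.
#'
#' @param doses per-sample doses in [0, 1] for one variant.
#' @return info score in [0, 1], or `NA`.
#' @examples
#' infoScore(c(0, 1, 0.5, 0.5))  # 0.5
#' @export
infoScore <- function(doses) {
  doses <- doses[!is.na(doses)]
  if (length(doses) < 2) return(NA_real_)
  p <- mean(doses)
  if (p <= 0 || p >= 1) return(NA_real_)
  val <- 1 - mean(doses * (1 - doses)) / (p * (1 - p))
  min(max(val, 0), 1)
}

#' Masking cross-validation of an imputation reference panel
#'
#' Masks a fraction of the panel's calls uniformly at random, imputes
#' each sample from all other samples (leave-one-out copying states),
#' hard-calls doses at 0.5 (ties to the reference allele) and reports
#' the overall concordance at masked calls plus the minor-allele
#' concordance per MAF bin (0-5, 5-10, 10-20, 20-30, 30-40, 40-50%).
#'
#' @param panel a complete [HaploidGenotypeMatrix-class].
#' @param maskFraction fraction of calls to mask (default 0.5).
#' @param seed RNG seed for the mask.
#' @param switchRate,errorRate copying-model parameters as in
#'   [haploidImpute()].
#' @return list with `overall` concordance, `byBin` (data.frame: bin,
#'   concordance, n over true minor-allele carriers) and `nMasked`.
#' @export
crossValidate <- function(panel, maskFraction = 0.5, seed = 1,
                          switchRate = 1e-8, errorRate = 1e-3) {
  calls <- genotypeCalls(panel)
  if (anyNA(calls)) stop("panel must have complete calls")
  n <- nrow(calls); V <- ncol(calls)
  if (maskFraction == 0)
    return(list(overall = 1.0, byBin = NULL, nMasked = 0L,
                note = "empty mask: concordance vacuously 1"))
  mask <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n * V) < maskFraction, n, V)
    full <- which(rowSums(!m) == 0)
    if (length(full)) {
      warning(length(full),
              " sample(s) fully masked; one call re-exposed each")
      for (i in full) m[i, sample.int(V, 1)] <- FALSE
    }
    m
  })
  tm <- calls; tm[mask] <- NA_integer_
  storage.mode(calls) <- "integer"; storage.mode(tm) <- "integer"
  doses <- .lsImputeCpp(calls, tm, switchRate, errorRate,
                        leaveOneOut = TRUE)
  hard <- doses > 0.5          # dose exactly 0.5 -> reference allele
  truth <- calls == 1L
  overall <- mean(hard[mask] == truth[mask])
  af <- colMeans(calls)
  maf <- pmin(af, 1 - af)
  minorIsAlt <- af <= 0.5
  bins <- cut(maf, breaks = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
              include.lowest = TRUE,
              labels = c("0-5%", "5-10%", "10-20%", "20-30%",
                         "30-40%", "40-50%"))
  carrier <- sweep(truth, 2, minorIsAlt, "==")   # true minor allele
  byBin <- do.call(rbind, lapply(levels(bins), function(bl) {
    cols <- which(bins == bl)
    if (!length(cols)) return(data.frame(bin = bl,
                                         concordance = NA_real_,
                                         n = 0L))
    sel <- mask[, cols, drop = FALSE] & carrier[, cols, drop = FALSE]
    nsel <- sum(sel)
    conc <- if (nsel) mean(hard[, cols, drop = FALSE][sel] ==
                             truth[, cols, drop = FALSE][sel])
            else NA_real_
    data.frame(bin = bl, concordance = conc, n = nsel)
  }))
  list(overall = overall, byBin = byBin, nMasked = sum(mask))
}

#' Post-imputation quality-control filtering
#'
#' Retains variants with estimated MAF >= `mafMin` (default 0.5%) and
#' info score >= `infoMin` (default 0.7); variants with undefined info
#' are removed.
#'
#' @param dosages an [ImputedDosage-class].
#' @param mafMin minimum estimated minor allele frequency.
#' @param infoMin minimum info score.
#' @return the filtered [ImputedDosage-class].
#' @export
postImputationFilter <- function(dosages, mafMin = 0.005,
                                 infoMin = 0.7) {
  d <- dosageMatrix(dosages)
  p <- colMeans(d, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  info <- infoScores(dosages)
  keep <- !is.na(maf) & maf >= mafMin & !is.na(info) & info >= infoMin
  ImputedDosage(d[, keep, drop = FALSE], info[keep],
                imputedFlags(dosages)[keep],
                variantInfo(dosages)[keep, , drop = FALSE])
}
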