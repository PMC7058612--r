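#' Haploid linkage disequilibrium r-squared for one variant pair
#'
#' Over jointly non-missing haplotypes, `D = p11 - px * py` and
#' `r2 = D^2 / (px (1-px) py (1-py))`, the original haplotype
#' definition of the LD metric. Equals the squared Pearson correlation
#' of the 0/1 call vectors. Returns `NA` (undefined) when either
#' variant is monomorphic over the compared haplotypes.
#'
#' @param x,y haploid 0/1 call vectors (`NA` = missing).
#' @return r-squared in [0, 1], or `NA`.
#' @examples
#' haploidR2(c(0,0,0,1,1,1), c(0,0,1,1,1,0))  # 1/9
#' @export
haploidR2 <- function(x, y) .pairLdOne(x, y)$r2

#' Absolute D-prime for one haploid variant pair
#'
#' `|D| / Dmax`, where `Dmax = min(px (1-py), (1-px) py)` when `D > 0`
#' and `min(px py, (1-px)(1-py))` otherwise; 1 indicates complete LD
#' (no recombinant gamete observed).
#'
#' @inheritParams haploidR2
#' @return |D'| in [0, 1], or `NA` for monomorphic input.
#' @examples
#' absDprime(c(0,0,0,1,1,1), c(0,0,1,1,1,0))  # 1/3
#' @export
absDprime <- function(x, y) .pairLdOne(x, y)$abs_dprime

.pairLdOne <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (!n) return(list(r2 = NA_real_, abs_dprime = NA_real_))
  px <- mean(x); py <- mean(y)
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1)
    return(list(r2 = NA_real_, abs_dprime = NA_real_))
  p11 <- mean(x == 1 & y == 1)
  D <- p11 - px * py
  r2 <- D^2 / (px * (1 - px) * py * (1 - py))
  dmax <- if (D > 0) min(px * (1 - py), (1 - px) * py)
          else min(px * py, (1 - px) * (1 - py))
  dp <- if (dmax == 0) 0 else abs(D) / dmax
  list(r2 = min(r2, 1), abs_dprime = min(dp, 1))
}

## All-pairs haploid LD matrices (r2, |D'|) for a 0/1 matrix with
## pairwise-complete handling of missing calls.
.pairLdMatrices <- function(calls) {
  M <- (!is.na(calls)) * 1
  A <- calls; A[is.na(A)] <- 0L
  storage.mode(A) <- "double"
  n11 <- crossprod(A)
  nb <- crossprod(M)
  n1x <- crossprod(A, M)
  nx1 <- t(n1x)
  p11 <- n11 / nb
  px <- n1x / nb
  py <- nx1 / nb
  D <- p11 - px * py
  den <- px * (1 - px) * py * (1 - py)
  r2 <- pmin(D^2 / den, 1)
  r2[den <= 0 | nb == 0] <- NA_real_
  dmax <- ifelse(D > 0, pmin(px * (1 - py), (1 - px) * py),
                 pmin(px * py, (1 - px) * (1 - py)))
  dp <- pmin(abs(D) / dmax, 1)
  dp[dmax == 0] <- 0
  dp[den <= 0 | nb == 0] <- NA_real_
  list(r2 = r2, abs_dprime = dp)
}

.commonIdx <- function(af, mafMin) {
  maf <- pmin(af, 1 - af)
  which(!is.na(maf) & maf >= mafMin)
}

#' All-pairs LD table for common mtDNA variants
#'
#' Computes r2 and |D'| for every pair of common variants
#' (MAF >= `mafMin`), with the pair distance as the linear coordinate
#' difference on the reference.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param mafMin common-variant MAF threshold (default 0.05).
#' @return data.frame: `i`, `j`, `pos_i`, `pos_j`, `distance`, `r2`,
#'   `abs_dprime`, `source` ("mt").
#' @export
mtLdPairs <- function(x, mafMin = 0.05) {
  idx <- .commonIdx(altFreqs(x), mafMin)
  if (length(idx) < 2) stop("fewer than two common variants")
  calls <- genotypeCalls(x)[, idx, drop = FALSE]
  pos <- variantPositions(x)[idx]
  ids <- variantInfo(x)$id[idx]
  ld <- .pairLdMatrices(calls)
  ut <- which(upper.tri(ld$r2), arr.ind = TRUE)
  data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
             pos_i = pos[ut[, 1]], pos_j = pos[ut[, 2]],
             distance = abs(pos[ut[, 2]] - pos[ut[, 1]]),
             r2 = ld$r2[ut], abs_dprime = ld$abs_dprime[ut],
             source = "mt")
}

#' Distance-matched random sample of nuclear variant pairs
#'
#' Random sample of common-variant pairs from a phased panel restricted
#' to coordinate distances no larger than `maxDistance` (default
#' 8300 bp, matching the mtDNA molecule scale), with per-pair r2 and
#' |D'| computed on the phased haplotypes.
#'
#' @param panel a [HaplotypePanel-class].
#' @param maxDistance maximum pair distance in bp (default 8300).
#' @param nPairs number of pairs to sample (default: all qualifying
#'   pairs up to 5000).
#' @param seed RNG seed for the pair sample.
#' @param mafMin common-variant MAF threshold (default 0.05).
#' @return data.frame as in [mtLdPairs()], `source` = "nuclear".
#' @export
matchedNuclearPairs <- function(panel, maxDistance = 8300,
                                nPairs = NULL, seed = 1,
                                mafMin = 0.05) {
  idx <- .commonIdx(altFreqs(panel), mafMin)
  if (length(idx) < 2) stop("fewer than two common variants in panel")
  pos <- variantPositions(panel)[idx]
  H <- panelHaplotypes(panel)[, idx, drop = FALSE]
  ## sliding window over position-sorted variants
  pr <- list(); k <- 0L
  for (a in seq_len(length(idx) - 1L)) {
    b <- a + 1L
    while (b <= length(idx) && pos[b] - pos[a] <= maxDistance) {
      k <- k + 1L; pr[[k]] <- c(a, b); b <- b + 1L
    }
  }
  if (!k) stop("no variant pairs within ", maxDistance, " bp")
  pairs <- do.call(rbind, pr)
  withr::with_seed(seed, {
    if (is.null(nPairs)) nPairs <- min(nrow(pairs), 5000L)
    take <- if (nrow(pairs) > nPairs)
      pairs[sample.int(nrow(pairs), nPairs), , drop = FALSE]
    else pairs
  })
  ids <- colnames(H) %||% as.character(seq_along(idx))
  res <- lapply(seq_len(nrow(take)), function(r) {
    a <- take[r, 1]; b <- take[r, 2]
    ld <- .pairLdOne(H[, a], H[, b])
    data.frame(i = ids[a], j = ids[b], pos_i = pos[a], pos_j = pos[b],
               distance = pos[b] - pos[a], r2 = ld$r2,
               abs_dprime = ld$abs_dprime, source = "nuclear")
  })
  do.call(rbind, res)
}

#' Distance-dependent LD decay correlation
#'
#' Pearson correlation between pair distance and r2, with the
#' two-sided p-value: a clearly negative correlation is the signature
#' of recombination-driven LD decay, while non-recombining molecules
#' show none.
#'
#' @param pairs an LD pair table ([mtLdPairs()] or
#'   [matchedNuclearPairs()]).
#' @return list with `R` and `p` (both `NA`, with a warning, when
#'   either vector has zero variance).
#' @export
ldDecayCorrelation <- function(pairs) {
  ok <- !is.na(pairs$r2)
  d <- pairs$distance[ok]; r2 <- pairs$r2[ok]
  if (length(d) < 3 || length(unique(d)) < 2)
    stop("need at least three pairs with distinct distances")
  if (stats::sd(r2) == 0 || stats::sd(d) == 0) {
    warning("zero variance; decay correlation undefined")
    return(list(R = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(d, r2, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value)
}

#' Tag-variant counts per common variant
#'
#' For each common variant, the number of other common variants with
#' r2 at or above `r2Threshold` (default 0.5). For nuclear panels the
#' search is restricted to a +/- `window` neighborhood (default 5 Mbp);
#' for the short mitochondrial molecule it is unrestricted.
#'
#' @param x a [HaploidGenotypeMatrix-class] or [HaplotypePanel-class].
#' @param r2Threshold tag threshold (default 0.5).
#' @param window search window in bp (`NULL` = unrestricted; default
#'   `NULL` for mtDNA, 5e6 for panels).
#' @param mafMin common-variant MAF threshold (default 0.05).
#' @return list with `table` (data.frame: variant, position, maf,
#'   n_tags, untagged) and `untagged_fraction`.
#' @export
tagCounts <- function(x, r2Threshold = 0.5, window = NULL,
                      mafMin = 0.05) {
  if (is(x, "HaploidGenotypeMatrix")) {
    mat <- genotypeCalls(x); pos <- variantPositions(x)
    ids <- variantInfo(x)$id
  } else if (is(x, "HaplotypePanel")) {
    mat <- panelHaplotypes(x); pos <- variantPositions(x)
    ids <- colnames(mat) %||% as.character(seq_along(pos))
    if (is.null(window)) window <- 5e6
  } else stop("unsupported input class")
  af <- colMeans(mat, na.rm = TRUE)
  idx <- .commonIdx(af, mafMin)
  if (length(idx) < 2) stop("fewer than two common variants")
  mat <- mat[, idx, drop = FALSE]; pos <- pos[idx]; ids <- ids[idx]
  r2 <- .pairLdMatrices(mat)$r2
  elig <- !diag(TRUE, length(idx))
  if (!is.null(window))
    elig <- elig & abs(outer(pos, pos, "-")) <= window
  hits <- (r2 >= r2Threshold) & elig
  hits[is.na(hits)] <- FALSE
  nt <- rowSums(hits)
  tab <- data.frame(variant = ids, position = pos,
                    maf = pmin(af[idx], 1 - af[idx]),
                    n_tags = nt, untagged = nt == 0)
  list(table = tab, untagged_fraction = mean(tab$untagged))
}

#' Detect common haplotypes spanning the molecule
#'
#' Builds a graph on common variants with edges where pairwise
#' r2 >= `r2Threshold` (default 0.8); connected components whose
#' positional extent (max - min member coordinate) covers at least
#' `extentFractionMin` of the molecule length are reported as
#' molecule-spanning haplotypes.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param r2Threshold edge threshold (default 0.8).
#' @param extentFractionMin minimum extent as a fraction of the
#'   molecule length (default 0.9).
#' @param mafMin common-variant MAF threshold (default 0.05).
#' @return list of spanning haplotypes, each with `members` (variant
#'   ids), `positions`, `extent` (bp) and `extent_fraction`.
#' @export
spanningHaplotypes <- function(x, r2Threshold = 0.8,
                               extentFractionMin = 0.9, mafMin = 0.05) {
  idx <- .commonIdx(altFreqs(x), mafMin)
  if (length(idx) < 2) return(list())
  calls <- genotypeCalls(x)[, idx, drop = FALSE]
  pos <- variantPositions(x)[idx]
  ids <- variantInfo(x)$id[idx]
  r2 <- .pairLdMatrices(calls)$r2
  adj <- r2 >= r2Threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (cm in unique(comp)) {
    mem <- which(comp == cm)
    if (length(mem) < 2) next
    extent <- max(pos[mem]) - min(pos[mem])
    frac <- extent / mtLength(x)
    if (frac >= extentFractionMin)
      out[[length(out) + 1L]] <- list(members = ids[mem],
                                      positions = pos[mem],
                                      extent = extent,
                                      extent_fraction = frac)
  }
  out
}

#' Enrichment of untagged variants in an annotated region
#'
#' Fisher's exact test (two-sided) on the 2x2 table of
#' (untagged?) x (inside region?), with the sample odds ratio. The
#' canonical use is testing whether common variants without any tag
#' variant concentrate in the hypermutable D-loop.
#'
#' @param tagTable the `table` element of [tagCounts()].
#' @param region a [RegionAnnotation-class] (default [dLoopRegion()]).
#' @return list with `odds_ratio` (sample OR; `Inf`/`NaN` signalled on
#'   an empty margin), `p` and `table` (the 2x2 counts).
#' @export
dloopUntaggedEnrichment <- function(tagTable, region = dLoopRegion()) {
  inr <- inRegion(tagTable$position, region)
  if (!any(inr) || all(inr))
    stop("need at least one variant inside and outside the region")
  tab <- matrix(c(sum(tagTable$untagged & inr),
                  sum(tagTable$untagged & !inr),
                  sum(!tagTable$untagged & inr),
                  sum(!tagTable$untagged & !inr)),
                2, 2, byrow = TRUE,
                dimnames = list(c("untagged", "tagged"),
                                c("in_region", "outside")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p, table = tab)
}
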