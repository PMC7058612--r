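#' Pairwise Hamming distances between haploid samples
#'
#' Proportion of discordant calls among jointly non-missing sites for
#' every sample pair (pairwise deletion). Pairs with no jointly
#' observed site get `NA`.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `"undefined"` lists pairs (if any) with no comparable site.
#' @export
hammingDistances <- function(x) {
  calls <- genotypeCalls(x)
  if (nrow(calls) < 2) stop("at least two samples required")
  M <- !is.na(calls)
  A <- calls; A[!M] <- 0L
  storage.mode(A) <- "double"; storage.mode(M) <- "double"
  X <- A * M; Y <- (1 - A) * M
  mism <- X %*% t(Y) + Y %*% t(X)
  denom <- M %*% t(M)
  d <- mism / denom
  d[denom == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(sampleIds(x), sampleIds(x))
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(und))
    attr(d, "undefined") <- data.frame(i = rownames(d)[und[, 1]],
                                       j = colnames(d)[und[, 2]])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}), returning an unrooted
#' tree with branch lengths. For exactly additive distances NJ recovers
#' the generating topology.
#'
#' @param d symmetric distance matrix with defined entries.
#' @return an \pkg{ape} `phylo` object (write with
#'   [ape::write.tree()] for newick output).
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 4) stop("at least four samples required")
  if (anyNA(d)) {
    und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distances for pairs: ",
         paste(sprintf("(%s,%s)", rownames(d)[und[, 1]],
                       colnames(d)[und[, 2]]), collapse = ", "))
  }
  ape::nj(stats::as.dist(d))
}

#' Fitch parsimony score of site patterns on a fixed tree
#'
#' Sum over sites of the minimum number of state changes on the tree
#' (Fitch dynamic program; exact for binary trees, including the
#' unrooted trifurcation produced by neighbor joining). Sites where any
#' leaf lacks a state are skipped and counted in the `"skipped"`
#' attribute.
#'
#' @param tree an \pkg{ape} `phylo` whose tip labels match the rownames
#'   of `sitePatterns`.
#' @param sitePatterns matrix of discrete states, leaves in rows, sites
#'   in columns (`NA` = missing).
#' @return integer parsimony score with attribute `"skipped"`.
#' @export
fitchParsimonyScore <- function(tree, sitePatterns) {
  sitePatterns <- as.matrix(sitePatterns)
  if (is.null(rownames(sitePatterns)))
    stop("sitePatterns must have leaf rownames")
  if (!all(tree$tip.label %in% rownames(sitePatterns)))
    stop("every tip needs a row of states")
  sp <- sitePatterns[tree$tip.label, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- tr$Nnode
  score <- 0L; skipped <- 0L
  for (s in seq_len(ncol(sp))) {
    states <- sp[, s]
    if (anyNA(states)) { skipped <- skipped + 1L; next }
    lev <- unique(states)
    if (length(lev) > 30) stop("more than 30 states at one site")
    bits <- bitwShiftL(1L, match(states, lev) - 1L)
    sets <- integer(nTip + nNode)
    sets[seq_len(nTip)] <- bits
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (sets[p] == 0L) sets[p] <- sets[ch]
      else {
        inter <- bitwAnd(sets[p], sets[ch])
        if (inter == 0L) {
          score <- score + 1L
          sets[p] <- bitwOr(sets[p], sets[ch])
        } else sets[p] <- inter
      }
    }
  }
  structure(score, skipped = skipped)
}

#' Principal-component embedding of haploid genotypes
#'
#' Mean-centers the call matrix (missing calls imputed to the variant
#' mean), drops zero-variance variants, and returns the top `k`
#' components with their explained-variance ratios.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param k number of components (default 20).
#' @return list with `coordinates` (samples x k), `explainedVariance`
#'   (ratios, summing to <= 1) and `sampleIds`.
#' @export
pcaEmbed <- function(x, k = 20) {
  calls <- .imputedCallMatrix(x)
  v <- apply(calls, 2, stats::var)
  calls <- calls[, v > 0, drop = FALSE]
  if (nrow(calls) < k)
    stop("need at least k samples for k components")
  pc <- stats::prcomp(calls, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (avail < k) {
    warning("rank ", avail, " < k = ", k, "; components truncated")
    k <- avail
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       explainedVariance = evr[seq_len(k)],
       sampleIds = sampleIds(x))
}

.imputedCallMatrix <- function(x) {
  calls <- genotypeCalls(x)
  storage.mode(calls) <- "double"
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- mu[idx[, 2]]
  }
  calls
}

#' UMAP embedding of haploid genotypes
#'
#' Two-component UMAP with the settings used for mitochondrial
#' variant-pattern classification: `n_neighbors = 100`,
#' `min_dist = 0.99`, and a fixed random state for reproducibility.
#' The embedding is delegated to the \code{umap-learn} library through
#' the `python` interpreter on the PATH.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param nNeighbors UMAP `n_neighbors` (default 100; clipped to
#'   `nSamples - 1` with a warning when the cohort is smaller).
#' @param minDist UMAP `min_dist` (default 0.99).
#' @param seed random state (default 42).
#' @param python path to the Python interpreter.
#' @return list with `coordinates` (samples x 2) and `sampleIds`.
#' @export
umapEmbed <- function(x, nNeighbors = 100, minDist = 0.99, seed = 42,
                      python = Sys.which("python")) {
  calls <- .imputedCallMatrix(x)
  if (nrow(calls) < 3) stop("at least three samples required")
  if (nNeighbors >= nrow(calls)) {
    warning("n_neighbors clipped to nSamples - 1 = ", nrow(calls) - 1)
    nNeighbors <- nrow(calls) - 1
  }
  if (!nzchar(python)) stop("python interpreter not found")
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(calls, fin, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  script <- paste(
    "import sys, numpy as np, warnings",
    "warnings.filterwarnings('ignore')",
    "import umap",
    "X = np.loadtxt(sys.argv[1])",
    "m = umap.UMAP(n_neighbors=int(sys.argv[3]),",
    "              min_dist=float(sys.argv[4]),",
    "              random_state=int(sys.argv[5]))",
    "np.savetxt(sys.argv[2], m.fit_transform(X), delimiter='\\t')",
    sep = "\n")
  rc <- system2(python, c("-c", shQuote(script), shQuote(fin),
                          shQuote(fout), nNeighbors, minDist, seed),
                stdout = FALSE, stderr = FALSE)
  if (rc != 0 || !file.exists(fout))
    stop("umap-learn embedding failed (exit code ", rc, ")")
  co <- as.matrix(utils::read.table(fout, sep = "\t"))
  dimnames(co) <- list(sampleIds(x), c("UMAP1", "UMAP2"))
  list(coordinates = co, sampleIds = sampleIds(x))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between cluster labels and (for example)
#' truncated haplogroup labels; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return adjusted Rand index in [-1, 1].
#' @export
labelConcordance <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(labelsA, labelsB)
}
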