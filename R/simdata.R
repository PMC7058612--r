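#' Configuration for the synthetic cohort generators
#'
#' Defaults emulate the statistical structure of a population-scale
#' Japanese WGS cohort: 1928 samples over 7 geographic regions, a
#' haplotree with 11 macrohaplogroups and hierarchical names up to 9
#' characters, a hypermutable control region, a recombining nuclear
#' contrast panel, and depth summaries encoding a true mtDNA copy
#' number. A single `seed` fans out to independent substreams per
#' generator, so adding one generator never perturbs another.
#'
#' @param nSamples number of samples (default 1928).
#' @param mtLength circular mtDNA length in bp (default 16,569).
#' @param nRegions number of geographic strata (default 7).
#' @param haplotreeDepth maximum name length in characters, 1-9.
#' @param nMacro number of macrohaplogroups (single-letter root
#'   children, default 11).
#' @param meanExtraEdgeVariants Poisson mean of defining variants per
#'   edge beyond the guaranteed one (default 0.5).
#' @param mutationRate mean per-site private (lineage-independent)
#'   mutation probability per sample outside the D-loop (default 2e-5,
#'   calibrated so a cohort of ~2000 samples segregates on the order
#'   of 2000 variant sites, the scale seen in deep-WGS mtDNA studies).
#' @param dloopRateMultiplier mutation-rate multiplier inside the
#'   D-loop (default 10, >= 1).
#' @param siteRateSdlog lognormal sdlog of per-site mutability (mean
#'   1; default 2), giving recurrent-mutation hotspots as observed in
#'   the control region.
#' @param backMutationRate per-edge probability of carrying a flagged
#'   back-mutation of an ancestral defining allele (default 0, off).
#' @param regionConcentration Dirichlet concentration tying regional
#'   haplogroup frequencies to the global spectrum; smaller values give
#'   stronger regional heterogeneity (default 20).
#' @param missingRate per-call missingness in the mtDNA matrix
#'   (default 0; deep WGS calls are near-complete).
#' @param nNuclearVariants number of nuclear panel variants.
#' @param nuclearLength length in bp of the simulated nuclear region.
#' @param nFounders founder haplotypes for the nuclear copying process.
#' @param recombRate effective per-bp crossover probability of the
#'   copying process (default 1e-4; population-scaled, so LD decays
#'   over kilobase distances as in real cohorts).
#' @param nChromosomes autosomes in the depth table (default 22).
#' @param autosomalDepth mean autosomal coverage (default 30x).
#' @param depthNoiseSd lognormal sdlog of depth noise (default 0.05).
#' @param mtcnMeanlog,mtcnSdlog lognormal parameters of the true mtDNA
#'   copy number (default ~100 copies/cell, sdlog 0.3).
#' @param nQuantTraits,nBinaryTraits phenotype counts.
#' @param seed integer master seed.
#' @return An object of class `SimConfig` (a validated list).
#' @export
simConfig <- function(nSamples = 1928L, mtLength = RCRS_LENGTH,
                      nRegions = 7L, haplotreeDepth = 9L, nMacro = 11L,
                      meanExtraEdgeVariants = 0.5, mutationRate = 2e-5,
                      dloopRateMultiplier = 10, siteRateSdlog = 2,
                      backMutationRate = 0,
                      regionConcentration = 20, missingRate = 0,
                      nNuclearVariants = 2000L, nuclearLength = 2e6,
                      nFounders = 20L, recombRate = 1e-4,
                      nChromosomes = 22L, autosomalDepth = 30,
                      depthNoiseSd = 0.05, mtcnMeanlog = log(100),
                      mtcnSdlog = 0.3, nQuantTraits = 2L,
                      nBinaryTraits = 2L, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$haplotreeDepth < 1 || cfg$haplotreeDepth > 9)
    stop("haplotreeDepth must be between 1 and 9")
  counts <- c("nSamples", "nRegions", "nMacro", "nNuclearVariants",
              "nFounders", "nChromosomes")
  if (any(unlist(cfg[counts]) < 1))
    stop("all counts must be positive")
  probs <- c("mutationRate", "backMutationRate", "missingRate")
  if (any(unlist(cfg[probs]) < 0) || any(unlist(cfg[probs]) > 1))
    stop("rates must lie in [0, 1]")
  if (cfg$recombRate < 0) stop("recombRate must be >= 0")
  if (cfg$dloopRateMultiplier < 1)
    stop("dloopRateMultiplier must be >= 1")
  if (cfg$autosomalDepth < 0 || cfg$depthNoiseSd < 0)
    stop("depth parameters must be non-negative")
  if (cfg$nNuclearVariants < 2)
    stop("nNuclearVariants must be >= 2")
  structure(cfg, class = "SimConfig")
}

## Independent RNG substream k of the master seed; keeps generators
## decoupled. Seeds stay below 2^31.
.withSubstream <- function(seed, k, code) {
  withr::with_seed((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647,
                   code)
}

## Deterministic reference sequence shared by the tree and cohort
## generators (substream 0).
.simReference <- function(config)
  .withSubstream(config$seed, 0L,
                 sample(c("A", "C", "G", "T"), config$mtLength,
                        replace = TRUE))

## Transition-biased derived allele for a reference base; ~16:1 Ti/Tv
## as observed in mitochondrial mutational spectra.
.mutateBase <- function(ref, tiProb = 0.94) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref, function(b) {
    if (stats::runif(1) < tiProb) ti[[b]]
    else sample(setdiff(c("A", "C", "G", "T"), c(b, ti[[b]])), 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a haplotree of hierarchically named haplogroups
#'
#' Root children are single-letter macrohaplogroups; deeper names
#' alternate digits and letters (M, M7, M7a, ...), so name length equals
#' hierarchy depth. Every edge carries at least one defining variant at
#' a position unique across the tree; optional flagged back-mutations
#' revert an ancestral allele.
#'
#' @param config a [simConfig()] object.
#' @return A [Haplotree-class].
#' @export
simulateHaplotree <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  refSeq <- .simReference(config)
  .withSubstream(config$seed, 1L, {
    macro <- LETTERS[seq_len(min(config$nMacro, 26L))]
    edges <- data.frame(child = macro,
                        parent = rep("MRCA", length(macro)))
    frontier <- macro
    d <- 1L
    while (d < config$haplotreeDepth && length(frontier)) {
      newfrontier <- character()
      for (nd in frontier) {
        k <- sample(0:3, 1, prob = c(0.15, 0.35, 0.35, 0.15))
        if (k == 0) next
        sfx <- if (grepl("[0-9]$", nd)) letters[seq_len(k)]
               else as.character(seq_len(k))
        kids <- paste0(nd, sfx)
        edges <- rbind(edges, data.frame(child = kids,
                                         parent = rep(nd, k)))
        newfrontier <- c(newfrontier, kids)
      }
      frontier <- newfrontier
      d <- d + 1L
    }
    nEdge <- nrow(edges)
    nv <- 1L + stats::rpois(nEdge, config$meanExtraEdgeVariants)
    pool <- sample(config$mtLength)   # unique positions across the tree
    if (sum(nv) > length(pool))
      stop("mtLength too small for the requested tree")
    off <- cumsum(c(0L, nv))
    defs <- vector("list", nEdge)
    names(defs) <- edges$child
    for (i in seq_len(nEdge)) {
      pos <- pool[(off[i] + 1L):off[i + 1L]]
      defs[[i]] <- data.frame(position = pos,
                              allele = .mutateBase(refSeq[pos]),
                              back = FALSE)
    }
    tree <- Haplotree(edges, defs)
    if (config$backMutationRate > 0) {
      ## revert one ancestral allele on randomly chosen deep edges
      for (i in seq_len(nEdge)) {
        anc <- expectedVariants(tree, edges$parent[i])
        if (length(anc) && stats::runif(1) < config$backMutationRate) {
          pick <- sample(length(anc), 1)
          pa <- .parseVariantKey(anc[pick])
          defs[[i]] <- rbind(defs[[i]],
                             data.frame(position = pa$position,
                                        allele = pa$allele, back = TRUE))
        }
      }
      tree <- Haplotree(edges, defs)
    }
    tree
  })
}

#' Simulate a non-recombining mtDNA cohort on a haplotree
#'
#' Each sample draws a leaf haplogroup from its region-specific
#' frequency distribution (regional Dirichlet perturbations of a global
#' spectrum, emulating geographic heterogeneity); its haplotype is the
#' union of defining variants on the root path plus private mutations
#' at `mutationRate` per site, with D-loop sites mutating at
#' `dloopRateMultiplier` times that rate. There is no recombination
#' anywhere.
#'
#' @param tree a [Haplotree-class].
#' @param config a [simConfig()] object.
#' @return list with `genotypes` (a [HaploidGenotypeMatrix-class]),
#'   `truth` (data.frame: sample_id, region, haplogroup) and
#'   `regionalFreqs` (regions x leaves matrix, rows summing to 1).
#' @export
simulateMtCohort <- function(tree, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$nRegions < 1) stop("at least one region required")
  refSeq <- .simReference(config)
  .withSubstream(config$seed, 2L, {
    leaves <- setdiff(tree@edges$child, tree@edges$parent)
    L <- length(leaves)
    global <- stats::rgamma(L, 1); global <- global / sum(global)
    regionalFreqs <- t(vapply(seq_len(config$nRegions), function(r) {
      w <- stats::rgamma(L, config$regionConcentration * global)
      w / sum(w)
    }, numeric(L)))
    dimnames(regionalFreqs) <- list(paste0("region", seq_len(config$nRegions)),
                                    leaves)
    n <- config$nSamples
    region <- sample(config$nRegions, n, replace = TRUE)
    hg <- vapply(region, function(r)
      leaves[sample.int(L, 1, prob = regionalFreqs[r, ])], character(1))

    expSets <- .expectedVariantSets(tree)
    dloop <- inRegion(seq_len(config$mtLength), dLoopRegion())
    ## heavy-tailed per-site mutability (mean 1) emulates recurrent
    ## mutation hotspots; the D-loop multiplier rides on top of it, so
    ## hypermutable control-region sites can recur across lineages
    siteRate <- stats::rlnorm(config$mtLength,
                              -config$siteRateSdlog^2 / 2,
                              config$siteRateSdlog)
    siteW <- siteRate * ifelse(dloop, config$dloopRateMultiplier, 1)
    effLen <- sum(siteW)
    nPriv <- stats::rpois(n, config$mutationRate * effLen)
    privPos <- lapply(nPriv, function(k)
      if (k) sample.int(config$mtLength, k, prob = siteW) else integer())

    ## variant universe: every tree-defining variant plus every private
    ## position observed in >= 1 sample
    defKeys <- unique(unlist(lapply(tree@definingVariants, function(d)
      .variantKey(d$position[!d$back], d$allele[!d$back]))))
    defPos <- vapply(defKeys, function(k) .parseVariantKey(k)$position,
                     numeric(1))
    privOnly <- sort(unique(setdiff(unlist(privPos), defPos)))
    privKeys <- .variantKey(privOnly, .mutateBase(refSeq[privOnly]))
    keys <- c(defKeys, privKeys)
    pos <- as.integer(c(defPos, privOnly))
    ord <- order(pos)
    keys <- keys[ord]; pos <- pos[ord]
    posToKey <- stats::setNames(keys, as.character(pos))

    V <- length(keys)
    calls <- matrix(0L, n, V)
    colIdx <- stats::setNames(seq_len(V), keys)
    for (i in seq_len(n)) {
      on <- expSets[[hg[i]]]
      if (length(privPos[[i]]))
        on <- union(on, posToKey[as.character(privPos[[i]])])
      calls[i, colIdx[on]] <- 1L
    }
    if (config$missingRate > 0) {
      nab <- stats::rbinom(1, length(calls), config$missingRate)
      if (nab) calls[sample(length(calls), nab)] <- NA_integer_
    }
    parsed <- lapply(keys, .parseVariantKey)
    variants <- data.frame(
      id = paste("MT", pos, refSeq[pos],
                 vapply(parsed, `[[`, character(1), "allele"), sep = "_"),
      contig = "MT", position = pos, ref = refSeq[pos],
      alt = vapply(parsed, `[[`, character(1), "allele"))
    sample_ids <- sprintf("S%04d", seq_len(n))
    dimnames(calls) <- list(sample_ids, variants$id)
    list(genotypes = HaploidGenotypeMatrix(calls, variants,
                                           mtLength = config$mtLength),
         truth = data.frame(sample_id = sample_ids,
                            region = paste0("region", region),
                            haplogroup = hg),
         regionalFreqs = regionalFreqs)
  })
}

#' Simulate a recombining phased nuclear haplotype panel
#'
#' 2N haplotypes are generated by a copying process over founder
#' haplotypes: each haplotype copies one founder and switches to a
#' uniformly chosen founder between adjacent variants with probability
#' 1 - exp(-recombRate * gap). Founder alleles are i.i.d. per site with
#' frequency ~ U(0.05, 0.5), so common variants exist and r^2 decreases
#' with distance in expectation.
#'
#' @param config a [simConfig()] object.
#' @return A [HaplotypePanel-class] with `2 * nSamples` haplotypes.
#' @export
simulateNuclearPanel <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSubstream(config$seed, 3L, {
    V <- config$nNuclearVariants
    K <- config$nFounders
    positions <- sort(sample.int(config$nuclearLength, V))
    freq <- stats::runif(V, 0.05, 0.5)
    founders <- matrix(stats::rbinom(K * V, 1, rep(freq, each = K)),
                       K, V)
    pswitch <- 1 - exp(-config$recombRate * diff(positions))
    H <- 2L * config$nSamples
    haps <- matrix(0L, H, V)
    for (h in seq_len(H)) {
      sw <- stats::rbinom(V - 1L, 1L, pswitch)
      cp <- which(sw == 1L)
      segLen <- diff(c(0L, cp, V))
      segF <- sample.int(K, length(segLen), replace = TRUE)
      states <- rep(segF, segLen)
      haps[h, ] <- founders[cbind(states, seq_len(V))]
    }
    rownames(haps) <- paste0("H", seq_len(H))
    colnames(haps) <- paste0("nv", seq_len(V))
    HaplotypePanel(haps, positions)
  })
}

#' Simulate depth summaries and phenotype/covariate tables
#'
#' Per-sample mean mtDNA depth encodes a true copy number:
#' `mt_depth = true_mtCN / 2 * mean(autosomal depth) * lognormal noise`,
#' with per-chromosome autosomal depths around `autosomalDepth`.
#' Quantitative phenotypes are covariate effects plus optional injected
#' mtDNA-variant effects plus unit Gaussian noise; binary phenotypes
#' come from a logistic model on the same linear predictor.
#'
#' @param truth cohort truth table from [simulateMtCohort()] (columns
#'   `sample_id`, `region`).
#' @param config a [simConfig()] object.
#' @param genotypes optional [HaploidGenotypeMatrix-class] whose calls
#'   carry the injected variant effects.
#' @param effects optional data.frame (`variant_id`, `trait`, `beta`)
#'   of injected per-allele effects; `trait` names a phenotype column.
#' @param trueMtcn optional per-sample true copy numbers (otherwise
#'   drawn lognormal from the config).
#' @return list with `depths` (data.frame: sample_id, mt_depth,
#'   chr1..), `pheno` (covariates + traits `qt*`, `bt*`) and `truth`
#'   (input truth augmented with `true_mtcn`).
#' @export
simulateDepthsAndPhenotypes <- function(truth, config, genotypes = NULL,
                                        effects = NULL, trueMtcn = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  n <- nrow(truth)
  if (!n) stop("truth table is empty")
  .withSubstream(config$seed, 4L, {
    if (is.null(trueMtcn))
      trueMtcn <- stats::rlnorm(n, config$mtcnMeanlog, config$mtcnSdlog)
    auto <- matrix(config$autosomalDepth *
                     stats::rlnorm(n * config$nChromosomes, 0,
                                   config$depthNoiseSd),
                   n, config$nChromosomes)
    mt <- trueMtcn / 2 * rowMeans(auto) *
      stats::rlnorm(n, 0, config$depthNoiseSd)
    depths <- data.frame(sample_id = truth$sample_id, mt_depth = mt)
    autodf <- as.data.frame(auto)
    names(autodf) <- paste0("chr", seq_len(config$nChromosomes))
    depths <- cbind(depths, autodf)

    pcs <- matrix(stats::rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("PC", 1:20)))
    pheno <- data.frame(sample_id = truth$sample_id,
                        age = round(stats::rnorm(n, 60, 10)),
                        sex = stats::rbinom(n, 1, 0.5),
                        region = truth$region,
                        platform = sample(c("arrayA", "arrayB"), n,
                                          replace = TRUE))
    pheno <- cbind(pheno, as.data.frame(pcs))

    injected <- function(trait) {
      eff <- numeric(n)
      if (is.null(effects) || is.null(genotypes)) return(eff)
      sel <- effects[effects$trait == trait, , drop = FALSE]
      for (k in seq_len(nrow(sel))) {
        g <- genotypeCalls(genotypes)[, sel$variant_id[k]]
        g[is.na(g)] <- 0L
        eff <- eff + sel$beta[k] * g
      }
      eff
    }
    for (q in seq_len(config$nQuantTraits)) {
      trait <- paste0("qt", q)
      pheno[[trait]] <- 0.02 * pheno$age + 0.3 * pheno$sex +
        0.1 * pcs[, 1] + injected(trait) + stats::rnorm(n)
    }
    for (b in seq_len(config$nBinaryTraits)) {
      trait <- paste0("bt", b)
      eta <- -1.5 + 0.02 * (pheno$age - 60) + 0.2 * pheno$sex +
        injected(trait)
      pheno[[trait]] <- stats::rbinom(n, 1, stats::plogis(eta))
    }
    truth$true_mtcn <- trueMtcn
    list(depths = depths, pheno = pheno, truth = truth)
  })
}
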