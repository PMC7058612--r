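test_that("generators are fully deterministic under a fixed seed", {
  cfg <- simConfig(nSamples = 60, seed = 17)
  t1 <- simulateHaplotree(cfg); t2 <- simulateHaplotree(cfg)
  expect_identical(t1@edges, t2@edges)
  expect_identical(t1@definingVariants, t2@definingVariants)
  c1 <- simulateMtCohort(t1, cfg); c2 <- simulateMtCohort(t2, cfg)
  expect_identical(genotypeCalls(c1$genotypes),
                   genotypeCalls(c2$genotypes))
  expect_identical(c1$truth, c2$truth)
  p1 <- simulateNuclearPanel(cfg); p2 <- simulateNuclearPanel(cfg)
  expect_identical(panelHaplotypes(p1), panelHaplotypes(p2))
  d1 <- simulateDepthsAndPhenotypes(c1$truth, cfg)
  d2 <- simulateDepthsAndPhenotypes(c2$truth, cfg)
  expect_identical(d1$depths, d2$depths)
  expect_identical(d1$pheno, d2$pheno)
})

test_that("haplotree names follow the hierarchical letter/digit scheme", {
  cfg <- simConfig(seed = 23, haplotreeDepth = 3, nMacro = 5)
  tree <- simulateHaplotree(cfg)
  nodes <- setdiff(treeNodes(tree), "MRCA")
  expect_true(all(nchar(nodes) <= 3))
  expect_true(all(grepl("^[A-Z]$", substr(nodes, 1, 1))))
  # every truncation of a deeper name is an ancestor in the tree
  deep <- nodes[nchar(nodes) == 3]
  expect_true(all(substr(deep, 1, 2) %in% nodes))
  # each edge carries at least one defining variant, unique positions
  nv <- vapply(tree@definingVariants, nrow, integer(1))
  expect_true(all(nv >= 1))
  allpos <- unlist(lapply(tree@definingVariants,
                          function(d) d$position[!d$back]))
  expect_false(anyDuplicated(allpos) > 0)
  # depth 1: only single-character macrohaplogroup names
  cfg1 <- simConfig(seed = 23, haplotreeDepth = 1)
  expect_true(all(nchar(setdiff(treeNodes(simulateHaplotree(cfg1)),
                                "MRCA")) == 1))
  expect_error(simConfig(haplotreeDepth = 0), "between 1 and 9")
  expect_error(simConfig(haplotreeDepth = 10), "between 1 and 9")
})

test_that("noiseless cohorts carry exactly their lineage's defining set", {
  cfg <- simConfig(nSamples = 80, mutationRate = 0, seed = 29)
  tree <- simulateHaplotree(cfg)
  coh <- simulateMtCohort(tree, cfg)
  v <- variantInfo(coh$genotypes)
  keys <- paste0(v$position, v$alt)
  calls <- genotypeCalls(coh$genotypes)
  leaves <- setdiff(tree@edges$child, tree@edges$parent)
  for (i in seq_len(nrow(calls))) {
    observed <- keys[calls[i, ] == 1]
    expected <- expectedVariants(tree, coh$truth$haplogroup[i])
    expect_setequal(observed, expected)
    # no recombinants: the lineage is a single leaf's root path
    expect_true(coh$truth$haplogroup[i] %in% leaves)
  }
  expect_true(all(abs(rowSums(coh$regionalFreqs) - 1) < 1e-12))
})

test_that("D-loop private mutations are enriched by the rate multiplier", {
  cfg <- simConfig(nSamples = 2000, dloopRateMultiplier = 10, seed = 37)
  tree <- simulateHaplotree(cfg)
  coh <- simulateMtCohort(tree, cfg)
  v <- variantInfo(coh$genotypes)
  defPos <- unlist(lapply(tree@definingVariants,
                          function(d) d$position))
  priv <- !(v$position %in% defPos)
  # carrier counts of private (recurrent + singleton) mutations
  carriers <- colSums(genotypeCalls(coh$genotypes)[, priv, drop = FALSE],
                      na.rm = TRUE)
  inD <- inRegion(v$position[priv], dLoopRegion())
  dlen <- sum(inRegion(1:16569, dLoopRegion()))
  x <- sum(carriers[inD]); tot <- sum(carriers)
  bt <- stats::binom.test(x, tot, p = dlen / 16569,
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("nuclear panel reduces to founder copies without recombination", {
  cfg <- simConfig(nSamples = 100, nNuclearVariants = 200,
                   recombRate = 0, nFounders = 8, seed = 41)
  pan <- simulateNuclearPanel(cfg)
  H <- panelHaplotypes(pan)
  expect_lte(nrow(unique(H)), 8)
  expect_true(!is.unsorted(variantPositions(pan)))
})

test_that("recombination produces distance-dependent r2 decay", {
  cfg <- simConfig(nSamples = 250, nNuclearVariants = 400,
                   nuclearLength = 4e5, recombRate = 0.01, seed = 43)
  pan <- simulateNuclearPanel(cfg)
  H <- panelHaplotypes(pan); pos <- variantPositions(pan)
  af <- colMeans(H)
  ok <- which(pmin(af, 1 - af) >= 0.05)
  set.seed(1)
  near <- c(); far <- c()
  for (rep in 1:400) {
    ab <- sample(ok, 2)
    d <- abs(pos[ab[1]] - pos[ab[2]])
    r2 <- haploidR2(H[, ab[1]], H[, ab[2]])
    if (is.na(r2)) next
    if (d < 500) near <- c(near, r2)
    if (d > 5000) far <- c(far, r2)
  }
  expect_gt(mean(near), mean(far))
})

test_that("depth simulation inverts to the true copy number", {
  cfg0 <- simConfig(nSamples = 3, depthNoiseSd = 0, autosomalDepth = 30,
                    seed = 47)
  truth <- data.frame(sample_id = c("a", "b", "c"),
                      region = "region1")
  d0 <- simulateDepthsAndPhenotypes(truth, cfg0,
                                    trueMtcn = c(100, 100, 100))
  expect_equal(d0$depths$mt_depth, rep(1500, 3))
  expect_equal(d0$truth$true_mtcn, rep(100, 3))
  expect_error(simConfig(autosomalDepth = -1), "non-negative")
  expect_error(simulateDepthsAndPhenotypes(truth[0, ], cfg0), "empty")
})

test_that("injected variant effects propagate into phenotypes", {
  cfg <- simConfig(nSamples = 5000, seed = 53)
  coh <- simulateMtCohort(simulateHaplotree(cfg), cfg)
  af <- altFreqs(coh$genotypes)
  vid <- variantInfo(coh$genotypes)$id[which.min(abs(af - 0.05))]
  eff <- data.frame(variant_id = vid, trait = "qt1", beta = 1)
  dp <- simulateDepthsAndPhenotypes(coh$truth, cfg,
                                    genotypes = coh$genotypes,
                                    effects = eff)
  g <- genotypeCalls(coh$genotypes)[, vid]
  fit <- summary(stats::lm(dp$pheno$qt1 ~ g))
  expect_gt(coef(fit)[2, 1], 0.7)
  expect_lt(coef(fit)[2, 4], 1e-10)
})
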