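test_that("r2 and |D'| match their haplotype-count definitions", {
  expect_equal(haploidR2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(haploidR2(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  expect_equal(haploidR2(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 0)),
               1 / 9)
  expect_equal(absDprime(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 0)),
               1 / 3)
  expect_equal(absDprime(c(0, 0, 1, 1), c(0, 0, 0, 1)), 1)  # no recombinant
  expect_equal(absDprime(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  # monomorphic input is undefined
  expect_true(is.na(haploidR2(c(0, 0, 0), c(0, 1, 0))))
  expect_true(is.na(absDprime(c(1, 1), c(0, 1))))
})

test_that("pairwise LD obeys its identities on random vectors", {
  set.seed(89)
  for (i in 1:60) {
    n <- sample(8:40, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    o <- bruteLd(x, y)
    r2 <- haploidR2(x, y); dp <- absDprime(x, y)
    expect_equal(r2, o$r2)
    expect_equal(dp, o$dprime)
    if (is.na(r2)) next
    # identity with squared Pearson correlation
    expect_equal(r2, suppressWarnings(stats::cor(x, y))^2,
                 tolerance = 1e-12)
    # symmetry and joint allele-relabel invariance
    expect_equal(haploidR2(y, x), r2)
    expect_equal(haploidR2(1 - x, 1 - y), r2)
    expect_equal(absDprime(1 - x, 1 - y), dp)
    # |r| <= |D'|
    expect_lte(sqrt(r2), dp + 1e-12)
  }
  # missing calls handled by pairwise deletion
  x <- c(0, 0, NA, 1, 1, 1); y <- c(0, 1, 1, NA, 1, 0)
  o <- bruteLd(x, y)
  expect_equal(haploidR2(x, y), o$r2)
})

test_that("mtDNA pair tables cover all common-variant pairs", {
  cfg <- simConfig(nSamples = 150, seed = 97)
  coh <- simulateMtCohort(simulateHaplotree(cfg), cfg)
  pr <- mtLdPairs(coh$genotypes)
  af <- altFreqs(coh$genotypes)
  nc <- sum(pmin(af, 1 - af) >= 0.05)
  expect_equal(nrow(pr), nc * (nc - 1) / 2)
  expect_true(all(pr$distance == abs(pr$pos_i - pr$pos_j)))
  expect_true(all(pr$r2 >= 0 & pr$r2 <= 1, na.rm = TRUE))
  expect_true(all(sqrt(pr$r2) <= pr$abs_dprime + 1e-9, na.rm = TRUE))
})

test_that("matched nuclear pairs respect the distance cap and seed", {
  cfg <- simConfig(nSamples = 120, nNuclearVariants = 300,
                   nuclearLength = 3e5, seed = 101)
  pan <- simulateNuclearPanel(cfg)
  p1 <- matchedNuclearPairs(pan, maxDistance = 8300, nPairs = 200,
                            seed = 3)
  expect_true(all(p1$distance <= 8300))
  expect_true(all(p1$distance >= 0))
  p2 <- matchedNuclearPairs(pan, maxDistance = 8300, nPairs = 200,
                            seed = 3)
  expect_identical(p1, p2)
  # per-pair r2 equals the brute-force count formula on the haplotypes
  H <- panelHaplotypes(pan)
  af <- colMeans(H)
  common <- colnames(H)[pmin(af, 1 - af) >= 0.05]
  for (r in sample(nrow(p1), 20)) {
    o <- bruteLd(H[, p1$i[r]], H[, p1$j[r]])
    expect_equal(p1$r2[r], o$r2)
  }
  expect_error(matchedNuclearPairs(pan, maxDistance = 0), "no variant pairs")
})

test_that("decay correlation flags degenerate input", {
  pr <- data.frame(distance = c(10, 200, 4000), r2 = c(0.3, 0.3, 0.3))
  expect_warning(res <- ldDecayCorrelation(pr), "zero variance")
  expect_true(is.na(res$R))
  expect_error(ldDecayCorrelation(pr[1:2, ]), "three pairs")
})

test_that("tag counts identify proxies and untagged variants", {
  set.seed(103)
  base <- rbinom(60, 1, 0.5)
  orth <- rbinom(60, 1, 0.5)
  while (abs(suppressWarnings(cor(base, orth))) > 0.2)
    orth <- rbinom(60, 1, 0.5)
  calls <- cbind(base, base, orth, rbinom(60, 1, 0.4))
  x <- makeHgm(calls, positions = c(100, 5000, 9000, 12000))
  tc <- tagCounts(x, r2Threshold = 0.5)
  tab <- tc$table
  expect_gte(tab$n_tags[1], 1)       # duplicated column is a perfect proxy
  expect_gte(tab$n_tags[2], 1)
  expect_true(tab$untagged[3])       # orthogonal variant has no tags
  expect_equal(tc$untagged_fraction, mean(tab$untagged))
  # nuclear window restriction
  H <- cbind(base, base, base)
  pan <- HaplotypePanel(H, positions = c(1, 1000, 6.1e6))
  tcw <- tagCounts(pan, window = 5e6)
  expect_equal(tcw$table$n_tags, c(1, 1, 0))
})

test_that("spanning haplotypes follow the r2 graph and extent rule", {
  set.seed(107)
  core <- rbinom(50, 1, 0.5)
  noise <- matrix(rbinom(50 * 3, 1, 0.5), 50, 3)
  calls <- cbind(core, core, core, noise)
  x <- makeHgm(calls, positions = c(100, 8000, 16000, 300, 500, 700))
  sh <- spanningHaplotypes(x, r2Threshold = 0.8,
                           extentFractionMin = 0.9)
  expect_identical(length(sh), 1L)
  expect_setequal(sh[[1]]$positions, c(100, 8000, 16000))
  expect_equal(sh[[1]]$extent, 15900)
  expect_equal(sh[[1]]$extent_fraction, 15900 / 16569, tolerance = 1e-9)
  # tightly clustered perfect LD does not span the molecule
  y <- makeHgm(cbind(core, core, core), positions = c(100, 500, 900))
  expect_identical(length(spanningHaplotypes(y)), 0L)
  # membership invariant under variant reordering
  ord <- c(4, 1, 6, 2, 3, 5)
  x2 <- makeHgm(calls[, ord], positions = c(100, 8000, 16000, 300,
                                            500, 700)[ord])
  sh2 <- spanningHaplotypes(x2)
  expect_identical(length(sh2), 1L)
  expect_setequal(sh2[[1]]$positions, sh[[1]]$positions)
})

test_that("untagged/D-loop enrichment uses Fisher's exact test", {
  tab <- data.frame(position = c(rep(16100, 10), rep(8000, 10)),
                    untagged = c(rep(TRUE, 10), rep(FALSE, 10)))
  en <- dloopUntaggedEnrichment(tab)
  expect_identical(en$odds_ratio, Inf)
  expect_equal(en$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_lt(en$p, 1e-4)
  tab2 <- data.frame(position = rep(c(16100, 8000), 10),
                     untagged = rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  en2 <- dloopUntaggedEnrichment(tab2)
  expect_equal(en2$odds_ratio, 1)
  expect_equal(en2$p, 1)
  expect_error(dloopUntaggedEnrichment(
    data.frame(position = c(16100, 16200), untagged = c(TRUE, FALSE))),
    "inside and outside")
})

test_that("hypermutable D-loop cohorts concentrate untagged variants there", {
  # elevated recurrent mutation creates common homoplasious D-loop
  # variants that no tree variant tags
  cfg <- simConfig(nSamples = 800, mutationRate = 2e-3, seed = 109)
  coh <- simulateMtCohort(simulateHaplotree(cfg), cfg)
  tc <- tagCounts(coh$genotypes)
  inD <- inRegion(tc$table$position, dLoopRegion())
  expect_gt(mean(tc$table$untagged[inD]),
            mean(tc$table$untagged[!inD]))
  en <- dloopUntaggedEnrichment(tc$table)
  expect_gt(en$odds_ratio, 1)
})
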