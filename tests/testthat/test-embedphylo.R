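test_that("Hamming distances count discordant calls over compared sites", {
  x <- makeHgm(rbind(c(0, 0, 1), c(0, 1, 1), c(0, 0, 1)))
  d <- hammingDistances(x)
  expect_equal(unname(d[1, 2]), 1 / 3)
  expect_equal(unname(d[1, 3]), 0)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  # pairwise deletion and undefined pairs
  y <- makeHgm(rbind(c(0, NA, 1), c(NA, 1, NA), c(0, 1, 1)))
  dy <- hammingDistances(y)
  expect_equal(unname(dy[2, 3]), 0)      # only site 2 compared
  z <- makeHgm(rbind(c(0, NA), c(NA, 1), c(0, 1)))
  dz <- hammingDistances(z)
  expect_true(is.na(dz[1, 2]))
  expect_false(is.null(attr(dz, "undefined")))
  expect_error(neighborJoining(rbind(cbind(dz, 0), 0)), "undefined")
})

test_that("NJ recovers additive topologies", {
  # quartet with ((A,B),(C,D)) structure
  tips <- c("A", "B", "C", "D")
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:1.5,D:2.5):1);")
  d <- ape::cophenetic.phylo(tr)[tips, tips]
  nj <- neighborJoining(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  # property: random additive trees up to 8 taxa
  set.seed(59)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    rt <- ape::rtree(n)
    rt$edge.length <- rt$edge.length + 0.1    # keep strictly additive
    D <- ape::cophenetic.phylo(rt)
    njt <- neighborJoining(D)
    expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(njt)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(neighborJoining(matrix(0, 3, 3)), "four")
})

test_that("the deepest NJ split separates two simulated clades", {
  # two macrohaplogroup-like clades with many defining differences
  set.seed(61)
  nA <- 12; nB <- 12; V <- 40
  base <- matrix(rbinom(24 * V, 1, 0.1), 24, V)
  base[1:nA, 1:10] <- 1L        # clade-defining block for clade A
  base[(nA + 1):24, 11:20] <- 1L
  x <- makeHgm(base)
  njt <- neighborJoining(hammingDistances(x))
  cladeA <- sampleIds(x)[1:nA]
  # the clade forms a split of the unrooted tree
  parts <- ape::prop.part(njt)
  splits <- lapply(parts, function(p) njt$tip.label[p])
  found <- any(vapply(splits, function(s)
    setequal(s, cladeA) || setequal(s, setdiff(sampleIds(x), cladeA)),
    logical(1)))
  expect_true(found)
})

test_that("Fitch score equals the exhaustive parsimony minimum", {
  qt <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sp <- matrix(c(0, 0, 1, 1), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(unclass(fitchParsimonyScore(qt, sp)), 1,
               ignore_attr = TRUE)
  sp2 <- matrix(c(0, 1, 0, 1), 4, 1,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(unclass(fitchParsimonyScore(qt, sp2)), 2,
               ignore_attr = TRUE)
  spc <- matrix(1, 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(unclass(fitchParsimonyScore(qt, spc)), 0,
               ignore_attr = TRUE)
  # missing leaf state: site skipped and reported
  spm <- cbind(sp, c(0, NA, 1, 1))
  rownames(spm) <- c("A", "B", "C", "D")
  fm <- fitchParsimonyScore(qt, spm)
  expect_equal(unclass(fm), 1, ignore_attr = TRUE)
  expect_equal(attr(fm, "skipped"), 1L)
  # oracle: exhaustive minimum over internal labelings, trees <= 8 leaves
  set.seed(67)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(sample(0:2, n, replace = TRUE),
                              tr$tip.label)
    sp <- matrix(states, ncol = 1, dimnames = list(names(states), NULL))
    expect_equal(unclass(fitchParsimonyScore(tr, sp)),
                 bruteParsimony(tr, states), ignore_attr = TRUE)
  }
})

test_that("Fitch agrees with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  set.seed(71)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    sp <- matrix(sample(c("a", "c"), n * 6, replace = TRUE), n, 6,
                 dimnames = list(tr$tip.label, NULL))
    pd <- phangorn::phyDat(sp, type = "USER", levels = c("a", "c"))
    expect_equal(unclass(fitchParsimonyScore(tr, sp)),
                 as.integer(phangorn::parsimony(tr, pd)),
                 ignore_attr = TRUE)
  }
})

test_that("PCA separates clades on PC1 and reports variance ratios", {
  set.seed(73)
  block <- matrix(rbinom(40 * 30, 1, 0.05), 40, 30)
  block[1:20, 1:12] <- 1L           # clade-defining block
  x <- makeHgm(block)
  pc <- pcaEmbed(x, k = 5)
  expect_identical(ncol(pc$coordinates), 5L)
  expect_lte(sum(pc$explainedVariance), 1)
  expect_gt(pc$explainedVariance[1], pc$explainedVariance[2])
  # PC1 separates the clades
  side <- pc$coordinates[, 1] > stats::median(pc$coordinates[, 1])
  expect_true(all(side[1:20] == side[1]) && all(side[21:40] != side[1]))
  # duplicated samples map to identical coordinates
  dup <- makeHgm(block[c(1, 1, 2:40), ])
  pd <- pcaEmbed(dup, k = 3)
  expect_equal(pd$coordinates[1, ], pd$coordinates[2, ],
               ignore_attr = TRUE)
  # k above rank is truncated with a warning
  tiny <- makeHgm(matrix(c(0, 1, 0, 1, 0, 1), 3, 2))
  expect_warning(pcaEmbed(tiny, k = 3), "truncated")
})

test_that("adjusted Rand index behaves at its reference points", {
  a <- rep(1:3, each = 10)
  expect_equal(labelConcordance(a, a), 1)
  expect_lte(labelConcordance(rep(1, 30), a), 0)
  set.seed(79)
  r1 <- sample(1:5, 1000, replace = TRUE)
  r2 <- sample(1:5, 1000, replace = TRUE)
  expect_lt(abs(labelConcordance(r1, r2)), 0.05)
  expect_error(labelConcordance(1:3, 1:4), "equal length")
})

test_that("UMAP embedding is reproducible and resolves haplogroup clusters", {
  # five well-separated variant-pattern clusters
  set.seed(83)
  k <- 5; per <- 50; V <- 60
  calls <- matrix(rbinom(k * per * V, 1, 0.02), k * per, V)
  for (g in seq_len(k))
    calls[((g - 1) * per + 1):(g * per),
          ((g - 1) * 12 + 1):(g * 12)] <- 1L
  x <- makeHgm(calls)
  truth <- rep(seq_len(k), each = per)
  e1 <- umapEmbed(x, nNeighbors = 50, minDist = 0.99, seed = 7)
  expect_identical(dim(e1$coordinates), c(250L, 2L))
  e2 <- umapEmbed(x, nNeighbors = 50, minDist = 0.99, seed = 7)
  expect_identical(e1$coordinates, e2$coordinates)
  km <- stats::kmeans(e1$coordinates, centers = k, nstart = 20)
  expect_gte(labelConcordance(km$cluster, truth), 0.8)
  expect_error(umapEmbed(makeHgm(matrix(0:1, 2, 3))), "three samples")
})
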