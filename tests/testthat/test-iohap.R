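test_that("VCF reading maps haploid and diploid GT encodings", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=MT,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
          "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("MT", "73", ".", "A", "G", ".", "PASS", ".", "GT",
          "0", "1", ".", sep = "\t"),
    paste("MT", "150", ".", "A", "G,C", ".", "PASS", ".", "GT",
          "1", "2", "0", sep = "\t"),
    paste("MT", "200", ".", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "1/1", "0/1", sep = "\t")), f)
  x <- readHaploidVcf(f, "MT")
  calls <- genotypeCalls(x)
  # haploid site: direct mapping with missing
  expect_identical(unname(calls[, 1]), c(0L, 1L, NA))
  # multiallelic split into two biallelic records
  expect_identical(variantInfo(x)$alt[2:3], c("G", "C"))
  expect_identical(unname(calls[, 2]), c(1L, 0L, 0L))
  expect_identical(unname(calls[, 3]), c(0L, 1L, 0L))
  # diploid homozygous accepted, heterozygous excluded as missing
  expect_identical(unname(calls[, 4]), c(0L, 1L, NA))
  expect_error(readHaploidVcf(f, "chr1"), "contig")
  expect_error(readHaploidVcf(tempfile(), "MT"), "not found")
})

test_that("write/read round trip preserves calls and variant fields", {
  cfg <- simConfig(nSamples = 40, seed = 5)
  coh <- simulateMtCohort(simulateHaplotree(cfg), cfg)
  f <- tempfile(fileext = ".vcf")
  writeHaploidVcf(coh$genotypes, f)
  back <- readHaploidVcf(f, "MT")
  expect_identical(genotypeCalls(back), genotypeCalls(coh$genotypes))
  expect_identical(variantInfo(back)[c("position", "ref", "alt")],
                   variantInfo(coh$genotypes)[c("position", "ref", "alt")])
})

test_that("MAF bins use the stated boundaries and partition [0, 0.5]", {
  expect_equal(as.character(classifyMafBin(c(0.004, 0.005, 0.05))),
               c("rare", "low_frequency", "common"))
  expect_equal(as.character(classifyMafBin(c(0, 0.0049999, 0.0499, 0.5))),
               c("rare", "rare", "low_frequency", "common"))
  # every valid MAF maps to exactly one bin
  set.seed(1)
  maf <- c(stats::runif(500, 0, 0.5), 0, 0.5, 0.005, 0.05)
  bins <- classifyMafBin(maf)
  expect_false(anyNA(bins))
  expect_error(classifyMafBin(0.6), "0, 0.5")
  expect_error(classifyMafBin(-0.1), "0, 0.5")
})

test_that("Ti/Tv counts transitions vs transversions", {
  expect_equal(titvRatio(data.frame(ref = c("A", "C", "G", "A"),
                                    alt = c("G", "T", "A", "C"))), 3)
  expect_equal(titvRatio(data.frame(ref = "A", alt = "C")), 0)
  expect_warning(
    r <- titvRatio(data.frame(ref = c("A", "T"), alt = c("G", "C"))),
    "undefined")
  expect_identical(r, Inf)
  expect_error(titvRatio(data.frame(ref = character(),
                                    alt = character())), "non-empty")
  # strand complement invariance: A->G and T->C are both transitions
  set.seed(2)
  bases <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(names(bases), 60, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(names(bases), b), 1), character(1))
  fwd <- titvRatio(data.frame(ref = ref, alt = alt))
  rev <- titvRatio(data.frame(ref = unname(bases[ref]),
                              alt = unname(bases[alt])))
  expect_equal(fwd, rev)
})

test_that("HWE exact test matches independent enumeration", {
  # independent oracle: direct conditional probability formula
  oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    rare <- min(2 * nAA + nAa, 2 * naa + nAa)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
      hr <- (rare - h) / 2; hc <- n - h - hr
      exp(h * log(2) + lfactorial(n) - lfactorial(h) -
            lfactorial(hr) - lfactorial(hc))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, hets)] + 1e-12])
  }
  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    g <- table(factor(sample(0:2, n, replace = TRUE,
                             prob = c(0.4, 0.4, 0.2)), levels = 0:2))
    expect_equal(hweExactTest(g[1], g[2], g[3]),
                 oracle(g[1], g[2], g[3]), tolerance = 1e-10)
  }
  expect_gt(hweExactTest(25, 50, 25), 0.9)   # perfect HWE proportions
  expect_lt(hweExactTest(50, 0, 50), 1e-6)   # extreme het deficit
})

test_that("nuclear QC applies call-rate, MAF and HWE filters", {
  set.seed(4)
  n <- 200
  good <- stats::rbinom(n, 2, 0.3)
  lowcr <- good; lowcr[sample(n, 5)] <- NA       # call rate 0.975
  mono <- rep(0L, n)
  hwe_bad <- c(rep(0L, n / 2), rep(2L, n / 2))   # no heterozygotes
  g <- cbind(good = good, lowcr = lowcr, mono = mono,
             hwe_bad = hwe_bad)
  qc <- nuclearVariantQc(g)
  expect_identical(colnames(qc$genotypes), "good")
  rep <- qc$report
  expect_false(rep$pass[rep$variant == "lowcr"])
  expect_false(rep$pass[rep$variant == "mono"])
  expect_lt(rep$hwe_p[rep$variant == "hwe_bad"], 1e-6)
  # HWE-consistent proportions retained
  expect_gt(rep$hwe_p[rep$variant == "good"], 1e-6)
})

test_that("D-loop membership wraps the circular origin", {
  r <- dLoopRegion()
  expect_identical(inRegion(c(16024, 16569, 1, 576, 577, 16023, 8000), r),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # region annotation round trip
  f <- tempfile(fileext = ".tsv")
  writeRegionAnnotation(list(`D-loop` = r), f)
  back <- readRegionAnnotation(f)
  expect_identical(inRegion(1:20000 %% 16569 + 1, back[["D-loop"]]),
                   inRegion(1:20000 %% 16569 + 1, r))
})

test_that("variant spectra summarize MAF bins, Ti/Tv and region content", {
  cfg <- simConfig(nSamples = 150, seed = 9)
  coh <- simulateMtCohort(simulateHaplotree(cfg), cfg)
  vs <- variantSpectra(coh$genotypes)
  expect_equal(sum(vs$maf_bins), 1)
  expect_gt(vs$titv, 5)            # transition-dominated spectrum
  expect_true(vs$region_fraction > 0 && vs$region_fraction < 1)
  expect_identical(nrow(vs$variants), ncol(genotypeCalls(coh$genotypes)))
})
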