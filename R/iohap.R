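#' Read haploid genotypes for one contig from a VCF file
#'
#' Parses a VCF 4.x file and returns the biallelic haploid genotype
#' matrix for the requested contig. Multiallelic rows are split into one
#' biallelic record per alternative allele. Haploid GT fields ("0", "1",
#' ".") are used directly; homozygous diploid encodings are accepted
#' ("0/0" -> 0, "1/1" -> 1) while heterozygous diploid calls — which on
#' the mitochondrial contig would represent heteroplasmy-like mixtures —
#' are set to missing.
#'
#' @param path path to a VCF file (optionally gzipped).
#' @param contig contig to extract (e.g. "MT").
#' @param mtLength circular reference length recorded on the result
#'   (default rCRS, 16,569 bp).
#' @return A [HaploidGenotypeMatrix-class].
#' @export
readHaploidVcf <- function(path, contig = "MT", mtLength = RCRS_LENGTH) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("malformed VCF '", path, "': ",
                       conditionMessage(e)))
  fix <- v@fix
  if (!contig %in% fix[, "CHROM"])
    stop("contig '", contig, "' not present in ", path)
  keep <- fix[, "CHROM"] == contig
  fix <- fix[keep, , drop = FALSE]
  gtraw <- v@gt[keep, -1, drop = FALSE]
  sample_ids <- colnames(v@gt)[-1]
  ## first colon-delimited field is GT
  gt <- sub(":.*$", "", gtraw)
  ## split multiallelic rows into one biallelic record per ALT allele
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    lapply(seq_along(alts), function(a) {
      calls <- .decodeGt(gt[i, ], a)
      list(variant = data.frame(
             id = paste(contig, pos, ref, alts[a], sep = "_"),
             contig = contig, position = pos, ref = ref,
             alt = alts[a], stringsAsFactors = FALSE),
           calls = calls)
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  variants <- do.call(rbind, lapply(rows, `[[`, "variant"))
  calls <- do.call(cbind, lapply(rows, `[[`, "calls"))
  dimnames(calls) <- list(sample_ids, variants$id)
  HaploidGenotypeMatrix(calls, variants, mtLength = mtLength)
}

## Map raw GT strings to 0/1/NA for alternative allele index `altIdx`.
## Haploid "0"/"k"/"." and homozygous diploid "0/0", "k/k" (or "|")
## are accepted; anything heterozygous or half-missing is NA.
.decodeGt <- function(g, altIdx) {
  g <- trimws(g)
  g[is.na(g)] <- "."
  parts <- strsplit(g, "[/|]")
  vapply(parts, function(p) {
    p <- p[p != ""]
    if (!length(p) || any(p == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) return(NA_integer_)
    if (length(unique(a)) > 1L) return(NA_integer_)  # heterozygous
    if (a[1] == altIdx) 1L else if (a[1] == 0L) 0L else 0L
  }, integer(1))
}

#' Write a HaploidGenotypeMatrix as a haploid VCF
#'
#' Emits a minimal VCF 4.2 file with one biallelic row per variant and
#' haploid GT fields ("0", "1", "."). Round-tripping through
#' [readHaploidVcf()] preserves calls, positions and alleles exactly.
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHaploidVcf <- function(x, path) {
  v <- variantInfo(x)
  calls <- genotypeCalls(x)
  gt <- matrix(as.character(t(calls)), nrow = nrow(v))
  gt[is.na(gt)] <- "."
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", v$contig[1],
                   as.integer(mtLength(x))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
  body <- paste(v$contig, v$position, v$id, v$ref, v$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify minor allele frequencies into the standard bins
#'
#' Rare: MAF < 0.5%; low-frequency: 0.5% <= MAF < 5%; common: MAF >= 5%.
#' The bins partition [0, 0.5].
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @return factor with levels `rare`, `low_frequency`, `common`.
#' @examples
#' classifyMafBin(c(0.004, 0.005, 0.05))
#' @export
classifyMafBin <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5))
    stop("MAF values must lie in [0, 0.5]")
  cut(maf, breaks = c(-Inf, 0.005, 0.05, Inf), right = FALSE,
      labels = c("rare", "low_frequency", "common"))
}

#' Transition/transversion ratio of a variant set
#'
#' Transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
#' (C<->T) substitutions; all other single-base substitutions are
#' transversions. With zero transversions the ratio is undefined and
#' `Inf` is returned with a warning rather than a silent division.
#'
#' @param variants data.frame with columns `ref` and `alt`
#'   (single-character bases).
#' @return The Ti/Tv ratio (possibly `Inf`).
#' @examples
#' titvRatio(data.frame(ref = c("A","C","G","A"), alt = c("G","T","A","C")))
#' @export
titvRatio <- function(variants) {
  if (!nrow(variants)) stop("variant list must be non-empty")
  ref <- toupper(variants$ref); alt <- toupper(variants$alt)
  subst <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  pur <- c("A", "G")
  ti <- sum(subst & (ref %in% pur) == (alt %in% pur))
  tv <- sum(subst) - ti
  if (tv == 0L) {
    warning("no transversions observed; Ti/Tv is undefined (Inf)")
    return(Inf)
  }
  ti / tv
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on diploid genotype counts, summing the
#' probabilities of all heterozygote counts no more likely than the
#' observed one, conditional on the allele counts.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return The exact two-sided p-value.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  nA <- 2 * nAA + nAa          # minor/major irrelevant: symmetric
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  ## feasible heterozygote counts share the parity of `rare`
  hets <- seq(rare %% 2, rare, by = 2)
  ## conditional probability of nAa = h given the allele counts is
  ## proportional to 2^h * n! / (h! * nhom_rare! * nhom_comm!);
  ## compute in log space and normalize over feasible h.
  nhom_rare <- (rare - hets) / 2
  nhom_comm <- (n - hets - nhom_rare)
  logp <- hets * log(2) + lfactorial(n) - lfactorial(hets) -
    lfactorial(nhom_rare) - lfactorial(nhom_comm)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Quality-control filtering of diploid nuclear variants
#'
#' Retains variants with call rate >= 0.99, MAF >= 1% and exact
#' Hardy-Weinberg p-value >= 1e-6, the standard pre-association filters.
#' Monomorphic variants fall to the MAF filter, not an error.
#'
#' @param genotypes integer matrix of diploid dosages (0/1/2, NA
#'   missing), samples in rows.
#' @param callRateMin minimum per-variant call rate (default 0.99).
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hwePMin minimum HWE exact p-value (default 1e-6).
#' @return list with `genotypes` (the retained columns) and `report`, a
#'   data.frame of per-variant statistics and pass flags.
#' @export
nuclearVariantQc <- function(genotypes, callRateMin = 0.99,
                             mafMin = 0.01, hwePMin = 1e-6) {
  cr <- colMeans(!is.na(genotypes))
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    hweExactTest(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                 sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  pass <- cr >= callRateMin & !is.na(maf) & maf >= mafMin & hwe >= hwePMin
  report <- data.frame(variant = colnames(genotypes) %||%
                         as.character(seq_len(ncol(genotypes))),
                       call_rate = cr, maf = maf, hwe_p = hwe,
                       pass = pass)
  list(genotypes = genotypes[, pass, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test positions for membership in an annotated region
#'
#' @param positions 1-based coordinates.
#' @param region a [RegionAnnotation-class] (intervals wrapping the
#'   circular origin are represented as explicit rows, so this is a
#'   plain inclusive interval test).
#' @return logical vector.
#' @examples
#' inRegion(c(16100, 300, 600), dLoopRegion())
#' @export
inRegion <- function(positions, region) {
  iv <- region@intervals
  out <- rep(FALSE, length(positions))
  for (k in seq_len(nrow(iv)))
    out <- out | (positions >= iv$start[k] & positions <= iv$end[k])
  out
}

#' Read a BED-like region annotation table
#'
#' Tab-separated with header columns `name`, `start`, `end` (1-based
#' inclusive). Rows sharing a name are merged into one region with
#' several intervals (e.g. the two arcs of the D-loop).
#'
#' @param path file path.
#' @return named list of [RegionAnnotation-class] objects.
#' @export
readRegionAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$name), function(d)
    RegionAnnotation(d$name[1], d[, c("start", "end")]))
}

#' Write a region annotation table
#' @param regions named list of [RegionAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionAnnotation <- function(regions, path) {
  tab <- do.call(rbind, lapply(regions, function(r)
    data.frame(name = r@name, start = r@intervals$start,
               end = r@intervals$end)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-sample depth summary table
#'
#' Tab-separated with header: `sample_id`, `mt_depth`, then one column
#' per autosomal chromosome (e.g. `chr1` .. `chr22`) of mean depths.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readDepthTable <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read a phenotype/covariate table
#' @param path tab-separated file with a header row; one row per sample.
#' @return data.frame.
#' @export
readPhenoTable <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Basic variant spectra of a haploid genotype matrix
#'
#' Per-variant alternative-allele frequencies fold to MAF; reports the
#' MAF-bin composition, the Ti/Tv ratio of the polymorphic sites and the
#' fraction of variants inside an annotated region (default: D-loop).
#'
#' @param x a [HaploidGenotypeMatrix-class].
#' @param region a [RegionAnnotation-class] (default [dLoopRegion()]).
#' @return list with `maf_bins` (table), `titv`, `region_fraction`,
#'   and the per-variant table `variants` (maf, bin, in_region).
#' @export
variantSpectra <- function(x, region = dLoopRegion()) {
  af <- altFreqs(x)
  maf <- pmin(af, 1 - af)
  bin <- classifyMafBin(maf)
  v <- variantInfo(x)
  inr <- inRegion(v$position, region)
  list(maf_bins = table(bin) / length(bin),
       titv = titvRatio(v),
       region_fraction = mean(inr),
       variants = data.frame(id = v$id, position = v$position,
                             maf = maf, bin = bin, in_region = inr))
}
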