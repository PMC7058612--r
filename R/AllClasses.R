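#' @import methods
NULL

## Length of the revised Cambridge Reference Sequence (rCRS), the circular
## human mitochondrial reference in 1-based coordinates.
RCRS_LENGTH <- 16569L

#' HaploidGenotypeMatrix: samples x biallelic haploid variants
#'
#' Container for haploid genotype calls (0 = reference, 1 = alternative,
#' `NA` = missing) at biallelic variant sites on a circular mitochondrial
#' reference. Multiallelic sites are represented as multiple biallelic
#' variants sharing a position.
#'
#' @slot calls integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids); values 0, 1 or NA.
#' @slot variants data.frame with one row per variant: `id`, `contig`,
#'   `position` (1-based), `ref`, `alt`.
#' @slot mtLength numeric, length of the circular reference molecule in bp.
#'
#' @exportClass HaploidGenotypeMatrix
setClass("HaploidGenotypeMatrix",
  representation(calls = "matrix", variants = "data.frame",
                 mtLength = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- object@variants
    if (ncol(object@calls) != nrow(v))
      msg <- c(msg, "ncol(calls) must equal nrow(variants)")
    need <- c("id", "contig", "position", "ref", "alt")
    if (!all(need %in% names(v)))
      msg <- c(msg, paste("variants must have columns:",
                          paste(need, collapse = ", ")))
    bad <- object@calls[!is.na(object@calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
      msg <- c(msg, "calls must be 0, 1 or NA")
    if ("position" %in% names(v)) {
      if (any(v$position < 1)) msg <- c(msg, "positions must be >= 1")
      if (any(v$position > object@mtLength))
        msg <- c(msg, "positions must not exceed the reference length")
    }
    if (all(c("ref", "alt") %in% names(v)) && nrow(v) &&
        any(v$ref == v$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (length(msg)) msg else TRUE
  })

#' Construct a HaploidGenotypeMatrix
#'
#' @param calls numeric/integer matrix of 0, 1, NA; samples in rows.
#' @param variants data.frame with columns `id`, `contig`, `position`,
#'   `ref`, `alt` (one row per column of `calls`).
#' @param mtLength reference molecule length in bp (default rCRS, 16,569).
#' @return A [HaploidGenotypeMatrix-class] object.
#' @examples
#' v <- data.frame(id = "MT_73_A_G", contig = "MT", position = 73,
#'                 ref = "A", alt = "G")
#' HaploidGenotypeMatrix(matrix(c(0, 1, NA), 3, 1,
#'                       dimnames = list(paste0("s", 1:3), v$id)), v)
#' @export
HaploidGenotypeMatrix <- function(calls, variants, mtLength = RCRS_LENGTH) {
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls))) colnames(calls) <- variants$id
  variants <- as.data.frame(variants)
  rownames(variants) <- NULL
  new("HaploidGenotypeMatrix", calls = calls, variants = variants,
      mtLength = as.numeric(mtLength))
}

#' HaplotypePanel: phased haploid nuclear haplotypes
#'
#' Phased nuclear haplotypes (2N rows for N diploid samples) at biallelic
#' sites with linear genomic coordinates, used for the distance-matched
#' LD comparison and as imputation reference material.
#'
#' @slot haplotypes integer matrix of 0/1, haplotypes in rows.
#' @slot positions numeric vector of 1-based variant coordinates
#'   (one per column), non-decreasing.
#'
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", positions = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@haplotypes) != length(object@positions))
      msg <- c(msg, "one position per haplotype column required")
    if (any(is.na(object@haplotypes)))
      msg <- c(msg, "phased haplotypes must be complete (no NA)")
    if (length(object@positions) > 1 && is.unsorted(object@positions))
      msg <- c(msg, "positions must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' @rdname HaplotypePanel-class
#' @param haplotypes 0/1 matrix, haplotypes in rows.
#' @param positions variant coordinates, one per column.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(haplotypes, positions) {
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", haplotypes = haplotypes,
      positions = as.numeric(positions))
}

#' Haplotree: rooted tree of hierarchically named haplogroups
#'
#' Each edge (parent -> child) carries one or more defining variant
#' alleles, written as `"<position><allele>"`; a back-mutation is flagged
#' and removes its target allele from the expected set of all descendants.
#'
#' @slot root character, name of the root node.
#' @slot edges data.frame with columns `child`, `parent`.
#' @slot definingVariants named list (by child) of data.frames with
#'   columns `position`, `allele`, `back` (logical).
#'
#' @exportClass Haplotree
setClass("Haplotree",
  representation(root = "character", edges = "data.frame",
                 definingVariants = "list"),
  validity = function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("child", "parent") %in% names(e)))
      msg <- c(msg, "edges must have columns child, parent")
    if (anyDuplicated(e$child))
      msg <- c(msg, "each node may have only one parent")
    if (object@root %in% e$child)
      msg <- c(msg, "root must not appear as a child")
    known <- c(object@root, e$child)
    if (!all(e$parent %in% known))
      msg <- c(msg, "every parent must be the root or another child")
    if (nrow(e) && !all(e$child %in% names(object@definingVariants)))
      msg <- c(msg, "every child needs a definingVariants entry")
    ## acyclicity: walk each node to the root
    if (!length(msg) && nrow(e)) {
      up <- stats::setNames(e$parent, e$child)
      for (n in e$child) {
        seen <- character(); cur <- n
        while (cur != object@root) {
          if (cur %in% seen) { msg <- c(msg, "tree contains a cycle"); break }
          seen <- c(seen, cur)
          cur <- up[[cur]]
          if (is.null(cur)) break
        }
        if (length(msg)) break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a Haplotree
#'
#' @param edges data.frame with columns `child`, `parent`.
#' @param definingVariants named list (by child name) of data.frames
#'   with columns `position`, `allele` and optionally `back`.
#' @param root root node name (default `"MRCA"`).
#' @return A [Haplotree-class] object.
#' @export
Haplotree <- function(edges, definingVariants, root = "MRCA") {
  edges <- as.data.frame(edges)
  definingVariants <- lapply(definingVariants, function(d) {
    d <- as.data.frame(d)
    if (is.null(d$back)) d$back <- FALSE
    d$allele <- as.character(d$allele)
    d$position <- as.integer(d$position)
    d
  })
  new("Haplotree", root = root, edges = edges,
      definingVariants = definingVariants)
}

#' ImputedDosage: posterior expected allele doses with info scores
#'
#' @slot doses numeric matrix in [0,1], samples in rows, variants in
#'   columns.
#' @slot info numeric vector, one imputation-quality score per variant
#'   (NA where undefined).
#' @slot imputed logical vector, TRUE where the variant was not typed in
#'   the target data and its doses are model posteriors.
#' @slot variants data.frame describing the variants (as in
#'   [HaploidGenotypeMatrix-class]).
#'
#' @exportClass ImputedDosage
setClass("ImputedDosage",
  representation(doses = "matrix", info = "numeric", imputed = "logical",
                 variants = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- object@doses[!is.na(object@doses)]
    if (length(d) && (min(d) < -1e-9 || max(d) > 1 + 1e-9))
      msg <- c(msg, "doses must lie in [0, 1]")
    if (length(object@info) != ncol(object@doses))
      msg <- c(msg, "one info score per variant required")
    if (length(object@imputed) != ncol(object@doses))
      msg <- c(msg, "one imputed flag per variant required")
    if (length(msg)) msg else TRUE
  })

ImputedDosage <- function(doses, info, imputed, variants) {
  new("ImputedDosage", doses = doses, info = as.numeric(info),
      imputed = as.logical(imputed), variants = as.data.frame(variants))
}

#' RegionAnnotation: named set of 1-based inclusive intervals
#'
#' Intervals that wrap the circular origin are given as two explicit
#' rows (e.g. the D-loop as 16,024-16,569 plus 1-576), so membership is
#' a plain interval test.
#'
#' @slot name character region name (gene symbol or "D-loop").
#' @slot intervals data.frame with columns `start`, `end` (1-based,
#'   inclusive, start <= end within each row).
#'
#' @exportClass RegionAnnotation
setClass("RegionAnnotation",
  representation(name = "character", intervals = "data.frame"),
  validity = function(object) {
    msg <- character()
    iv <- object@intervals
    if (!all(c("start", "end") %in% names(iv)))
      msg <- c(msg, "intervals must have columns start, end")
    else {
      if (!nrow(iv)) msg <- c(msg, "at least one interval required")
      else if (any(iv$start > iv$end))
        msg <- c(msg, "start must be <= end in every interval")
      if (nrow(iv) && any(iv$start < 1))
        msg <- c(msg, "coordinates are 1-based")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname RegionAnnotation-class
#' @param name region name.
#' @param intervals data.frame with `start`, `end`.
#' @return A [RegionAnnotation-class] object.
#' @export
RegionAnnotation <- function(name, intervals) {
  new("RegionAnnotation", name = name,
      intervals = as.data.frame(intervals))
}

#' The mitochondrial control region (D-loop)
#'
#' Canonical control-region bounds on the rCRS: 16,024-16,569 wrapping
#' the origin into 1-576.
#'
#' @return A [RegionAnnotation-class] for the D-loop.
#' @export
dLoopRegion <- function() {
  RegionAnnotation("D-loop",
                   data.frame(start = c(16024L, 1L), end = c(16569L, 576L)))
}
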