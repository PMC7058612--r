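## Variant-set keys: "<position><derived allele>", e.g. "73G".
.variantKey <- function(position, allele) paste0(position, allele)

.parseVariantKey <- function(key) {
  m <- regmatches(key, regexec("^([0-9]+)(.+)$", key))[[1]]
  if (length(m) != 3) stop("malformed variant key: ", key)
  list(position = as.integer(m[2]), allele = m[3])
}

#' Expected variant set of a haplotree node
#'
#' Union of defining variant alleles on the root-to-node path; a flagged
#' back-mutation removes its target allele from the set for the node and
#' its descendants.
#'
#' @param tree a [Haplotree-class].
#' @param node node name.
#' @return character vector of variant keys (`"<position><allele>"`).
#' @export
setGeneric("expectedVariants",
           function(tree, node) standardGeneric("expectedVariants"))

#' @rdname expectedVariants
#' @export
setMethod("expectedVariants", "Haplotree", function(tree, node) {
  if (!node %in% treeNodes(tree)) stop("unknown node: ", node)
  if (node == tree@root) return(character())
  up <- stats::setNames(tree@edges$parent, tree@edges$child)
  path <- character(); cur <- node
  while (cur != tree@root) { path <- c(cur, path); cur <- up[[cur]] }
  set <- character()
  for (nd in path) {
    d <- tree@definingVariants[[nd]]
    set <- union(set, .variantKey(d$position[!d$back], d$allele[!d$back]))
    if (any(d$back))
      set <- setdiff(set, .variantKey(d$position[d$back], d$allele[d$back]))
  }
  set
})

## Expected sets for every node at once (single BFS; used by the
## vectorized assigner and the cohort simulator).
.expectedVariantSets <- function(tree) {
  sets <- list()
  sets[[tree@root]] <- character()
  todo <- tree@edges$child[tree@edges$parent == tree@root]
  while (length(todo)) {
    nxt <- character()
    for (nd in todo) {
      d <- tree@definingVariants[[nd]]
      s <- union(sets[[tree@edges$parent[tree@edges$child == nd]]],
                 .variantKey(d$position[!d$back], d$allele[!d$back]))
      if (any(d$back))
        s <- setdiff(s, .variantKey(d$position[d$back], d$allele[d$back]))
      sets[[nd]] <- s
      nxt <- c(nxt, tree@edges$child[tree@edges$parent == nd])
    }
    todo <- nxt
  }
  sets
}

#' Kulczynski similarity between observed and expected variant sets
#'
#' `0.5 * (|O n E| / |E| + |O n E| / |O|)`; 0 when the observed set is
#' empty. Equals 1 exactly when the two non-empty sets coincide.
#'
#' @param observed,expected character vectors of variant keys; the
#'   expected set must be non-empty.
#' @return similarity in [0, 1].
#' @examples
#' kulczynskiScore(c("73G"), c("73G", "146C"))  # 0.75
#' @export
kulczynskiScore <- function(observed, expected) {
  if (!length(expected)) stop("expected set must be non-empty")
  observed <- unique(observed); expected <- unique(expected)
  if (!length(observed)) return(0)
  i <- length(intersect(observed, expected))
  0.5 * (i / length(expected) + i / length(observed))
}

#' Assign a sample's variant set to a haplogroup
#'
#' Scores every tree node by [kulczynskiScore()] against its expected
#' set and returns the maximizer; ties are broken by greater name depth
#' (character count), then lexicographic order. A sample with no
#' observed variants is assigned the root.
#'
#' @param tree a [Haplotree-class].
#' @param observed character vector of variant keys carried by the
#'   sample.
#' @return data.frame row: `best_node`, `score`, `runner_up_score`.
#' @export
assignHaplogroup <- function(tree, observed) {
  nodes <- setdiff(treeNodes(tree), tree@root)
  if (!length(nodes)) stop("tree has no non-root nodes")
  sets <- .expectedVariantSets(tree)
  sc <- vapply(nodes, function(nd) kulczynskiScore(observed, sets[[nd]]),
               numeric(1))
  .pickBest(nodes, sc, rootName = tree@root,
            emptyObserved = !length(observed))
}

.pickBest <- function(nodes, sc, rootName, emptyObserved) {
  if (emptyObserved)
    return(data.frame(best_node = rootName, score = 0,
                      runner_up_score = 0))
  best <- max(sc)
  cand <- nodes[sc >= best - 1e-12]
  cand <- cand[order(-nchar(cand), cand)]
  runner <- if (length(sc) > 1) max(sc[nodes != cand[1]]) else 0
  data.frame(best_node = cand[1], score = best,
             runner_up_score = runner)
}

#' Assign every sample of a haploid genotype matrix to a haplogroup
#'
#' Vectorized over samples: each sample's observed set is the keys of
#' its alternative calls; scoring is as in [assignHaplogroup()].
#'
#' @param tree a [Haplotree-class].
#' @param x a [HaploidGenotypeMatrix-class].
#' @return data.frame: `sample_id`, `best_node`, `score`,
#'   `runner_up_score`.
#' @export
assignHaplogroups <- function(tree, x) {
  nodes <- setdiff(treeNodes(tree), tree@root)
  if (!length(nodes)) stop("tree has no non-root nodes")
  sets <- .expectedVariantSets(tree)
  v <- variantInfo(x)
  keys <- .variantKey(v$position, v$alt)
  universe <- unique(unlist(sets[nodes]))
  E <- vapply(nodes, function(nd) universe %in% sets[[nd]],
              logical(length(universe)))
  E <- matrix(as.numeric(E), ncol = length(nodes),
              dimnames = list(universe, nodes))
  expSize <- colSums(E)
  calls <- genotypeCalls(x)
  calls0 <- calls; calls0[is.na(calls0)] <- 0L
  inU <- match(keys, universe)
  O <- matrix(0, nrow(calls), length(universe))
  hit <- !is.na(inU)
  ## collapse matrix columns sharing a universe key (multiple variants
  ## at one position map to distinct keys, so this is one-to-one here)
  O[, inU[hit]] <- calls0[, hit]
  inter <- O %*% E                          # samples x nodes
  obsSize <- rowSums(calls0)
  sc <- 0.5 * (sweep(inter, 2, expSize, "/") + inter / pmax(obsSize, 1))
  res <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    .pickBest(nodes, sc[i, ], tree@root, obsSize[i] == 0)))
  cbind(data.frame(sample_id = sampleIds(x)), res)
}

#' Truncate a haplogroup name to a given depth
#'
#' Depth counts characters including digits, so `"D4b"` is depth 3.
#'
#' @param name haplogroup name(s).
#' @param depth number of leading characters to keep (>= 1).
#' @return truncated name(s).
#' @examples
#' truncateHaplogroup("D4b2", 3)    # "D4b"
#' truncateHaplogroup("M9a1a1c1a", 1)
#' @export
truncateHaplogroup <- function(name, depth) {
  if (depth < 1) stop("depth must be >= 1")
  if (any(!nzchar(name))) stop("empty haplogroup name")
  substr(name, 1L, depth)
}

#' Haplogroup frequency spectrum by stratum and name depth
#'
#' Relative frequencies of depth-truncated haplogroup names within each
#' stratum (rows summing to 1), as in stacked regional bar plots.
#'
#' @param assignments character vector of haplogroup names.
#' @param strata stratum label per sample.
#' @param depth truncation depth in characters.
#' @return matrix strata x truncated names, rows summing to 1.
#' @export
haplogroupSpectrum <- function(assignments, strata, depth) {
  if (length(assignments) != length(strata))
    stop("assignments and strata must align")
  keep <- !is.na(strata)
  if (any(!keep)) warning("samples with missing stratum omitted")
  tr <- truncateHaplogroup(assignments[keep], depth)
  tab <- table(strata[keep], tr)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("empty strata omitted: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' Cumulative distinct-haplogroup counts by name depth
#'
#' Number of distinct depth-truncated names at each depth; the count is
#' non-decreasing in depth, with diminishing increments once the depth
#' exceeds the resolution of the underlying tree.
#'
#' @param assignments character vector of haplogroup names.
#' @param depths depths to evaluate (default 1:9).
#' @return named integer vector.
#' @export
haplogroupCounts <- function(assignments, depths = 1:9) {
  stats::setNames(vapply(depths, function(d)
    length(unique(truncateHaplogroup(assignments, d))), integer(1)),
    paste0("depth", depths))
}

#' Read a haplotree from its TSV representation
#'
#' Columns `child`, `parent`, `variants`; `variants` is a
#' comma-separated list of `"<position><allele>"` tokens, with a
#' trailing `"!"` marking a back-mutation.
#'
#' @param path file path.
#' @param root root node name (default `"MRCA"`).
#' @return A [Haplotree-class].
#' @export
readHaplotree <- function(path, root = "MRCA") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  defs <- lapply(strsplit(tab$variants, ",", fixed = TRUE), function(v) {
    v <- trimws(v)
    back <- grepl("!$", v)
    v <- sub("!$", "", v)
    p <- lapply(v, .parseVariantKey)
    data.frame(position = vapply(p, `[[`, numeric(1), "position"),
               allele = vapply(p, `[[`, character(1), "allele"),
               back = back)
  })
  names(defs) <- tab$child
  Haplotree(tab[, c("child", "parent")], defs, root = root)
}

#' Write a haplotree to TSV
#' @param tree a [Haplotree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHaplotree <- function(tree, path) {
  vstr <- vapply(tree@edges$child, function(nd) {
    d <- tree@definingVariants[[nd]]
    paste0(.variantKey(d$position, d$allele),
           ifelse(d$back, "!", ""), collapse = ",")
  }, character(1))
  tab <- data.frame(child = tree@edges$child,
                    parent = tree@edges$parent, variants = vstr)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
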