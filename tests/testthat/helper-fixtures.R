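# Small in-code fixtures shared across test files.

# HaploidGenotypeMatrix from a bare call matrix; variants get default
# A>G alleles at the given positions.
makeHgm <- function(calls, positions = seq_len(ncol(calls)),
                    mtLength = 16569, alt = NULL) {
  calls <- as.matrix(calls)
  if (is.null(alt)) alt <- rep("G", ncol(calls))
  v <- data.frame(id = paste0("MT_", positions, "_A_", alt),
                  contig = "MT", position = as.integer(positions),
                  ref = "A", alt = alt)
  rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  colnames(calls) <- v$id
  HaploidGenotypeMatrix(calls, v, mtLength = mtLength)
}

# Three-level chain MRCA -> A (73G) -> A1 (146C) -> A1a (back 73G, 200T)
chainTree <- function() {
  Haplotree(
    edges = data.frame(child = c("A", "A1", "A1a"),
                       parent = c("MRCA", "A", "A1")),
    definingVariants = list(
      A = data.frame(position = 73, allele = "G", back = FALSE),
      A1 = data.frame(position = 146, allele = "C", back = FALSE),
      A1a = data.frame(position = c(73, 200), allele = c("G", "T"),
                       back = c(TRUE, FALSE))))
}

# Independent brute-force 2x2 haplotype-count LD oracle.
bruteLd <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  px <- (n11 + n10) / n; py <- (n11 + n01) / n
  if (px %in% c(0, 1) || py %in% c(0, 1))
    return(list(r2 = NA_real_, dprime = NA_real_))
  D <- n11 / n - px * py
  r2 <- D^2 / (px * (1 - px) * py * (1 - py))
  dmax <- if (D > 0) min(px * (1 - py), (1 - px) * py)
          else min(px * py, (1 - px) * (1 - py))
  list(r2 = r2, dprime = if (dmax == 0) 0 else abs(D) / dmax)
}

# Exhaustive-minimum parsimony oracle: minimize state changes over all
# assignments of internal node states (rooted traversal of an ape tree).
bruteParsimony <- function(tree, states) {
  states <- states[tree$tip.label]
  lev <- unique(states)
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_along(lev)), nInt)))
  stateIdx <- match(states, lev)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    full <- c(stateIdx, grid[g, ])
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Brute-force posterior over copying-state paths of the haploid
# Li-Stephens HMM (enumeration over K^T paths).
brutePosteriorDose <- function(panel, target, switchRate, errorRate) {
  K <- nrow(panel); V <- ncol(panel)
  typed <- which(!is.na(target))
  T <- length(typed)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  logw <- apply(paths, 1, function(pth) {
    lp <- -log(K)
    for (t in seq_len(T)) {
      if (t > 1) {
        stay <- pth[t] == pth[t - 1]
        pr <- (1 - switchRate) * stay + switchRate / K
        lp <- lp + log(pr)
      }
      match <- panel[pth[t], typed[t]] == target[typed[t]]
      lp <- lp + log(if (match) 1 - errorRate else errorRate)
    }
    lp
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  # state marginals at each typed site
  gamma <- matrix(0, T, K)
  for (t in seq_len(T))
    for (k in seq_len(K)) gamma[t, k] <- sum(w[paths[, t] == k])
  # doses: typed -> observation; untyped -> nearest typed site's
  # posterior (ties to the left), matching the implementation contract
  dose <- numeric(V)
  for (v in seq_len(V)) {
    if (!is.na(target[v])) { dose[v] <- target[v]; next }
    cand <- typed[order(abs(typed - v), typed)][1]
    t <- match(cand, typed)
    dose[v] <- sum(gamma[t, ] * panel[, v])
  }
  list(gamma = gamma, dose = dose, typed = typed)
}
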