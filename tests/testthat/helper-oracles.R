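# Shared fixtures and independent oracles used across the suite.

treeQuartet <- function() ape::read.tree(
  text = "((a:0.12,b:0.2):0.07,(c:0.15,d:0.1):0.09);")

treeSix <- function() ape::read.tree(
  text = "((a:0.15,b:0.15):0.1,(c:0.15,d:0.15):0.1,(e:0.2,f:0.2):0.1);")

# Exhaustive-enumeration log-likelihood, independent of the pruning path:
# sums over every assignment of states to interior nodes, with transition
# probabilities from Matrix::expm (not the package's eigendecomposition).
# Single rate class; mixtures are averaged by the caller.
enumLogLikOneClass <- function(tree, states, Q, freqs, rate = 1,
                               perSite = FALSE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- states[match(tr$tip.label, rownames(states)), , drop = FALSE]
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  S <- length(freqs)
  Ps <- lapply(tr$edge.length, function(t)
    as.matrix(Matrix::expm(Q * t * rate)))
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), nnode)))
  root <- ntip + 1L
  siteLik <- numeric(ncol(states))
  base <- freqs[combos[, root - ntip]]
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    if (ch > ntip)
      base <- base * Ps[[k]][cbind(combos[, par - ntip], combos[, ch - ntip])]
  }
  tipEdges <- which(tr$edge[, 2] <= ntip)
  for (site in seq_len(ncol(states))) {
    lik <- base
    for (k in tipEdges) {
      par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
      s <- states[ch, site]
      if (!is.na(s)) lik <- lik * Ps[[k]][combos[, par - ntip], s]
    }
    siteLik[site] <- sum(lik)
  }
  if (perSite) log(siteLik) else sum(log(siteLik))
}

randomProteinStates <- function(ntip, nsites, gapProb = 0.05) {
  m <- matrix(sample.int(20, ntip * nsites, replace = TRUE), ntip, nsites)
  m[runif(length(m)) < gapProb] <- NA
  m
}

statesToAlignment <- function(states, tipLabels) {
  chars <- apply(states, 1, function(row) {
    ch <- ponevo:::AA_ALPHABET[row]
    ch[is.na(ch)] <- "-"
    paste(ch, collapse = "")
  })
  phyloAlignment(setNames(chars, tipLabels), "protein")
}

# brute-force mean pairwise distance for the clustering statistic
bruteMeanPairwise <- function(xyz, idx) {
  d <- as.matrix(dist(xyz))[idx, idx]
  mean(d[upper.tri(d)])
}
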