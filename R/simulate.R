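#' @include sitemodels.R
NULL

# resolve any supported model into simulation classes:
# list(weights, labels, states alphabet, per-class list(eigBg, eigFg, rate))
simulationClasses <- function(model, flavor) {
  if (inherits(model, "AAModel")) {
    qm <- buildRateMatrix(model)
    eig <- eigenReversible(qm$Q, qm$freqs)
    rates <- gammaRates(model)
    p <- model$pInvariant
    k <- length(rates)
    cls <- lapply(rates / (1 - p), function(r)
      list(eigBg = eig, eigFg = NULL, rate = r))
    weights <- rep((1 - p) / k, k)
    labels <- paste0("G", seq_len(k))
    if (p > 0) {
      cls <- c(cls, list(list(eigBg = eig, eigFg = NULL, rate = 0)))
      weights <- c(weights, p)
      labels <- c(labels, "invariant")
    }
    list(classes = cls, weights = weights, labels = labels, freqs = qm$freqs)
  } else if (inherits(model, "CodonModel")) {
    qm <- buildRateMatrix(model)
    eig <- eigenReversible(qm$Q, qm$freqs)
    list(classes = list(list(eigBg = eig, eigFg = NULL, rate = 1)),
         weights = 1, labels = "w", freqs = qm$freqs)
  } else if (inherits(model, "SiteClassModel")) {
    classes <- siteClasses(model)
    se <- siteClassEigens(model, classes)
    cls <- lapply(seq_len(nrow(classes)), function(i) {
      bg <- se$eigs[[as.character(classes$omegaBg[i])]]
      fg <- if (classes$omegaFg[i] != classes$omegaBg[i])
        se$eigs[[as.character(classes$omegaFg[i])]] else NULL
      list(eigBg = bg, eigFg = fg, rate = 1 / se$scale)
    })
    list(classes = cls, weights = classes$weight, labels = classes$label,
         freqs = model$freqs)
  } else stop("unsupported model for simulation")
}

#' Simulate an alignment along a tree
#'
#' Samples root states from the model's stationary frequencies and evolves
#' them along each branch using the exact transition probabilities
#' `exp(Q t)` of the same scaled rate matrices the likelihood engine uses,
#' so simulation and inference share one substitution process. For mixture
#' models each site's latent class (and rate category) is drawn first and
#' recorded in a truth table; for branch-site models the foreground classes
#' switch omega on the marked branches.
#'
#' @param tree `phylo` with branch lengths (and foreground marks for
#'   branch-site models).
#' @param model `AAModel`, `CodonModel` or `SiteClassModel`.
#' @param nSites number of sites (codons for codon models), >= 1.
#' @param seed integer seed; identical inputs give identical output.
#' @return a [PhyloAlignment-class]; `attr(, "truth")` is a data.frame with
#'   one row per site giving the latent class label.
#' @export
simulateAlignment <- function(tree, model, nSites, seed) {
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree needs non-negative branch lengths")
  nSites <- as.integer(nSites)
  if (nSites < 1) stop("nSites must be >= 1")
  flavor <- if (inherits(model, "AAModel")) "protein" else "codon"
  sim <- simulationClasses(model, flavor)
  needsFg <- any(vapply(sim$classes, function(c) !is.null(c$eigFg),
                        logical(1)))
  fg <- foregroundEdges(tree)
  if (needsFg && !any(fg))
    stop("branch-site simulation requires foreground marks on the tree")
  tr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  fg <- fg[ord]
  ntip <- length(tr$tip.label)
  nnodes <- ntip + tr$Nnode
  S <- length(sim$freqs)
  alphabet <- names(sim$freqs)
  withStream(seed, "alignment", {
    classOf <- sample.int(length(sim$weights), nSites, replace = TRUE,
                          prob = sim$weights)
    states <- matrix(NA_integer_, ntip, nSites)
    for (ci in seq_along(sim$classes)) {
      idx <- which(classOf == ci)
      if (!length(idx)) next
      cl <- sim$classes[[ci]]
      node <- matrix(NA_integer_, nnodes, length(idx))
      node[ntip + 1L, ] <- sample.int(S, length(idx), replace = TRUE,
                                      prob = sim$freqs)
      for (k in seq_len(nrow(tr$edge))) {
        par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
        t <- tr$edge.length[k] * cl$rate
        if (t == 0) { node[ch, ] <- node[par, ]; next }
        eig <- if (!is.null(cl$eigFg) && fg[k]) cl$eigFg else cl$eigBg
        P <- probMatrix(eig, t)
        P <- P / rowSums(P)
        from <- node[par, ]
        out <- integer(length(from))
        for (s in unique(from)) {
          w <- which(from == s)
          out[w] <- sample.int(S, length(w), replace = TRUE, prob = P[s, ])
        }
        node[ch, ] <- out
      }
      states[, idx] <- node[seq_len(ntip), , drop = FALSE]
    }
    aln <- new("PhyloAlignment", seqNames = tr$tip.label, states = states,
               alphabet = alphabet, flavor = flavor)
    attr(aln, "truth") <- data.frame(site = seq_len(nSites),
                                     class = sim$labels[classOf])
    aln
  })
}
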