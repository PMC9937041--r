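#' @include ratematrix.R alignment.R trees.R
NULL

# Preprocess an (alignment, tree) pair for pruning: site-pattern compression,
# postorder edge traversal, tip states aligned to tip indices.
prepLikelihood <- function(aln, tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (!setequal(tree$tip.label, aln@seqNames))
    stop("tree leaf names and alignment names differ")
  tree2 <- ape::reorder.phylo(tree, "postorder")
  # carry foreground marks through the reordering by matching edge child ids
  fg <- foregroundEdges(tree)
  ord <- match(paste(tree2$edge[, 1], tree2$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  fg <- fg[ord]
  comp <- compressPatterns(aln@states[match(tree2$tip.label, aln@seqNames), ,
                                      drop = FALSE])
  list(tree = tree2, ntip = length(tree2$tip.label),
       nnode = tree2$Nnode, root = length(tree2$tip.label) + 1L,
       edges = tree2$edge, lens = tree2$edge.length, foreground = fg,
       tipStates = comp$states, patW = comp$weights, map = comp$map,
       nStates = length(aln@alphabet), freqsNames = aln@alphabet)
}

# per-pattern likelihood for one mixture class given per-edge P matrices,
# reusing edge messages shared between classes of one mixture evaluation.
# `keys` labels each edge with the identity of its transition process (e.g.
# the omega in force); edges whose entire subtree carries identical labels
# across two classes contribute identical messages, which `cacheEnv` dedups.
classSiteLikShared <- function(prep, Ps, rootFreqs, keys, cacheEnv) {
  S <- prep$nStates
  npat <- ncol(prep$tipStates)
  nn <- prep$ntip + prep$nnode
  partial <- vector("list", nn)
  sig <- character(nn)
  edges <- prep$edges
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    msgKey <- if (ch <= prep$ntip) paste0(k, ":", keys[k])
              else paste0(k, ":", keys[k], "{", sig[ch], "}")
    M <- cacheEnv[[msgKey]]
    if (is.null(M)) {
      P <- Ps[[k]]
      if (ch <= prep$ntip) {
        st <- prep$tipStates[ch, ]
        if (!anyNA(st)) {
          M <- P[, st, drop = FALSE]
        } else {
          M <- matrix(1, S, npat)
          ok <- which(!is.na(st))
          if (length(ok)) M[, ok] <- P[, st[ok]]
        }
      } else {
        M <- P %*% partial[[ch]]
      }
      cacheEnv[[msgKey]] <- M
    }
    sig[par] <- paste0(sig[par], "(", msgKey, ")")
    partial[[par]] <- if (is.null(partial[[par]])) M else partial[[par]] * M
  }
  as.vector(rootFreqs %*% partial[[prep$root]])
}

# per-pattern likelihood for one mixture class given per-edge P matrices
classSiteLik <- function(prep, Ps, rootFreqs) {
  S <- prep$nStates
  npat <- ncol(prep$tipStates)
  partial <- vector("list", prep$ntip + prep$nnode)
  edges <- prep$edges
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]
    P <- Ps[[k]]
    if (ch <= prep$ntip) {
      st <- prep$tipStates[ch, ]
      if (!anyNA(st)) {
        M <- P[, st, drop = FALSE]
      } else {
        M <- matrix(1, S, npat)
        ok <- which(!is.na(st))
        if (length(ok)) M[, ok] <- P[, st[ok]]
      }
    } else {
      M <- P %*% partial[[ch]]
    }
    partial[[par]] <- if (is.null(partial[[par]])) M else partial[[par]] * M
  }
  as.vector(rootFreqs %*% partial[[prep$root]])
}

# per-pattern likelihood of the invariant-sites class: pi_s if the pattern is
# constant at state s (gaps ignored), 1 if all-gap, else 0
invariantSiteLik <- function(prep, freqs) {
  apply(prep$tipStates, 2, function(col) {
    st <- unique(col[!is.na(col)])
    if (length(st) == 0) 1
    else if (length(st) == 1) freqs[st]
    else 0
  })
}

# assemble per-edge P matrices for one class; eig or (eigBg, eigFg) with the
# prep's foreground flags; rate is a scalar multiplier on branch lengths
classPs <- function(prep, eig, rate = 1, eigFg = NULL) {
  lapply(seq_along(prep$lens), function(k) {
    e <- if (!is.null(eigFg) && prep$foreground[k]) eigFg else eig
    probMatrix(e, prep$lens[k] * rate)
  })
}

# mixture classes -> list(logLik per pattern, per-pattern class likelihood
# matrix). Each class: list(weight, lik = npat vector)
mixtureFromClassLiks <- function(prep, liks, weights) {
  L <- do.call(cbind, liks)
  tot <- as.vector(L %*% weights)
  list(patLik = tot, L = L, weights = weights)
}

# expand per-pattern quantities to per-site using the compression map
expandPatterns <- function(x, prep) x[prep$map]

# build the mixture class list for a plain model (AAModel or CodonModel)
modelClasses <- function(model, prep) {
  if (inherits(model, "AAModel")) {
    qm <- buildRateMatrix(model)
    eig <- eigenReversible(qm$Q, qm$freqs)
    rates <- gammaRates(model)
    p <- model$pInvariant
    k <- length(rates)
    liks <- lapply(rates, function(r)
      classSiteLik(prep, classPs(prep, eig, r / (1 - p)), qm$freqs))
    weights <- rep((1 - p) / k, k)
    labels <- paste0("G", seq_len(k))
    if (p > 0) {
      liks <- c(liks, list(invariantSiteLik(prep, qm$freqs)))
      weights <- c(weights, p)
      labels <- c(labels, "invariant")
    }
    list(liks = liks, weights = weights, labels = labels, freqs = qm$freqs)
  } else if (inherits(model, "CodonModel")) {
    qm <- buildRateMatrix(model)
    eig <- eigenReversible(qm$Q, qm$freqs)
    list(liks = list(classSiteLik(prep, classPs(prep, eig), qm$freqs)),
         weights = 1, labels = "M0", freqs = qm$freqs)
  } else stop("unsupported model")
}

#' Exact pruning log-likelihood of an alignment on a fixed tree
#'
#' Computes the phylogenetic log-likelihood by Felsenstein pruning with
#' site-pattern compression. Gaps and ambiguous states are missing data.
#' Rate mixtures (discrete Gamma, invariant sites; site-class mixtures for
#' codon models) are averaged per site.
#'
#' @param aln a [PhyloAlignment-class].
#' @param tree `phylo` with branch lengths in expected substitutions per site.
#' @param model an `AAModel`, `CodonModel` or `SiteClassModel`.
#' @return a [ModelFit-class] with per-site log-likelihoods and, for mixture
#'   models, per-site class posterior probabilities.
#' @export
treeLogLikelihood <- function(aln, tree, model) {
  if (inherits(model, "SiteClassModel"))
    return(siteClassLogLikelihood(aln, tree, model))
  prep <- prepLikelihood(aln, tree)
  cls <- modelClasses(model, prep)
  mix <- mixtureFromClassLiks(prep, cls$liks, cls$weights)
  finishFit(prep, mix, cls$labels, tree, model,
            parameters = modelParameterList(model))
}

modelParameterList <- function(model) {
  if (inherits(model, "AAModel"))
    list(model = model$name, gammaShape = model$gammaShape,
         pInvariant = model$pInvariant)
  else if (inherits(model, "CodonModel"))
    list(kappa = model$kappa, omega = model$omega)
  else list()
}

finishFit <- function(prep, mix, labels, tree, model, parameters,
                      diagnostics = list()) {
  patLL <- log(mix$patLik)
  siteLL <- expandPatterns(patLL, prep)
  post <- mix$L * rep(mix$weights, each = nrow(mix$L))
  post <- post / rowSums(post)
  post <- post[prep$map, , drop = FALSE]
  colnames(post) <- labels
  new("ModelFit", logLik = sum(patLL * prep$patW), siteLogLik = siteLL,
      parameters = parameters, posteriors = post, tree = tree, model = model,
      diagnostics = diagnostics)
}
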