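#' @include selection.R
NULL

# per-pattern likelihood for a single omega class at fixed kappa, freqs,
# branch lengths and mixture scale; optionally a different foreground omega
omegaPatLik <- function(prep, kappa, freqs, omegaBg, omegaFg = NULL,
                        rate = 1) {
  Qb <- codonRateMatrix(kappa, omegaBg, freqs, scale = FALSE)$Q
  eb <- eigenReversible(Qb, freqs)
  ef <- NULL
  if (!is.null(omegaFg) && omegaFg != omegaBg) {
    Qf <- codonRateMatrix(kappa, omegaFg, freqs, scale = FALSE)$Q
    ef <- eigenReversible(Qf, freqs)
  }
  classSiteLik(prep, classPs(prep, eb, rate, eigFg = ef), freqs)
}

# grids used by the empirical-Bayes integration: equally spaced bin
# midpoints, uniform prior mass
bebGrid <- function(n = 10L) (seq_len(n) - 0.5) / n

#' Identify positively selected sites (NEB or BEB)
#'
#' Naive empirical Bayes (NEB) applies Bayes' rule to the per-site class
#' likelihoods at the maximum-likelihood estimates. Bayes empirical Bayes
#' (BEB) additionally averages the posterior over a discrete uniform prior
#' grid on the class-proportion and omega parameters (10 points per
#' dimension by default), which accounts for their sampling error. Sites
#' whose posterior probability of belonging to the positive-selection
#' class(es) exceeds `threshold` are flagged.
#'
#' @param fit a [ModelFit-class] from [fitSiteModel()] (M2a or M8) or
#'   [fitBranchSite()] (alternative model).
#' @param threshold posterior probability cutoff in (0, 1); default 0.5.
#' @param method `"BEB"` (default) or `"NEB"`.
#' @param gridPoints prior grid resolution per dimension for BEB.
#' @return data.frame with `site`, `posterior` (probability of the
#'   selection class(es)) and `selected`.
#' @export
identifySelectedSites <- function(fit, threshold = 0.5,
                                  method = c("BEB", "NEB"),
                                  gridPoints = 10L) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  model <- fit@model
  if (!inherits(model, "SiteClassModel") ||
      !model$family %in% c("M2a", "M8", "BranchSiteA"))
    stop("fit must expose a positive-selection class (M2a, M8 or ",
         "branch-site alternative)")
  if (method == "NEB") {
    selCols <- switch(model$family, M2a = "w2", M8 = "ws",
                      BranchSiteA = c("2a", "2b"))
    post <- rowSums(fit@posteriors[, selCols, drop = FALSE])
  } else {
    post <- bebPosterior(fit, gridPoints)
  }
  data.frame(site = seq_along(post), posterior = unname(post),
             selected = unname(post) > threshold)
}

bebPosterior <- function(fit, d = 10L) {
  model <- fit@model
  prep <- prepLikelihood(bebAlignmentFromFit(fit), fit@tree)
  classes <- siteClasses(model)
  se <- siteClassEigens(model, classes)
  rate <- 1 / se$scale
  kappa <- model$kappa
  freqs <- model$freqs
  grid <- bebGrid(d)
  w0Grid <- grid                 # omega0 in (0, 1)
  w2Grid <- 1 + 10 * grid        # omega2 in (1, 11)
  patW <- prep$patW
  map <- prep$map
  if (model$family == "M2a") {
    f0 <- vapply(w0Grid, function(w)
      omegaPatLik(prep, kappa, freqs, w, rate = rate), numeric(length(patW)))
    f1 <- omegaPatLik(prep, kappa, freqs, 1, rate = rate)
    f2 <- vapply(w2Grid, function(w)
      omegaPatLik(prep, kappa, freqs, w, rate = rate), numeric(length(patW)))
    props <- expand.grid(p0 = grid, p1 = grid)
    props <- props[props$p0 + props$p1 <= 1, ]
    acc <- bebAccumulate(
      propRows = cbind(props$p0, props$p1, 1 - props$p0 - props$p1),
      likSets = list(f0, list(f1), f2),
      setIndexGrids = expand.grid(i0 = seq_len(d), i2 = seq_len(d)),
      selClass = 3L, patW = patW)
  } else if (model$family == "M8") {
    # beta shapes held at their MLEs; integrate over p0 and omega_s
    betaOm <- discretizeBeta(model$p, model$q, model$kBeta)
    fBeta <- vapply(betaOm, function(w)
      omegaPatLik(prep, kappa, freqs, w, rate = rate), numeric(length(patW)))
    fBetaMean <- rowMeans(fBeta)
    fS <- vapply(w2Grid, function(w)
      omegaPatLik(prep, kappa, freqs, w, rate = rate), numeric(length(patW)))
    props <- data.frame(p0 = grid)
    acc <- bebAccumulate(
      propRows = cbind(props$p0, 1 - props$p0),
      likSets = list(list(fBetaMean), fS),
      setIndexGrids = expand.grid(iS = seq_len(d)),
      selClass = 2L, patW = patW)
  } else {
    fg <- any(foregroundEdges(fit@tree))
    if (!fg) stop("branch-site BEB requires foreground marks")
    f0 <- vapply(w0Grid, function(w)
      omegaPatLik(prep, kappa, freqs, w, rate = rate), numeric(length(patW)))
    f1 <- omegaPatLik(prep, kappa, freqs, 1, rate = rate)
    f2a <- array(NA_real_, c(length(patW), d, d))
    for (i in seq_len(d)) for (j in seq_len(d))
      f2a[, i, j] <- omegaPatLik(prep, kappa, freqs, w0Grid[i],
                                 omegaFg = w2Grid[j], rate = rate)
    f2b <- vapply(w2Grid, function(w)
      omegaPatLik(prep, kappa, freqs, 1, omegaFg = w, rate = rate),
      numeric(length(patW)))
    props <- expand.grid(p0 = grid, p1 = grid)
    props <- props[props$p0 + props$p1 <= 1 - 1e-9, ]
    keep <- props$p0 + props$p1 > 0
    props <- props[keep, ]
    rest <- 1 - props$p0 - props$p1
    p2a <- rest * props$p0 / (props$p0 + props$p1)
    p2b <- rest * props$p1 / (props$p0 + props$p1)
    # accumulate over the (w0, w2) grid explicitly
    npat <- length(patW)
    logPost <- matrix(-Inf, nrow(props), d * d)
    postSel <- numeric(npat)
    norm <- 0
    ll <- vector("list", d * d)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      F <- cbind(f0[, i], f1, f2a[, i, j], f2b[, j])
      idx <- (i - 1) * d + j
      W <- rbind(props$p0, props$p1, p2a, p2b)
      fsite <- F %*% W                   # npat x ngridProp
      lp <- colSums(log(fsite) * patW)
      ll[[idx]] <- list(F = F, fsite = fsite, lp = lp)
      logPost[, idx] <- lp
    }
    m <- max(logPost)
    pw <- exp(logPost - m)
    pw <- pw / sum(pw)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      idx <- (i - 1) * d + j
      e <- ll[[idx]]
      selLik <- outer(e$F[, 3], p2a) + outer(e$F[, 4], p2b)
      postSel <- postSel + as.vector((selLik / e$fsite) %*% pw[, idx])
    }
    return(pmin(1, pmax(0, postSel))[map])
  }
  acc[map]
}

# shared accumulator for mixtures whose selection class is a single column:
# likSets is a list of per-class likelihood sets (matrix columns indexed by
# the grid, or length-1 list for a fixed class)
bebAccumulate <- function(propRows, likSets, setIndexGrids, selClass, patW) {
  npat <- length(patW)
  combos <- setIndexGrids
  nProp <- nrow(propRows)
  nCombo <- nrow(combos)
  lp <- matrix(NA_real_, nProp, nCombo)
  store <- vector("list", nCombo)
  for (ci in seq_len(nCombo)) {
    F <- matrix(NA_real_, npat, length(likSets))
    gi <- 1
    for (s in seq_along(likSets)) {
      set <- likSets[[s]]
      if (is.list(set)) {
        F[, s] <- set[[1]]
      } else {
        F[, s] <- set[, combos[ci, gi]]
        gi <- gi + 1
      }
    }
    fsite <- F %*% t(propRows)          # npat x nProp
    lp[, ci] <- colSums(log(fsite) * patW)
    store[[ci]] <- list(F = F, fsite = fsite)
  }
  m <- max(lp)
  pw <- exp(lp - m); pw <- pw / sum(pw)
  post <- numeric(npat)
  for (ci in seq_len(nCombo)) {
    e <- store[[ci]]
    selLik <- outer(e$F[, selClass], propRows[, selClass])
    post <- post + as.vector((selLik / e$fsite) %*% pw[, ci])
  }
  pmin(1, pmax(0, post))
}

#' Assemble a positive-selection report from a nested model pair
#'
#' Runs the appropriate likelihood-ratio test (site-model pairs with df = 2,
#' branch-site pairs with df = 1), computes NEB and BEB site posteriors
#' under the alternative model, and packages everything as a
#' [SelectionReport-class]. Selection calls use the BEB posteriors, with
#' NEB retained alongside.
#'
#' @param nullFit,altFit the nested [ModelFit-class] pair.
#' @param threshold posterior cutoff for calling a site selected.
#' @return a [SelectionReport-class].
#' @export
selectionReport <- function(nullFit, altFit, threshold = 0.5) {
  lrt <- if (identical(altFit@model$family, "BranchSiteA"))
    branchSiteLrt(nullFit, altFit)
  else siteModelLrt(nullFit, altFit)
  neb <- identifySelectedSites(altFit, threshold, "NEB")
  beb <- identifySelectedSites(altFit, threshold, "BEB")
  sites <- data.frame(site = neb$site, nebPosterior = neb$posterior,
                      bebPosterior = beb$posterior,
                      selected = beb$selected)
  prop <- altFit@parameters$proportionSelected
  if (is.null(prop)) {
    cls <- siteClasses(altFit@model)
    sel <- switch(altFit@model$family, M2a = "w2", M8 = "ws",
                  BranchSiteA = c("2a", "2b"))
    prop <- sum(cls$weight[cls$label %in% sel])
  }
  new("SelectionReport", nullFit = nullFit, altFit = altFit, lrt = lrt,
      sites = sites, proportionSelected = prop)
}

# the alignment is not stored in a ModelFit; rebuild the pruning context
# from the tree and the model requires it, so fits carry the alignment in
# diagnostics when produced by the site-model fitters
bebAlignmentFromFit <- function(fit) {
  aln <- fit@diagnostics$alignment
  if (is.null(aln))
    stop("fit does not carry its alignment; refit with the package fitters")
  aln
}
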