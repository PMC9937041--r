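#' @include sitemodels.R
NULL

# fast total log-likelihood of a SiteClassModel on a prepared context
siteClassTotalLogLik <- function(prep, model, cache = NULL) {
  sl <- siteClassLikList(prep, model, cache)
  tot <- as.vector(do.call(cbind, sl$liks) %*% sl$classes$weight)
  sum(log(tot) * prep$patW)
}

# parameter blocks per family: name, lower, upper and one row of inits per
# deterministic restart (multimodal surfaces get three, per the known
# M2a/M8 pathology)
siteFamilySpec <- function(family) {
  switch(family,
    M0 = list(names = c("kappa", "omega"),
              lower = c(0.05, 1e-6), upper = c(100, 50),
              inits = rbind(c(2, 0.5))),
    M1a = list(names = c("kappa", "p0", "omega0"),
               lower = c(0.05, 1e-4, 1e-4), upper = c(100, 0.9999, 0.9999),
               inits = rbind(c(2, 0.7, 0.5))),
    M2a = list(names = c("kappa", "s1", "s2", "omega0", "omega2"),
               lower = c(0.05, 1e-4, 1e-4, 1e-4, 1),
               upper = c(100, 0.9999, 0.9999, 0.9999, 50),
               inits = rbind(c(2, 0.7, 0.8, 0.5, 1.5),
                             c(2, 0.6, 0.7, 0.2, 4),
                             c(2, 0.8, 0.9, 0.8, 10))),
    M7 = list(names = c("kappa", "p", "q"),
              lower = c(0.05, 0.05, 0.05), upper = c(100, 99, 99),
              inits = rbind(c(2, 1, 1))),
    M8 = list(names = c("kappa", "p0", "p", "q", "omegaS"),
              lower = c(0.05, 1e-4, 0.05, 0.05, 1),
              upper = c(100, 0.9999, 99, 99, 50),
              inits = rbind(c(2, 0.9, 1, 1, 1.5),
                            c(2, 0.7, 0.5, 1.5, 4),
                            c(2, 0.95, 2, 2, 10))),
    BranchSiteA = list(names = c("kappa", "s1", "s2", "omega0", "omega2"),
                       lower = c(0.05, 1e-4, 1e-4, 1e-4, 1),
                       upper = c(100, 0.9999, 0.9999, 0.9999, 50),
                       # first start mirrors the conventional kappa = 2,
                       # omega = 1 initialization; the others step off the
                       # omega2 = 1 boundary, where the surface is flat
                       inits = rbind(c(2, 0.7, 0.8, 0.5, 1),
                                     c(2, 0.75, 0.67, 0.2, 4),
                                     c(2, 0.9, 0.5, 0.5, 10))),
    BranchSiteA_null = list(names = c("kappa", "s1", "s2", "omega0"),
                            lower = c(0.05, 1e-4, 1e-4, 1e-4),
                            upper = c(100, 0.9999, 0.9999, 0.9999),
                            inits = rbind(c(2, 0.7, 0.8, 0.5),
                                          c(2, 0.75, 0.67, 0.2))),
    stop("unknown family ", family))
}

buildSiteModel <- function(family, par, names, freqs, kBeta) {
  v <- setNames(as.list(par), names)
  # stick-breaking (s1, s2) -> simplex (p0, p1, rest)
  if (!is.null(v$s1)) { v$p0 <- v$s1; v$p1 <- (1 - v$s1) * v$s2 }
  siteClassModel(family, kappa = v$kappa, frequencies = freqs,
                 p0 = v$p0 %||% NA, p1 = v$p1 %||% NA,
                 omega0 = v$omega0 %||% NA, omega2 = v$omega2 %||% NA,
                 omega = v$omega %||% NA, p = v$p %||% NA, q = v$q %||% NA,
                 omegaS = v$omegaS %||% NA, kBeta = kBeta)
}

resolveCodonFreqs <- function(aln, frequencies) {
  if (is.character(frequencies) && length(frequencies) == 1 &&
      frequencies %in% c("F3x4", "F1x4", "F61"))
    codonFrequencies(aln, frequencies)
  else if (identical(frequencies, "equal"))
    setNames(rep(1 / 61, 61), senseCodons())
  else frequencies
}

fitSiteClassFamily <- function(aln, tree, family, frequencies, kBeta,
                               branchLengths, control, extraInits = NULL) {
  stopifnot(aln@flavor == "codon")
  freqs <- resolveCodonFreqs(aln, frequencies)
  needsFg <- family %in% c("BranchSiteA", "BranchSiteA_null")
  if (needsFg && !any(foregroundEdges(tree)))
    stop("branch-site model requires at least one foreground branch mark")
  workTree <- tree
  if (identical(branchLengths, "m0")) {
    m0 <- fitModel(aln, tree, codonModel(2, 0.5, freqs),
                   free = c("kappa", "omega"))
    workTree <- m0@tree
    attr(workTree, "foreground") <- attr(tree, "foreground")
  }
  prep <- prepLikelihood(aln, workTree)
  spec <- siteFamilySpec(family)
  if (!is.null(extraInits)) spec$inits <- rbind(extraInits)
  nb <- if (identical(branchLengths, "optimize")) length(prep$lens) else 0L
  eigCache <- new.env(parent = emptyenv())
  lower <- c(rep(log(BL_MIN), nb), spec$lower)
  upper <- c(rep(log(BL_MAX), nb), spec$upper)
  obj <- function(par) {
    if (nb) prep$lens <- exp(par[seq_len(nb)])
    m <- tryCatch(
      buildSiteModel(family, par[nb + seq_along(spec$names)], spec$names,
                     freqs, kBeta),
      error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- tryCatch(siteClassTotalLogLik(prep, m, eigCache),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  nRestart <- nrow(spec$inits)
  best <- NULL
  for (r in seq_len(nRestart)) {
    init <- c(if (nb) log(pmax(prep$lens, 1e-6)), spec$inits[r, ])
    # with several starts, survey coarsely first and polish only the winner
    ctl <- control
    if (nRestart > 1) {
      ctl$factr <- (control$factr %||% 1e7) * 100
      ctl$iter.max <- min(control$iter.max %||% 300, 80)
    }
    opt <- boundedOptim(init, obj, lower, upper, ctl)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (nRestart > 1) {
    opt <- boundedOptim(best$par, obj, lower, upper, control)
    if (opt$objective > best$objective) opt <- best
  } else opt <- best
  if (nb) {
    prep$lens <- exp(opt$par[seq_len(nb)])
    ord <- match(paste(workTree$edge[, 1], workTree$edge[, 2]),
                 paste(prep$edges[, 1], prep$edges[, 2]))
    workTree$edge.length <- prep$lens[ord]
  }
  mHat <- buildSiteModel(family, opt$par[nb + seq_along(spec$names)],
                         spec$names, freqs, kBeta)
  fit <- siteClassLogLikelihood(aln, workTree, mHat)
  pnames <- spec$names
  est <- opt$par[nb + seq_along(pnames)]
  atBound <- pnames[est <= spec$lower + 1e-6 | est >= spec$upper - 1e-6]
  fit@diagnostics <- list(converged = opt$convergence == 0,
                          iterations = opt$iterations,
                          atBound = atBound,
                          restarts = nrow(spec$inits),
                          branchLengths = branchLengths,
                          alignment = aln)
  fit
}

#' Fit a codon site model (M0, M1a, M2a, M7, M8)
#'
#' Maximum-likelihood fit of a site-class mixture model. All continuous
#' parameters (kappa, class proportions, class omegas or beta shapes) are
#' optimized by bounded quasi-Newton search; M2a and M8 use three
#' deterministic restarts to mitigate the known multimodality of their
#' likelihood surfaces. Per-site class posterior probabilities (naive
#' empirical Bayes, i.e. Bayes rule at the MLEs) are recorded.
#'
#' @param aln codon-flavor [PhyloAlignment-class].
#' @param tree `phylo` with branch lengths.
#' @param family `"M0"`, `"M1a"`, `"M2a"`, `"M7"` or `"M8"`.
#' @param kBeta beta discretization classes for M7/M8 (default 10).
#' @param frequencies `"F3x4"` (default, estimated from the alignment),
#'   `"F1x4"`, `"F61"`, `"equal"`, or an explicit length-61 vector.
#' @param branchLengths `"optimize"` (joint with model parameters), `"m0"`
#'   (fix at an M0 estimate, a fast standard shortcut), or `"fixed"` (use
#'   the tree as given).
#' @param control passed to [stats::nlminb()].
#' @return a [ModelFit-class].
#' @export
fitSiteModel <- function(aln, tree, family = c("M0", "M1a", "M2a", "M7", "M8"),
                         kBeta = 10L, frequencies = "F3x4",
                         branchLengths = c("optimize", "m0", "fixed"),
                         control = list(iter.max = 300, eval.max = 2000)) {
  family <- match.arg(family)
  branchLengths <- match.arg(branchLengths)
  fitSiteClassFamily(aln, tree, family, frequencies, kBeta, branchLengths,
                     control)
}

#' Fit branch-site model A (alternative or null)
#'
#' Four-class branch-site model: sites are purifying (omega0) or neutral on
#' all branches, or switch to omega2 on the foreground branches (classes 2a
#' and 2b). The null fixes omega2 = 1. Initial kappa = 2 and omega2 = 1.
#' The estimated proportion of sites under selection is `p2a + p2b`.
#'
#' @inheritParams fitSiteModel
#' @param tree `phylo` carrying at least one foreground mark (see
#'   [readMarkedTree()] / [markForeground()]).
#' @param null fit the null variant (omega2 fixed at 1).
#' @return a [ModelFit-class]; `fitParameters()` includes
#'   `proportionSelected`.
#' @export
fitBranchSite <- function(aln, tree, null = FALSE, frequencies = "F3x4",
                          branchLengths = c("optimize", "m0", "fixed"),
                          control = list(iter.max = 300, eval.max = 2000)) {
  branchLengths <- match.arg(branchLengths)
  family <- if (null) "BranchSiteA_null" else "BranchSiteA"
  fit <- fitSiteClassFamily(aln, tree, family, frequencies, 10L,
                            branchLengths, control)
  cls <- siteClasses(fit@model)
  fit@parameters$proportionSelected <- sum(cls$weight[cls$label %in%
                                                        c("2a", "2b")])
  fit
}

#' Fit the branch-site null/alternative pair
#'
#' Fits the null (omega2 = 1) first, then warm-starts the alternative from
#' the null solution (once at the omega2 = 1 boundary and twice stepped off
#' it). Because one alternative start coincides with the null optimum, the
#' alternative log-likelihood cannot end below the null's beyond optimizer
#' tolerance, enforcing the nesting invariant by construction.
#'
#' @inheritParams fitBranchSite
#' @return list with `null`, `alt` ([ModelFit-class]) and `lrt`
#'   (see [branchSiteLrt()]).
#' @export
fitBranchSitePair <- function(aln, tree, frequencies = "F3x4",
                              branchLengths = c("optimize", "m0", "fixed"),
                              control = list(iter.max = 300, factr = 1e8)) {
  branchLengths <- match.arg(branchLengths)
  workTree <- tree
  if (branchLengths == "m0") {
    freqs <- resolveCodonFreqs(aln, frequencies)
    m0 <- fitModel(aln, tree, codonModel(2, 0.5, freqs),
                   free = c("kappa", "omega"), control = control)
    workTree <- m0@tree
    attr(workTree, "foreground") <- attr(tree, "foreground")
    branchLengths <- "fixed"
    frequencies <- freqs
  }
  nullFit <- fitSiteClassFamily(aln, workTree, "BranchSiteA_null",
                                frequencies, 10L, branchLengths, control)
  p <- nullFit@model
  s1 <- p$p0
  s2 <- if (p$p0 < 1 - 1e-6) min(p$p1 / (1 - p$p0), 0.9999) else 0.5
  warm <- rbind(c(p$kappa, s1, s2, p$omega0, 1),
                c(p$kappa, s1, s2, p$omega0, 4))
  altFit <- fitSiteClassFamily(aln, workTree, "BranchSiteA", frequencies,
                               10L, branchLengths, control, extraInits = warm)
  for (f in c("nullFit", "altFit")) {
    ff <- get(f)
    cls <- siteClasses(ff@model)
    ff@parameters$proportionSelected <- sum(cls$weight[cls$label %in%
                                                         c("2a", "2b")])
    assign(f, ff)
  }
  list(null = nullFit, alt = altFit, lrt = branchSiteLrt(nullFit, altFit))
}

#' Likelihood-ratio test between nested site models
#'
#' Compares M1a against M2a, or M7 against M8, with df = 2.
#'
#' @param nullFit,altFit [ModelFit-class] objects from [fitSiteModel()].
#' @return list with `statistic` (clamped at 0), `df` and `p`.
#' @export
siteModelLrt <- function(nullFit, altFit) {
  pair <- c(nullFit@model$family, altFit@model$family)
  if (!(identical(pair, c("M1a", "M2a")) || identical(pair, c("M7", "M8"))))
    stop("not a supported nested pair: ", paste(pair, collapse = " vs "))
  lrtPvalue(nullFit@logLik, altFit@logLik, df = 2)
}

#' Likelihood-ratio test for branch-site model A
#'
#' Alternative against the omega2 = 1 null with df = 1 (plain chi-square
#' calibration; the raw statistic is returned so other calibrations can be
#' applied).
#'
#' @param nullFit,altFit [ModelFit-class] objects from [fitBranchSite()].
#' @return list with `statistic`, `df` and `p`.
#' @export
branchSiteLrt <- function(nullFit, altFit) {
  if (!identical(nullFit@model$family, "BranchSiteA_null") ||
      !identical(altFit@model$family, "BranchSiteA"))
    stop("expected a BranchSiteA_null / BranchSiteA pair")
  lrtPvalue(nullFit@logLik, altFit@logLik, df = 1)
}
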