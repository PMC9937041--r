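#' @include optimize.R
NULL

#' Codon site-class mixture model
#'
#' Describes the site-model families used in positive-selection scans:
#' `M0` (one ratio), `M1a` (nearly neutral: omega0 < 1 and omega = 1),
#' `M2a` (adds a class with omega2 > 1), `M7` (beta-distributed omega on
#' (0,1), discretized), `M8` (beta plus a selection class), and branch-site
#' model A (`BranchSiteA`, with null variant fixing omega2 = 1), in which
#' sites in the selection classes have omega2 on the designated foreground
#' branches only.
#'
#' @param family one of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`,
#'   `"BranchSiteA"`, `"BranchSiteA_null"`.
#' @param kappa transition/transversion ratio.
#' @param frequencies length-61 codon frequencies (or `"equal"`).
#' @param p0,p1 class-proportion parameters (meaning depends on family; for
#'   branch-site A the four class proportions are `p0`, `p1`,
#'   `(1-p0-p1) p0/(p0+p1)` and `(1-p0-p1) p1/(p0+p1)`).
#' @param omega0 purifying-class omega in (0, 1).
#' @param omega2 positive-selection omega (>= 1 where present).
#' @param omega single ratio for `M0`.
#' @param p,q beta shape parameters for `M7`/`M8`.
#' @param omegaS selection-class omega for `M8`.
#' @param kBeta number of equal-probability beta discretization classes.
#' @return object of class `SiteClassModel`.
#' @export
siteClassModel <- function(family = c("M0", "M1a", "M2a", "M7", "M8",
                                      "BranchSiteA", "BranchSiteA_null"),
                           kappa = 2, frequencies = "equal",
                           p0 = NA, p1 = NA, omega0 = NA, omega2 = NA,
                           omega = NA, p = NA, q = NA, omegaS = NA,
                           kBeta = 10L) {
  family <- match.arg(family)
  if (kappa <= 0) stop("kappa must be > 0")
  freqs <- if (is.character(frequencies)) {
    stopifnot(identical(frequencies, "equal"))
    setNames(rep(1 / 61, 61), senseCodons())
  } else {
    stopifnot(length(frequencies) == 61, abs(sum(frequencies) - 1) < 1e-9)
    setNames(as.numeric(frequencies), senseCodons())
  }
  m <- structure(list(family = family, kappa = kappa, freqs = freqs,
                      p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2,
                      omega = omega, p = p, q = q, omegaS = omegaS,
                      kBeta = as.integer(kBeta)),
                 class = c("SiteClassModel", "ponevoModel"))
  validateSiteClassModel(m)
  m
}

validateSiteClassModel <- function(m) {
  chkProp <- function(x, nm) if (is.na(x) || x < 0 || x > 1)
    stop(nm, " must be in [0, 1]")
  chk01 <- function(x, nm) if (is.na(x) || x <= 0 || x >= 1)
    stop(nm, " must be in (0, 1)")
  switch(m$family,
    M0 = if (is.na(m$omega) || m$omega < 0) stop("omega must be >= 0"),
    M1a = { chkProp(m$p0, "p0"); chk01(m$omega0, "omega0") },
    M2a = {
      chkProp(m$p0, "p0"); chkProp(m$p1, "p1")
      if (m$p0 + m$p1 > 1 + 1e-9) stop("p0 + p1 must be <= 1")
      chk01(m$omega0, "omega0")
      if (is.na(m$omega2) || m$omega2 < 1) stop("omega2 must be >= 1")
    },
    M7 = if (is.na(m$p) || is.na(m$q) || m$p <= 0 || m$q <= 0)
           stop("beta shapes p, q must be > 0"),
    M8 = {
      chkProp(m$p0, "p0")
      if (is.na(m$p) || is.na(m$q) || m$p <= 0 || m$q <= 0)
        stop("beta shapes p, q must be > 0")
      if (is.na(m$omegaS) || m$omegaS < 1) stop("omegaS must be >= 1")
    },
    BranchSiteA = ,
    BranchSiteA_null = {
      chkProp(m$p0, "p0"); chkProp(m$p1, "p1")
      if (m$p0 + m$p1 > 1 + 1e-9) stop("p0 + p1 must be <= 1")
      if (m$p0 + m$p1 <= 0) stop("p0 + p1 must be > 0")
      chk01(m$omega0, "omega0")
      w2 <- if (m$family == "BranchSiteA_null") 1 else m$omega2
      if (is.na(w2) || w2 < 1) stop("omega2 must be >= 1")
    })
  invisible(m)
}

# equal-probability discretization of Beta(p, q): bin means
discretizeBeta <- function(p, q, k) {
  breaks <- qbeta(seq(0, 1, length.out = k + 1), p, q)
  upper <- pbeta(breaks[-1], p + 1, q)
  lower <- pbeta(breaks[-(k + 1)], p + 1, q)
  k * (upper - lower) * p / (p + q)
}

# resolve a SiteClassModel into concrete classes:
# data.frame(weight, omegaBg, omegaFg, label)
siteClasses <- function(m) {
  w2 <- if (m$family == "BranchSiteA_null") 1 else m$omega2
  switch(m$family,
    M0 = data.frame(weight = 1, omegaBg = m$omega, omegaFg = m$omega,
                    label = "w"),
    M1a = data.frame(weight = c(m$p0, 1 - m$p0),
                     omegaBg = c(m$omega0, 1), omegaFg = c(m$omega0, 1),
                     label = c("w0", "w1")),
    M2a = {
      p2 <- 1 - m$p0 - m$p1
      data.frame(weight = c(m$p0, m$p1, p2),
                 omegaBg = c(m$omega0, 1, m$omega2),
                 omegaFg = c(m$omega0, 1, m$omega2),
                 label = c("w0", "w1", "w2"))
    },
    M7 = {
      om <- discretizeBeta(m$p, m$q, m$kBeta)
      data.frame(weight = rep(1 / m$kBeta, m$kBeta), omegaBg = om,
                 omegaFg = om, label = paste0("beta", seq_len(m$kBeta)))
    },
    M8 = {
      om <- discretizeBeta(m$p, m$q, m$kBeta)
      data.frame(weight = c(rep(m$p0 / m$kBeta, m$kBeta), 1 - m$p0),
                 omegaBg = c(om, m$omegaS), omegaFg = c(om, m$omegaS),
                 label = c(paste0("beta", seq_len(m$kBeta)), "ws"))
    },
    BranchSiteA = ,
    BranchSiteA_null = {
      rest <- 1 - m$p0 - m$p1
      p2a <- rest * m$p0 / (m$p0 + m$p1)
      p2b <- rest * m$p1 / (m$p0 + m$p1)
      data.frame(weight = c(m$p0, m$p1, p2a, p2b),
                 omegaBg = c(m$omega0, 1, m$omega0, 1),
                 omegaFg = c(m$omega0, 1, w2, w2),
                 label = c("0", "1", "2a", "2b"))
    })
}

# eigen systems for every distinct omega of a class table, unscaled; the
# common mixture mean rate (computed with background omegas, i.e. the rate
# that applies on all but the foreground branches) is returned as `scale`
# and applied as a branch-length multiplier. Eigen systems depend only on
# (kappa, omega) and can be memoized across optimizer evaluations through
# `cache`.
siteClassEigens <- function(m, classes, cache = NULL) {
  omAll <- unique(c(classes$omegaBg, classes$omegaFg))
  eigs <- list()
  for (w in omAll) {
    key <- sprintf("%.15g|%.15g", m$kappa, w)
    e <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(e)) {
      Q <- codonRateMatrix(m$kappa, w, m$freqs, scale = FALSE)$Q
      e <- eigenReversible(Q, m$freqs)
      e$mu <- -sum(m$freqs * diag(Q))
      if (!is.null(cache)) cache[[key]] <- e
    }
    eigs[[as.character(w)]] <- e
  }
  mu <- vapply(as.character(classes$omegaBg), function(w) eigs[[w]]$mu,
               numeric(1))
  s <- sum(classes$weight * mu)
  if (s <= 0) stop("degenerate mixture (zero mean rate)")
  list(eigs = eigs, scale = s)
}

# per-class per-pattern likelihoods, sharing transition matrices between
# classes that use the same omega on the same branches
siteClassLikList <- function(prep, model, cache = NULL) {
  classes <- siteClasses(model)
  if (any(classes$omegaBg != classes$omegaFg) && !any(prep$foreground))
    stop("branch-site model requires at least one foreground branch mark")
  se <- siteClassEigens(model, classes, cache)
  rate <- 1 / se$scale
  fgIdx <- which(prep$foreground)
  PbyOmega <- list()
  for (w in unique(as.character(classes$omegaBg)))
    PbyOmega[[w]] <- lapply(prep$lens, function(t)
      probMatrix(se$eigs[[w]], t * rate))
  PfgByOmega <- list()
  needFg <- unique(as.character(classes$omegaFg[classes$omegaFg !=
                                                  classes$omegaBg]))
  for (w in needFg) {
    Pw <- vector("list", length(prep$lens))
    for (k in fgIdx) Pw[[k]] <- probMatrix(se$eigs[[w]], prep$lens[k] * rate)
    PfgByOmega[[w]] <- Pw
  }
  msgCache <- new.env(parent = emptyenv())
  liks <- lapply(seq_len(nrow(classes)), function(i) {
    wb <- as.character(classes$omegaBg[i])
    wf <- as.character(classes$omegaFg[i])
    Ps <- PbyOmega[[wb]]
    keys <- rep(wb, length(Ps))
    if (classes$omegaFg[i] != classes$omegaBg[i]) {
      Ps[fgIdx] <- PfgByOmega[[wf]][fgIdx]
      keys[fgIdx] <- wf
    }
    classSiteLikShared(prep, Ps, model$freqs, keys, msgCache)
  })
  list(classes = classes, liks = liks)
}

siteClassLogLikelihood <- function(aln, tree, model) {
  stopifnot(aln@flavor == "codon")
  prep <- prepLikelihood(aln, tree)
  sl <- siteClassLikList(prep, model)
  mix <- mixtureFromClassLiks(prep, sl$liks, sl$classes$weight)
  finishFit(prep, mix, sl$classes$label, tree, model,
            parameters = siteClassParamList(model))
}

siteClassParamList <- function(m) {
  keep <- c("family", "kappa", "p0", "p1", "omega0", "omega2", "omega",
            "p", "q", "omegaS")
  out <- m[keep]
  out[!vapply(out, function(x) length(x) == 1 && is.na(x), logical(1))]
}
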