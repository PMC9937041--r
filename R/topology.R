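#' @include optimize.R
NULL

#' Likelihood-ratio test p-value
#'
#' Computes `max(0, 2 (logL1 - logL0))` and its upper-tail chi-square
#' probability. This is also the calibration applied to the constrained
#' duplication-topology contrasts (df = 1), mirroring the convention used
#' to compare fixed gene-family tree models.
#'
#' @param logL0 log-likelihood of the worse/null model.
#' @param logL1 log-likelihood of the better/alternative model.
#' @param df chi-square degrees of freedom (>= 1).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrtPvalue <- function(logL0, logL1, df = 1) {
  if (df < 1) stop("df must be >= 1")
  stat <- max(0, 2 * (logL1 - logL0))
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Compare fixed candidate topologies by maximized likelihood
#'
#' Optimizes branch lengths and the requested free model parameters
#' independently on each candidate topology, ranks the topologies by
#' log-likelihood, and reports likelihood-ratio records for every ordered
#' pair with df = 1 (the convention for these fixed-topology contrasts;
#' the raw statistic is always included so other calibrations can be
#' applied).
#'
#' @param aln a [PhyloAlignment-class].
#' @param trees named list of `phylo` candidates spanning the same leaf set
#'   as `aln`.
#' @param model substitution model for the fits.
#' @param free free model parameters, passed to [fitModel()].
#' @return list with `fits` (per-tree [ModelFit-class]), `logLik` (named
#'   vector), `best` (label), and `pairs` (data.frame of pairwise LRTs).
#' @export
compareFixedTopologies <- function(aln, trees, model, free = character(0)) {
  if (length(trees) < 2) stop("need at least 2 candidate topologies")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  for (nm in names(trees))
    if (!setequal(trees[[nm]]$tip.label, aln@seqNames))
      stop("tree '", nm, "' does not span the alignment's sequences")
  fits <- lapply(trees, function(tr) fitModel(aln, tr, model, free = free))
  ll <- vapply(fits, function(f) f@logLik, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  pairs <- do.call(rbind, lapply(seq_along(fits), function(i) {
    do.call(rbind, lapply(seq_along(fits), function(j) {
      if (i == j) return(NULL)
      r <- lrtPvalue(ll[i], ll[j], df = 1)
      data.frame(null = names(trees)[i], alt = names(trees)[j],
                 delta = ll[j] - ll[i], statistic = r$statistic, df = r$df,
                 p = r$p)
    }))
  }))
  list(fits = fits, logLik = ll, best = names(trees)[ord[1]],
       ranking = names(trees)[ord], pairs = pairs)
}

#' Select among fitted models by AIC
#'
#' `AIC = 2 k - 2 logL`; ties are broken by fewer parameters, then label
#' order.
#'
#' @param fits data.frame-like input with one entry per model: a list of
#'   lists with `label`, `logLik`, `nFreeParams`.
#' @return data.frame ranked by ascending AIC; the first row is selected.
#' @export
aicSelect <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(label = f$label, logLik = f$logLik, k = f$nFreeParams)))
  tab$aic <- 2 * tab$k - 2 * tab$logLik
  tab <- tab[order(tab$aic, tab$k, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
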