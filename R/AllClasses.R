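#' @include ponevo-package.R
NULL

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# 61 sense codons of the standard code, alphabetical, fixed at load time
senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  cod <- sort(names(gc))
  cod[gc[cod] != "*"]
}

#' Aligned sequence matrix (protein or in-frame codon flavor)
#'
#' Thin container for a multiple sequence alignment used by the likelihood
#' machinery. Sequences are stored as integer state indices into a fixed
#' alphabet (20 amino acids or the 61 sense codons of the standard code);
#' gaps and ambiguous residues are `NA` and are treated as missing data.
#'
#' @slot seqNames character, unique sequence identifiers.
#' @slot states integer matrix, one row per sequence, one column per site
#'   (alignment column for protein, codon for codon flavor).
#' @slot alphabet character vector of state labels.
#' @slot flavor `"protein"` or `"codon"`.
#' @exportClass PhyloAlignment
setClass("PhyloAlignment",
  representation(seqNames = "character", states = "matrix",
                 alphabet = "character", flavor = "character"))

setValidity("PhyloAlignment", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@seqNames)) msg <- c(msg, "sequence names must be unique")
  if (nrow(object@states) != length(object@seqNames))
    msg <- c(msg, "one row of states per sequence required")
  if (ncol(object@states) < 1) msg <- c(msg, "alignment has zero sites")
  if (!object@flavor %in% c("protein", "codon"))
    msg <- c(msg, "flavor must be 'protein' or 'codon'")
  st <- object@states[!is.na(object@states)]
  if (length(st) && (min(st) < 1 || max(st) > length(object@alphabet)))
    msg <- c(msg, "state index outside alphabet")
  if (length(msg)) msg else TRUE
})

#' Result of a likelihood computation or model fit
#'
#' Returned by [treeLogLikelihood()], [fitModel()], [fitSiteModel()] and
#' [fitBranchSite()]. The total log-likelihood always equals the sum of the
#' per-site values.
#'
#' @slot logLik total log-likelihood.
#' @slot siteLogLik numeric, per-site (not per-pattern) log-likelihoods.
#' @slot parameters named list of model parameter values at the reported point.
#' @slot posteriors matrix of per-site class posterior probabilities
#'   (sites x classes) for mixture models, else a 0 x 0 matrix.
#' @slot tree the `phylo` tree used (branch lengths as optimized, if they were).
#' @slot model the model object the fit was computed under.
#' @slot diagnostics list: optimizer iterations, convergence flag, notes.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(logLik = "numeric", siteLogLik = "numeric",
                 parameters = "list", posteriors = "matrix",
                 tree = "ANY", model = "ANY", diagnostics = "list"))

setValidity("ModelFit", function(object) {
  if (length(object@siteLogLik) &&
      abs(object@logLik - sum(object@siteLogLik)) > 1e-6 * max(1, abs(object@logLik)))
    return("logLik does not equal the sum of per-site log-likelihoods")
  if (nrow(object@posteriors) > 0) {
    s <- rowSums(object@posteriors)
    if (any(abs(s - 1) > 1e-6)) return("class posteriors must sum to 1 per site")
  }
  TRUE
})

#' Positive-selection test report
#'
#' @slot nullFit,altFit `ModelFit` objects for the nested pair.
#' @slot lrt list with `statistic`, `df`, `p`.
#' @slot sites data.frame of per-site posteriors and selected flags.
#' @slot proportionSelected estimated proportion of sites in the
#'   positive-selection class(es) under the alternative model.
#' @exportClass SelectionReport
setClass("SelectionReport",
  representation(nullFit = "ModelFit", altFit = "ModelFit", lrt = "list",
                 sites = "data.frame", proportionSelected = "numeric"))

#' Spatial clustering permutation-test result
#'
#' @slot observed observed statistic (mean pairwise C-alpha distance, Angstrom).
#' @slot nPerm number of permutations N.
#' @slot nAsExtreme count b of permutations with statistic <= observed.
#' @slot p permutation p-value, (b + 1) / (N + 1).
#' @slot seed RNG seed used.
#' @slot statistic name of the clustering statistic used.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(observed = "numeric", nPerm = "numeric",
                 nAsExtreme = "numeric", p = "numeric", seed = "numeric",
                 statistic = "character"))

setValidity("ClusterTestResult", function(object) {
  lo <- 1 / (object@nPerm + 1)
  if (object@p < lo - 1e-12 || object@p > 1 + 1e-12)
    return("p outside [1/(N+1), 1]")
  TRUE
})

setMethod("show", "PhyloAlignment", function(object) {
  cat(sprintf("PhyloAlignment: %d sequences x %d %s sites\n",
              length(object@seqNames), ncol(object@states),
              object@flavor))
  cat("  ", paste(head(object@seqNames, 5), collapse = ", "),
      if (length(object@seqNames) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: logLik = %.4f over %d sites\n",
              object@logLik, length(object@siteLogLik)))
  p <- object@parameters
  if (length(p)) {
    scal <- vapply(p, function(x) is.numeric(x) && length(x) == 1, logical(1))
    if (any(scal))
      cat("  ", paste(sprintf("%s = %.4g", names(p)[scal], unlist(p[scal])),
                      collapse = ", "), "\n", sep = "")
  }
  if (isTRUE(object@diagnostics$converged)) cat("  converged\n")
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: 2*dlnL = %.4f (df = %d), p = %.4g\n",
              object@lrt$statistic, object@lrt$df, object@lrt$p))
  cat(sprintf("  proportion of sites under selection: %.3f\n",
              object@proportionSelected))
  cat(sprintf("  %d site(s) above the posterior threshold\n",
              sum(object@sites$selected)))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf("ClusterTestResult: observed %s = %.3f A, p = %.3g (N = %d)\n",
              object@statistic, object@observed, object@p,
              as.integer(object@nPerm)))
})

# ---- accessors ---------------------------------------------------------

#' @rdname PhyloAlignment-class
#' @param x a `PhyloAlignment`.
#' @export
seqNames <- function(x) x@seqNames

#' @rdname PhyloAlignment-class
#' @export
nSites <- function(x) ncol(x@states)

#' @rdname PhyloAlignment-class
#' @export
alignmentFlavor <- function(x) x@flavor

#' @rdname ModelFit-class
#' @param fit a `ModelFit`.
#' @export
modelLogLik <- function(fit) fit@logLik

#' @rdname ModelFit-class
#' @export
fitParameters <- function(fit) fit@parameters

#' @rdname ModelFit-class
#' @export
sitePosteriors <- function(fit) fit@posteriors

#' @rdname ClusterTestResult-class
#' @param x a `ClusterTestResult`.
#' @export
permutationP <- function(x) x@p
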