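#' @include likelihood.R
NULL

BL_MIN <- 1e-8
BL_MAX <- 50

# forward-difference gradient for nlminb: p+1 evaluations per call, which is
# markedly cheaper than the optimizer's own central-difference default on
# likelihood surfaces this expensive
numGrad <- function(fn, eps = 1e-7) {
  function(par) {
    f0 <- fn(par)
    vapply(seq_along(par), function(i) {
      h <- eps * max(1, abs(par[i]))
      p2 <- par; p2[i] <- p2[i] + h
      (fn(p2) - f0) / h
    }, numeric(1))
  }
}

# box-constrained quasi-Newton maximization workhorse shared by the fitters
boundedOptim <- function(init, obj, lower, upper,
                         control = list()) {
  maxit <- control$iter.max %||% 300
  factr <- control$factr %||% 1e7
  opt <- optim(init, obj, gr = numGrad(obj), method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = maxit, factr = factr))
  list(par = opt$par, objective = opt$value,
       convergence = opt$convergence, iterations = opt$counts[["function"]])
}

# total log-likelihood for prep with current prep$lens under a plain model;
# AA eigen systems can be passed in to avoid recomputation across evals
plainLogLik <- function(prep, model, cache = NULL) {
  cls <- if (!is.null(cache) && inherits(model, "AAModel")) {
    rates <- gammaRates(model)
    p <- model$pInvariant
    k <- length(rates)
    liks <- lapply(rates, function(r)
      classSiteLik(prep, classPs(prep, cache$eig, r / (1 - p)), cache$freqs))
    weights <- rep((1 - p) / k, k)
    if (p > 0) {
      liks <- c(liks, list(cache$invLik))
      weights <- c(weights, p)
    }
    list(liks = liks, weights = weights)
  } else modelClasses(model, prep)
  mix <- mixtureFromClassLiks(prep, cls$liks, cls$weights)
  sum(log(mix$patLik) * prep$patW)
}

#' Optimize branch lengths by cyclic univariate search
#'
#' Coordinate-wise bounded Brent optimization of each branch length on the
#' log-length scale, cycled until the log-likelihood improves by less than
#' `tol` over a full sweep. The log-likelihood is non-decreasing across
#' sweeps by construction.
#'
#' @param aln a [PhyloAlignment-class].
#' @param tree starting `phylo`; its branch lengths seed the search.
#' @param model substitution model.
#' @param tol convergence tolerance in log-likelihood units per sweep.
#' @param maxSweeps sweep limit; non-convergence is flagged, best-so-far
#'   returned.
#' @return list with `tree` (optimized lengths) and `fit` (a [ModelFit-class]
#'   whose diagnostics record the per-sweep log-likelihood trace).
#' @export
optimizeBranchLengths <- function(aln, tree, model, tol = 1e-6,
                                  maxSweeps = 20L) {
  prep <- prepLikelihood(aln, tree)
  cache <- aaCache(prep, model)
  lens <- pmax(prep$lens, BL_MIN)
  cur <- { prep$lens <- lens; plainLogLik(prep, model, cache) }
  trace <- cur
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    for (k in seq_along(lens)) {
      obj <- function(lt) {
        lens2 <- lens; lens2[k] <- exp(lt)
        prep$lens <- lens2
        -plainLogLik(prep, model, cache)
      }
      opt <- optimize(obj, interval = log(c(BL_MIN, BL_MAX)), tol = 1e-8)
      if (-opt$objective > cur) {   # never accept a worse point
        lens[k] <- exp(opt$minimum)
        cur <- -opt$objective
      }
    }
    trace <- c(trace, cur)
    if (diff(tail(trace, 2)) < tol) { converged <- TRUE; break }
  }
  prep$lens <- lens
  outTree <- prep$tree
  outTree$edge.length <- lens
  # map lengths back onto the caller's edge ordering
  ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
               paste(prep$edges[, 1], prep$edges[, 2]))
  res <- tree
  res$edge.length <- lens[ord]
  fit <- treeLogLikelihood(aln, res, model)
  fit@diagnostics <- list(converged = converged, sweeps = length(trace) - 1,
                          trace = trace)
  list(tree = res, fit = fit)
}

aaCache <- function(prep, model) {
  if (!inherits(model, "AAModel")) return(NULL)
  qm <- buildRateMatrix(model)
  list(eig = eigenReversible(qm$Q, qm$freqs), freqs = qm$freqs,
       invLik = if (model$pInvariant > 0) invariantSiteLik(prep, qm$freqs)
                else NULL)
}

modelFreeParamSpec <- function(model, free) {
  spec <- list(
    gammaShape = list(init = 1, lower = 0.05, upper = 100),
    pInvariant = list(init = 0.05, lower = 0, upper = 0.99),
    kappa = list(init = 2, lower = 0.05, upper = 100),
    omega = list(init = 0.5, lower = 1e-6, upper = 50))
  valid <- if (inherits(model, "AAModel")) c("gammaShape", "pInvariant")
           else c("kappa", "omega")
  bad <- setdiff(free, valid)
  if (length(bad)) stop("free parameters not in model: ",
                        paste(bad, collapse = ", "))
  spec[free]
}

applyFreeParams <- function(model, free, values) {
  for (i in seq_along(free)) model[[free[i]]] <- values[i]
  model
}

#' Write a ModelFit as JSON (and optionally the optimized tree as newick)
#'
#' @param fit a [ModelFit-class].
#' @param path JSON output path.
#' @param treePath optional newick output path for the fitted tree.
#' @export
writeModelFit <- function(fit, path, treePath = NULL) {
  pars <- fit@parameters
  pars <- pars[vapply(pars, function(x) is.numeric(x) || is.character(x),
                      logical(1))]
  jsonlite::write_json(
    list(logLik = fit@logLik, parameters = pars,
         diagnostics = fit@diagnostics[c("converged", "iterations",
                                         "atBound")],
         nSites = length(fit@siteLogLik)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(treePath)) writeMarkedTree(fit@tree, treePath)
  invisible(path)
}

#' Fit model parameters and branch lengths by maximum likelihood
#'
#' Joint bounded quasi-Newton optimization (via [stats::nlminb()]) of the
#' requested free model parameters and (optionally) all branch lengths on
#' the log scale. With `free = character(0)` and
#' `optimizeBranches = FALSE` this reduces to [treeLogLikelihood()].
#'
#' @inheritParams optimizeBranchLengths
#' @param free character vector of free model parameter names
#'   (`"gammaShape"`, `"pInvariant"` for amino-acid models; `"kappa"`,
#'   `"omega"` for codon models).
#' @param optimizeBranches also optimize all branch lengths.
#' @param control passed to [stats::nlminb()].
#' @return a [ModelFit-class]; `fitParameters()` carries the estimates,
#'   diagnostics flag convergence and parameters at bounds.
#' @export
fitModel <- function(aln, tree, model, free = character(0),
                     optimizeBranches = TRUE,
                     control = list(iter.max = 500, eval.max = 2000)) {
  if (!length(free) && !optimizeBranches)
    return(treeLogLikelihood(aln, tree, model))
  prep <- prepLikelihood(aln, tree)
  spec <- modelFreeParamSpec(model, free)
  nb <- if (optimizeBranches) length(prep$lens) else 0L
  init <- c(if (nb) log(pmax(prep$lens, 1e-6)),
            vapply(spec, `[[`, numeric(1), "init"))
  lower <- c(rep(log(BL_MIN), nb), vapply(spec, `[[`, numeric(1), "lower"))
  upper <- c(rep(log(BL_MAX), nb), vapply(spec, `[[`, numeric(1), "upper"))
  baseLens <- prep$lens
  cacheEnv <- new.env()
  objective <- function(par) {
    if (nb) prep$lens <- exp(par[seq_len(nb)]) else prep$lens <- baseLens
    m2 <- applyFreeParams(model, free, par[nb + seq_along(free)])
    cache <- if (inherits(model, "AAModel")) {
      # eigen system is parameter-independent for AA models; cache once
      if (is.null(cacheEnv$c)) cacheEnv$c <- aaCache(prep, m2)
      cc <- cacheEnv$c
      if (m2$pInvariant > 0 && is.null(cc$invLik))
        cc$invLik <- invariantSiteLik(prep, cc$freqs)
      cc
    } else NULL
    ll <- tryCatch(plainLogLik(prep, m2, cache), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- boundedOptim(init, objective, lower, upper, control)
  if (nb) prep$lens <- exp(opt$par[seq_len(nb)])
  fitted <- applyFreeParams(model, free, opt$par[nb + seq_along(free)])
  outTree <- tree
  if (nb) {
    ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                 paste(prep$edges[, 1], prep$edges[, 2]))
    outTree$edge.length <- prep$lens[ord]
  }
  fit <- treeLogLikelihood(aln, outTree, fitted)
  atBound <- free[abs(opt$par[nb + seq_along(free)] -
                        upper[nb + seq_along(free)]) < 1e-6 |
                  abs(opt$par[nb + seq_along(free)] -
                        lower[nb + seq_along(free)]) < 1e-6]
  fit@diagnostics <- list(converged = opt$convergence == 0,
                          iterations = opt$iterations,
                          atBound = atBound, nFreeParams = length(init))
  fit
}
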