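#' @include models.R
NULL

# cache of codon-pair structure (which pairs differ at one position, whether
# the change is a transition, whether it is synonymous)
codonPairsEnv <- new.env(parent = emptyenv())

codonPairs <- function() {
  if (!is.null(codonPairsEnv$pairs)) return(codonPairsEnv$pairs)
  cod <- senseCodons()
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[cod])
  chars <- do.call(rbind, strsplit(cod, ""))
  n <- length(cod)
  ndiff <- matrix(0L, n, n)
  for (pos in 1:3) ndiff <- ndiff + outer(chars[, pos], chars[, pos], "!=")
  one <- ndiff == 1L
  transition <- matrix(FALSE, n, n)
  isTs <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
                         (a == "C" & b == "T") | (a == "T" & b == "C")
  for (pos in 1:3) {
    d <- outer(chars[, pos], chars[, pos], "!=")
    transition <- transition | (one & d & outer(chars[, pos], chars[, pos], isTs))
  }
  synonymous <- outer(aa, aa, "==")
  res <- list(one = one, transition = transition, synonymous = synonymous,
              aa = aa)
  codonPairsEnv$pairs <- res
  res
}

#' Build a scaled reversible rate matrix
#'
#' Builds the instantaneous rate matrix Q of a model, with zero row sums,
#' detailed balance (`pi_i Q_ij = pi_j Q_ji`), and scaled so that the
#' expected substitution rate at stationarity is 1 per unit branch length.
#' For models with a rate mixture (discrete Gamma, invariant sites) the
#' scaling accounts for the mixture, so branch lengths stay in expected
#' substitutions per site.
#'
#' @param model an `AAModel` or `CodonModel`.
#' @param scale if `FALSE`, return the unscaled matrix (mean rate as built).
#' @return list with `Q` (matrix) and `freqs`.
#' @export
buildRateMatrix <- function(model, scale = TRUE) {
  UseMethod("buildRateMatrix")
}

#' @export
buildRateMatrix.AAModel <- function(model, scale = TRUE) {
  pi <- model$freqs
  if (abs(sum(pi) - 1) > 1e-9) stop("frequencies must sum to 1")
  Q <- model$exchange * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (scale) {
    # scale to mean rate 1; the Gamma categories have mean 1 by construction
    # and the invariant class is handled by dividing the category rates by
    # (1 - pInvariant) at likelihood time, keeping the full mixture at mean 1
    mu <- -sum(pi * diag(Q))
    if (mu <= 0) stop("degenerate rate matrix (zero mean rate)")
    Q <- Q / mu
  }
  list(Q = Q, freqs = pi)
}

#' @export
buildRateMatrix.CodonModel <- function(model, scale = TRUE) {
  codonRateMatrix(model$kappa, model$omega, model$freqs, scale = scale)
}

# raw GY-style codon rate matrix for one omega
codonRateMatrix <- function(kappa, omega, freqs, scale = TRUE) {
  cp <- codonPairs()
  n <- length(freqs)
  R <- matrix(0, n, n)
  R[cp$one] <- 1
  R[cp$one & cp$transition] <- kappa
  R[cp$one & !cp$synonymous] <- R[cp$one & !cp$synonymous] * omega
  Q <- R * rep(freqs, each = n)
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(freqs * diag(Q))
    if (mu <= 0) stop("degenerate rate matrix (zero mean rate)")
    Q <- Q / mu
  }
  dimnames(Q) <- list(names(freqs), names(freqs))
  list(Q = Q, freqs = freqs)
}

gammaRates <- function(model) {
  if (is.na(model$gammaShape)) return(1)
  discretizeGamma(model$gammaShape, model$nRateCategories)
}

# eigendecomposition of a reversible Q via the pi-square-root similarity
# transform; exact and stable, reusable across branches
eigenReversible <- function(Q, pi) {
  s <- sqrt(pi)
  S <- Q * outer(s, 1 / s)
  S <- (S + t(S)) / 2  # symmetrize away rounding
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / s,        # diag(1/s) %*% U
       left = t(e$vectors * s))      # t(U) %*% diag(s)
}

# P(t) = right %*% diag(exp(values * t)) %*% left
probMatrix <- function(eig, t) {
  if (t < 0) stop("negative branch length")
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P
}
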