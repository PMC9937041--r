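#' @include AllClasses.R
NULL

# checksums of the shipped exchangeability tables (published constants,
# Jones et al. 1992 and Le & Gascuel 2008, in the standard .dat layout)
DAT_MD5 <- c(jtt.dat = "ba3a5d51811e752665cbf6293222abcd",
             lg.dat  = "305ee0a1306242fbf8b5489bd489188a")

readExchangeDat <- function(name) {
  path <- system.file("extdata", name, package = "ponevo")
  if (!nzchar(path)) stop("missing model table ", name)
  sum <- unname(md5sum(path))
  if (!identical(sum, unname(DAT_MD5[name])))
    stop("checksum mismatch for ", name)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nums <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  S <- matrix(0, 20, 20)
  for (i in 2:20) S[i, 1:(i - 1)] <- nums[[i - 1]]
  S <- S + t(S)
  freqs <- nums[[20]]
  freqs <- freqs / sum(freqs)
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  list(exchange = S, freqs = setNames(freqs, AA_ALPHABET))
}

#' Empirical amino-acid substitution model
#'
#' Constructs a reversible amino-acid model from a named exchangeability
#' table (JTT, LG) or the Poisson model (equal exchangeabilities and
#' frequencies), optionally with discrete-Gamma rate heterogeneity and a
#' proportion of invariant sites.
#'
#' @param name `"JTT"`, `"LG"` or `"Poisson"`.
#' @param gammaShape Gamma shape alpha (> 0) for among-site rate variation,
#'   or `NA` for a single rate.
#' @param nRateCategories number of equal-probability discrete Gamma
#'   categories (default 4, the convention behind "+G" fits).
#' @param pInvariant proportion of invariant sites in `[0, 1)`, or 0.
#' @param frequencies optional length-20 stationary frequency override.
#' @return an object of class `AAModel` (list-based).
#' @export
aminoAcidModel <- function(name = c("JTT", "LG", "Poisson"), gammaShape = NA,
                           nRateCategories = 4L, pInvariant = 0,
                           frequencies = NULL) {
  name <- match.arg(name)
  if (!is.na(gammaShape) && gammaShape <= 0) stop("gammaShape must be > 0")
  if (pInvariant < 0 || pInvariant >= 1) stop("pInvariant must be in [0, 1)")
  if (name == "Poisson") {
    exchange <- matrix(1, 20, 20); diag(exchange) <- 0
    dimnames(exchange) <- list(AA_ALPHABET, AA_ALPHABET)
    freqs <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    tab <- readExchangeDat(paste0(tolower(name), ".dat"))
    exchange <- tab$exchange
    freqs <- tab$freqs
  }
  if (!is.null(frequencies)) {
    if (length(frequencies) != 20) stop("frequencies must have length 20")
    if (abs(sum(frequencies) - 1) > 1e-9) stop("frequencies must sum to 1")
    freqs <- setNames(as.numeric(frequencies), AA_ALPHABET)
  }
  structure(list(name = name, exchange = exchange, freqs = freqs,
                 gammaShape = gammaShape,
                 nRateCategories = as.integer(nRateCategories),
                 pInvariant = pInvariant),
            class = c("AAModel", "ponevoModel"))
}

#' Discrete-Gamma rate categories
#'
#' Splits a Gamma(alpha, alpha) distribution (mean 1) into `k` equal
#' probability bins and returns the mean rate of each bin, so that the
#' returned rates have mean exactly 1.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` rates, each with probability `1/k`.
#' @export
discretizeGamma <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k == 1) return(1)
  # mean of Gamma(a, a) over quantile bin (q0, q1]:
  #   k * [ P(a+1, x1) - P(a+1, x0) ]  with P the regularized incomplete gamma
  breaks <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  upper <- pgamma(breaks[-1], shape = alpha + 1, rate = alpha)
  lower <- pgamma(breaks[-(k + 1)], shape = alpha + 1, rate = alpha)
  rates <- k * (upper - lower)
  rates / mean(rates) * 1  # guard tiny numerical drift; mean is already 1
}

#' Goldman-Yang style codon substitution model (M0)
#'
#' One-ratio codon model over the 61 sense codons of the standard genetic
#' code: instantaneous rates are zero between codons differing at more than
#' one nucleotide, proportional to the target codon frequency, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous changes.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param frequencies either a length-61 codon frequency vector (summing
#'   to 1, ordered as [senseCodons()]), or one of `"equal"`, `"F1x4"`,
#'   `"F3x4"`, `"F61"`; the named options are resolved against an alignment
#'   with [codonFrequencies()].
#' @return an object of class `CodonModel`.
#' @export
codonModel <- function(kappa = 2, omega = 0.5, frequencies = "equal") {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  cod <- senseCodons()
  if (is.character(frequencies)) {
    freqs <- switch(frequencies,
      equal = setNames(rep(1 / 61, 61), cod),
      stop("named frequency option '", frequencies,
           "' must be resolved with codonFrequencies() first"))
  } else {
    if (length(frequencies) != 61) stop("frequencies must have length 61")
    if (abs(sum(frequencies) - 1) > 1e-9) stop("frequencies must sum to 1")
    freqs <- setNames(as.numeric(frequencies), cod)
  }
  structure(list(kappa = kappa, omega = omega, freqs = freqs),
            class = c("CodonModel", "ponevoModel"))
}

#' Empirical codon frequencies from an alignment
#'
#' @param aln codon-flavor [PhyloAlignment-class].
#' @param method `"F61"` (observed codon frequencies), `"F3x4"` (products of
#'   position-specific nucleotide frequencies, renormalized over sense
#'   codons) or `"F1x4"` (overall nucleotide frequencies).
#' @return length-61 frequency vector over [senseCodons()].
#' @export
codonFrequencies <- function(aln, method = c("F3x4", "F1x4", "F61")) {
  method <- match.arg(method)
  stopifnot(aln@flavor == "codon")
  cod <- senseCodons()
  obs <- aln@states[!is.na(aln@states)]
  if (method == "F61") {
    counts <- tabulate(obs, nbins = 61) + 0.1  # light pseudocount
    f <- counts / sum(counts)
  } else {
    codChars <- do.call(rbind, strsplit(cod, ""))
    usedCod <- cod[obs]
    mat <- do.call(rbind, strsplit(usedCod, ""))
    if (method == "F1x4") {
      nf <- table(factor(mat, levels = c("A", "C", "G", "T"))) + 0.1
      nf <- nf / sum(nf)
      f <- nf[codChars[, 1]] * nf[codChars[, 2]] * nf[codChars[, 3]]
    } else {
      f <- rep(1, 61)
      for (pos in 1:3) {
        nf <- table(factor(mat[, pos], levels = c("A", "C", "G", "T"))) + 0.1
        nf <- nf / sum(nf)
        f <- f * as.numeric(nf[codChars[, pos]])
      }
    }
    f <- as.numeric(f) / sum(f)
  }
  setNames(as.numeric(f), cod)
}
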