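#' @include structure.R alignment.R
NULL

#' Map alignment columns of a query row to structure residue numbers
#'
#' Walks the ungapped residues of the query row through the structure
#' sequence: each non-gap column maps to the next structure residue; gap
#' columns map to nothing. Mismatches between the query residues and the
#' structure sequence above 5 percent abort with an error (unresolved or
#' modified residues cause occasional tolerated mismatches below that).
#'
#' @param msa a protein [PhyloAlignment-class].
#' @param queryName name of the alignment row that corresponds to the
#'   structure.
#' @param structureSeq one-letter sequence of the structure residues, in
#'   residue order.
#' @param structureResnums optional residue numbers parallel to
#'   `structureSeq` (defaults to 1..n).
#' @return data.frame `column` (alignment column), `resnum` (structure
#'   residue number); unmappable non-gap columns beyond the structure end
#'   are absent.
#' @export
mapAlignmentToStructure <- function(msa, queryName, structureSeq,
                                    structureResnums = NULL) {
  if (!queryName %in% msa@seqNames) stop("query '", queryName,
                                         "' not in alignment")
  row <- msa@states[match(queryName, msa@seqNames), ]
  qChars <- msa@alphabet[row]          # NA at gaps
  sChars <- strsplit(toupper(structureSeq), "")[[1]]
  if (is.null(structureResnums)) structureResnums <- seq_along(sChars)
  if (length(structureResnums) != length(sChars))
    stop("structureResnums length mismatch")
  cols <- which(!is.na(row))
  n <- min(length(cols), length(sChars))
  mismatch <- sum(qChars[cols[seq_len(n)]] != sChars[seq_len(n)])
  if (mismatch / max(1, n) > 0.05)
    stop("query/structure sequences disagree at ", mismatch, " of ", n,
         " positions (> 5%)")
  data.frame(column = cols[seq_len(n)],
             resnum = structureResnums[seq_len(n)])
}

#' Permutation test for spatial clustering of selected residues
#'
#' Tests whether a set of residues sits closer together on the structure
#' than equally sized random subsets of a candidate pool (the
#' solvent-exposed residues by default). The statistic is the mean pairwise
#' C-alpha distance (or mean nearest-neighbor distance); the p-value uses
#' the add-one correction p = (b + 1) / (N + 1), so p can never drop below
#' 1 / (N + 1) — claims at the 1e-6 scale need N >= 1e6.
#'
#' @param selected integer vector of residue numbers under test.
#' @param structure list from [classifyExposed()] (or [parseStructure()]
#'   with `restrictToExposed = FALSE` and ASA not required).
#' @param restrictToExposed draw the null pool from exposed residues only;
#'   selected residues outside the pool are dropped with a message.
#' @param nPerm number of random subsets N.
#' @param seed integer seed (mandatory for reproducibility).
#' @param statistic `"meanPairwise"` (default) or `"meanNearestNeighbor"`.
#' @return a [ClusterTestResult-class].
#' @export
clusteringPermutationTest <- function(selected, structure,
                                      restrictToExposed = TRUE,
                                      nPerm = 1e6, seed,
                                      statistic = c("meanPairwise",
                                                    "meanNearestNeighbor")) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("seed is required")
  res <- structure$residues
  pool <- res[res$hasCa, , drop = FALSE]
  if (restrictToExposed) {
    if (all(is.na(pool$exposed)))
      stop("exposure not classified; run computeAsa() and classifyExposed()")
    pool <- pool[pool$exposed %in% TRUE, , drop = FALSE]
  }
  inPool <- selected %in% pool$resnum
  if (any(!inPool)) {
    message(sum(!inPool), " selected residue(s) outside the candidate ",
            "pool dropped")
    selected <- selected[inPool]
  }
  m <- length(selected)
  if (m < 2) stop("need at least 2 selected residues in the pool")
  if (nrow(pool) < m) stop("candidate pool smaller than the selected set")
  xyz <- as.matrix(pool[, c("cax", "cay", "caz")])
  D <- as.matrix(dist(xyz))
  selIdx <- match(selected, pool$resnum)
  statFun <- if (statistic == "meanPairwise") {
    function(i) { d <- D[i, i]; sum(d) / (length(i) * (length(i) - 1)) }
  } else {
    function(i) { d <- D[i, i]; diag(d) <- Inf; mean(apply(d, 1, min)) }
  }
  observed <- statFun(selIdx)
  withStream(seed, "clusterPermutation", {
    b <- 0L
    nPool <- nrow(pool)
    for (r in seq_len(nPerm)) {
      idx <- sample.int(nPool, m)
      if (statFun(idx) <= observed) b <- b + 1L
    }
    new("ClusterTestResult", observed = observed, nPerm = as.numeric(nPerm),
        nAsExtreme = as.numeric(b), p = (b + 1) / (nPerm + 1),
        seed = as.numeric(seed), statistic = statistic)
  })
}
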