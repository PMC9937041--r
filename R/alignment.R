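#' @include AllClasses.R
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build a PhyloAlignment from character sequences
#'
#' @param seqs named character vector of aligned sequences (equal length).
#'   For `flavor = "codon"` the sequences are in-frame nucleotide sequences
#'   whose length is divisible by 3 and which contain no stop codons
#'   (terminal stops must already be trimmed, as is conventional for
#'   dN/dS analysis).
#' @param flavor `"protein"` or `"codon"`.
#' @return a [PhyloAlignment-class] object. Gaps (`-`, `.`) and ambiguity
#'   codes become missing data.
#' @export
phyloAlignment <- function(seqs, flavor = c("protein", "codon")) {
  flavor <- match.arg(flavor)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must have equal length")
  seqs <- toupper(seqs)
  if (flavor == "protein") {
    alphabet <- AA_ALPHABET
    chars <- do.call(rbind, strsplit(seqs, ""))
    states <- matrix(match(chars, alphabet), nrow = length(seqs))
  } else {
    n <- unique(nchar(seqs))
    if (n %% 3 != 0) stop("codon alignment length must be divisible by 3")
    alphabet <- senseCodons()
    codmat <- t(vapply(seqs, function(s) {
      substring(s, seq(1, n, 3), seq(3, n, 3))
    }, character(n / 3)))
    if (any(codmat %in% STOP_CODONS))
      stop("codon alignment contains stop codons")
    states <- matrix(match(codmat, alphabet), nrow = length(seqs))
  }
  new("PhyloAlignment", seqNames = names(seqs), states = states,
      alphabet = alphabet, flavor = flavor)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of aligned sequences.
#' @inheritParams phyloAlignment
#' @export
readAlignmentFasta <- function(path, flavor = c("protein", "codon")) {
  flavor <- match.arg(flavor)
  set <- if (flavor == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  phyloAlignment(seqs, flavor)
}

#' Write an alignment as FASTA
#'
#' @param aln a [PhyloAlignment-class].
#' @param path output file.
#' @export
writeAlignmentFasta <- function(aln, path) {
  seqs <- alignmentCharacters(aln)
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' @rdname PhyloAlignment-class
#' @param aln a `PhyloAlignment`.
#' @export
alignmentCharacters <- function(aln) {
  alpha <- aln@alphabet
  gap <- if (aln@flavor == "codon") "---" else "-"
  out <- apply(aln@states, 1, function(row) {
    ch <- alpha[row]
    ch[is.na(ch)] <- gap
    paste(ch, collapse = "")
  })
  setNames(out, aln@seqNames)
}

# site-pattern compression: identical columns are collapsed and weighted;
# the likelihood over patterns x weights equals the uncompressed one exactly
compressPatterns <- function(states) {
  key <- apply(states, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                              collapse = ","))
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  list(states = states[, keep, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(keep))))),
       map = idx)
}
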