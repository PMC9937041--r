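#' @include family-scan.R ponevo-package.R
NULL

#' Simulate a gene locus table with planted family structure
#'
#' Emits a coordinate table (species, gene_id, scaffold, start, end,
#' strand, exon_count), a matching domtblout-style hit text, and a truth
#' list recording every planted feature, so that the family-scan rules can
#' be checked against ground truth.
#'
#' Planted tandem arrays place `nGenes` loci on one scaffold separated by
#' the requested inter-gene gap. Species listed in `absences` for a family
#' receive no locus and no hit line for it. Per-array intron-loss plants
#' make one member single-exon (the others keep `exonCount` exons).
#' Decoy hits (non-family genes) straddle the 1e-6 e-value cutoff: half
#' pass both e-value filters, half fail at least one.
#'
#' @param species character vector of species names.
#' @param arrays data.frame with columns `species`, `family`, `scaffold`,
#'   `nGenes`, `gapBp` (and optional `intronLoss` logical: plant one
#'   single-exon member).
#' @param absences named list: family -> character vector of species with
#'   no member (consistency-checked against `arrays`).
#' @param nDecoys number of decoy hits straddling the e-value cutoff.
#' @param geneLength gene span in bp.
#' @param exonCount exon count of ordinary members.
#' @param seed integer seed.
#' @return list with `loci` (data.frame), `hitText` (character lines),
#'   `truth` (list: `arrays`, `absences`, `intronLoss`, `decoyPass`).
#' @export
simulateLocusTable <- function(species, arrays, absences = list(),
                               nDecoys = 0, geneLength = 20000,
                               exonCount = 9, seed = 1) {
  stopifnot(all(c("species", "family", "scaffold", "nGenes", "gapBp")
                %in% names(arrays)))
  if (any(arrays$gapBp < 0)) stop("gaps must be >= 0")
  if (any(arrays$nGenes < 1)) stop("arrays need at least one gene")
  if (!all(arrays$species %in% species)) stop("unknown species in arrays")
  for (fam in names(absences)) {
    clash <- intersect(absences[[fam]],
                       arrays$species[arrays$family == fam])
    if (length(clash))
      stop("species ", paste(clash, collapse = ","),
           " both absent and planted for family ", fam)
  }
  key <- paste(arrays$species, arrays$scaffold)
  if (anyDuplicated(key))
    stop("overlapping planted arrays on one scaffold")
  withStream(seed, "loci", {
    lociList <- list()
    truthArrays <- list()
    intronLossIds <- character(0)
    for (r in seq_len(nrow(arrays))) {
      a <- arrays[r, ]
      start0 <- sample.int(100000, 1)
      ids <- sprintf("%s_%s_g%d", a$species, a$family, seq_len(a$nGenes))
      starts <- start0 + (seq_len(a$nGenes) - 1) * (geneLength + a$gapBp)
      exo <- rep(exonCount, a$nGenes)
      if (isTRUE(a$intronLoss) && a$nGenes >= 2) {
        pick <- sample.int(a$nGenes, 1)
        exo[pick] <- 1L
        intronLossIds <- c(intronLossIds, ids[pick])
      }
      lociList[[r]] <- data.frame(
        species = a$species, gene_id = ids, scaffold = a$scaffold,
        start = starts, end = starts + geneLength - 1,
        strand = sample(c("+", "-"), a$nGenes, replace = TRUE),
        exon_count = exo, family = a$family)
      truthArrays[[r]] <- data.frame(
        species = a$species, family = a$family, scaffold = a$scaffold,
        gene_ids = I(list(ids)), gapBp = a$gapBp, nGenes = a$nGenes)
    }
    loci <- do.call(rbind, lociList)
    # hit lines for every planted gene: e-values clearly below the cutoff
    planted <- data.frame(
      target = paste0(loci$species, "|", loci$gene_id),
      fullE = 10^runif(nrow(loci), -30, -8),
      domE = 10^runif(nrow(loci), -30, -8))
    decoyPass <- logical(0)
    decoys <- NULL
    if (nDecoys > 0) {
      dSpecies <- sample(species, nDecoys, replace = TRUE)
      dIds <- sprintf("%s_decoy%d", dSpecies, seq_len(nDecoys))
      pass <- runif(nDecoys) < 0.5
      fullE <- ifelse(pass, 10^runif(nDecoys, -8, log10(1e-6)),
                      10^runif(nDecoys, log10(2e-6), -3))
      domE <- ifelse(pass, 10^runif(nDecoys, -8, log10(1e-6)),
                     ifelse(runif(nDecoys) < 0.5,
                            10^runif(nDecoys, log10(2e-6), -3),
                            10^runif(nDecoys, -8, log10(1e-6))))
      decoys <- data.frame(target = paste0(dSpecies, "|", dIds),
                           fullE = fullE, domE = domE)
      decoyPass <- setNames(pass, dIds)
    }
    hits <- rbind(planted, decoys)
    hitText <- c(
      "# target name | query name | full E-value | i-Evalue (domtblout dialect)",
      vapply(seq_len(nrow(hits)), function(i)
        paste(hits$target[i], "-", 400, "arylesterase", "PF01731.21", 243,
              format(hits$fullE[i], digits = 3), 100.0, 0.1, 1, 1,
              format(hits$domE[i] * 0.9, digits = 3),
              format(hits$domE[i], digits = 3), 95.0, 0.1,
              5, 240, 20, 260, 10, 270, 0.95, "-", sep = " "),
        character(1)))
    list(loci = loci[, c("species", "gene_id", "scaffold", "start", "end",
                         "strand", "exon_count", "family")],
         hitText = hitText,
         truth = list(arrays = do.call(rbind, truthArrays),
                      absences = absences,
                      intronLoss = intronLossIds,
                      decoyPass = decoyPass))
  })
}

#' Write a locus table as TSV
#'
#' @param loci data.frame from [simulateLocusTable()] (or the same layout).
#' @param path output file.
#' @export
writeLocusTable <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus table TSV
#'
#' @param path TSV with columns species, gene_id, scaffold, start, end,
#'   strand, exon_count.
#' @export
readLocusTable <- function(path) {
  loci <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  need <- c("species", "gene_id", "scaffold", "start", "end", "strand",
            "exon_count")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("locus table lacks columns: ",
                         paste(miss, collapse = ", "))
  loci
}
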