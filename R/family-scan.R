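#' @include AllClasses.R
NULL

#' Parse a domtblout-style domain hit table
#'
#' Reads the whitespace-separated per-domain table emitted by profile-HMM
#' searches (one line per domain, `#` comments), and aggregates domains to
#' one record per gene: the full-sequence e-value, the smallest per-domain
#' independent e-value (`best_domain_evalue`) and the domain count.
#' Target names of the form `species|gene_id` are split into the two
#' fields; otherwise `species` is `NA`.
#'
#' @param text character vector of lines, or a length-1 path to a file.
#' @return data.frame with columns `species`, `gene_id`, `full_seq_evalue`,
#'   `best_domain_evalue`, `n_domains`.
#' @export
parseDomtblout <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  lines <- text[!grepl("^#", text) & nzchar(trimws(text))]
  if (!length(lines))
    return(data.frame(species = character(0), gene_id = character(0),
                      full_seq_evalue = numeric(0),
                      best_domain_evalue = numeric(0),
                      n_domains = integer(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 22)
  if (length(bad))
    stop("malformed domtblout line ", bad[1], ": expected >= 22 columns, ",
         "found ", nf[bad[1]])
  target <- vapply(fields, `[[`, character(1), 1)
  fullE <- as.numeric(vapply(fields, `[[`, character(1), 7))
  domE <- as.numeric(vapply(fields, `[[`, character(1), 13))
  if (anyNA(fullE) || anyNA(domE))
    stop("malformed domtblout: non-numeric e-value field")
  sp <- ifelse(grepl("\\|", target), sub("\\|.*$", "", target), NA_character_)
  gene <- ifelse(grepl("\\|", target), sub("^[^|]*\\|", "", target), target)
  agg <- split(seq_along(gene), paste(sp, gene, sep = "\r"))
  out <- do.call(rbind, lapply(agg, function(i) {
    data.frame(species = sp[i[1]], gene_id = gene[i[1]],
               full_seq_evalue = fullE[i[1]],
               best_domain_evalue = min(domE[i]),
               n_domains = length(i))
  }))
  out <- out[order(out$species, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter domain hits by the dual e-value rule
#'
#' Keeps exactly the hits whose full-sequence e-value and best-domain
#' e-value are both at or below their thresholds (default 1e-6, the bounds
#' read as attainable, i.e. inclusive). The number of domains is never
#' considered. The filter is idempotent and order-preserving.
#'
#' @param hits data.frame as from [parseDomtblout()].
#' @param fullThresh,domThresh maximum e-values (> 0).
#' @return the retained rows of `hits`.
#' @export
filterHits <- function(hits, fullThresh = 1e-6, domThresh = 1e-6) {
  if (fullThresh <= 0 || domThresh <= 0) stop("thresholds must be > 0")
  keep <- hits$full_seq_evalue <= fullThresh &
    hits$best_domain_evalue <= domThresh
  hits[keep, , drop = FALSE]
}

#' Name loci by the tandem-array convention
#'
#' Groups one species' loci into tandem arrays by single-linkage chaining:
#' two loci are linked when they lie on the same scaffold and the gap
#' between their nearest gene ends is at most `window` (overlapping loci
#' have gap 0). Arrays are ordered by scaffold name and leftmost start and
#' lettered A, B, ...; a single-gene array gets the bare letter, a
#' multi-gene array gets letter plus index 1..k by start coordinate. The
#' result does not depend on the input row order.
#'
#' @param loci data.frame with columns `species`, `gene_id`, `scaffold`,
#'   `start`, `end`, `strand`, `exon_count`, all from one species.
#' @param window maximum gap in bp (default 100000).
#' @return data.frame `gene_id`, `name`, `array_id`, `scaffold`.
#' @export
assignNames <- function(loci, window = 100000) {
  stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(loci)))
  if (length(unique(loci$species)) > 1)
    stop("assignNames expects loci from a single species")
  if (anyDuplicated(loci$gene_id))
    stop("duplicate gene_id in locus table")
  if (any(loci$start > loci$end)) stop("locus with start > end")
  loci <- loci[order(loci$scaffold, loci$start, loci$gene_id), , drop = FALSE]
  arrayId <- integer(nrow(loci))
  nextId <- 0L
  for (sc in unique(loci$scaffold)) {
    i <- which(loci$scaffold == sc)
    # sorted by start: single-linkage chaining reduces to comparing each
    # locus with the running right-most end of the open array
    nextId <- nextId + 1L
    arrayId[i[1]] <- nextId
    if (length(i) > 1) {
      maxEnd <- loci$end[i[1]]
      for (k in 2:length(i)) {
        # gap = bases strictly between the nearest gene ends; overlap -> 0
        gap <- max(0, loci$start[i[k]] - maxEnd - 1)
        if (gap > window) nextId <- nextId + 1L
        arrayId[i[k]] <- nextId
        maxEnd <- max(maxEnd, loci$end[i[k]])
      }
    }
  }
  letters27 <- function(n) {
    # A, B, ..., Z, AA, AB, ... deterministic beyond 26 arrays
    if (n <= 26) LETTERS[n]
    else paste0(LETTERS[(n - 1) %/% 26], LETTERS[(n - 1) %% 26 + 1])
  }
  out <- do.call(rbind, lapply(seq_len(max(arrayId)), function(a) {
    i <- which(arrayId == a)
    i <- i[order(loci$start[i])]
    letter <- letters27(a)
    nm <- if (length(i) == 1) letter else paste0(letter, seq_along(i))
    data.frame(gene_id = loci$gene_id[i], name = nm, array_id = a,
               scaffold = loci$scaffold[i])
  }))
  rownames(out) <- NULL
  out
}

#' Conservative per-group loss calls
#'
#' A (group, family) pair is claimed lost only when no species of the group
#' has a retained hit for the family.
#'
#' @param presence logical matrix or data.frame, species x families.
#' @param groups named character vector mapping each species (names) to its
#'   group.
#' @return data.frame `group`, `family` of loss claims.
#' @export
inferLoss <- function(presence, groups) {
  presence <- as.matrix(presence)
  if (!all(rownames(presence) %in% names(groups)))
    stop("every species needs a group assignment")
  gs <- groups[rownames(presence)]
  if (any(table(groups) == 0)) stop("empty group")
  out <- do.call(rbind, lapply(unique(gs), function(g) {
    sub <- presence[gs == g, , drop = FALSE]
    lost <- colnames(presence)[colSums(sub) == 0]
    if (!length(lost)) return(NULL)
    data.frame(group = g, family = lost)
  }))
  if (is.null(out)) out <- data.frame(group = character(0),
                                      family = character(0))
  rownames(out) <- NULL
  out
}

#' Flag candidate retroduplications by intron loss
#'
#' Within one family clade, a locus is flagged when it is single-exon while
#' the median exon count of the other clade members is at least 2 (introns
#' present in relatives, absent in the copy).
#'
#' @param loci data.frame with `gene_id` and `exon_count` (>= 2 rows).
#' @return character vector of flagged gene ids.
#' @export
flagRetroduplication <- function(loci) {
  if (nrow(loci) < 2) stop("need at least 2 loci in the clade")
  flags <- vapply(seq_len(nrow(loci)), function(i) {
    loci$exon_count[i] == 1 &&
      median(loci$exon_count[-i]) >= 2
  }, logical(1))
  loci$gene_id[flags]
}

#' Filter BLAST tabular hits by coverage and identity
#'
#' Keeps hits with query coverage and percent identity at or above the
#' thresholds (inclusive). If `subject_locus` and `subject_length` columns
#' are present, only the longest passing isoform per subject locus is
#' retained. Order-preserving and idempotent.
#'
#' @param hits data.frame with at least `percent_identity` and
#'   `query_coverage` (both in percent).
#' @param minQcov,minPid thresholds in `[0, 100]`.
#' @return retained rows.
#' @export
filterBlastHits <- function(hits, minQcov = 90, minPid = 50) {
  if (minQcov < 0 || minQcov > 100 || minPid < 0 || minPid > 100)
    stop("thresholds must be in [0, 100]")
  keep <- hits$query_coverage >= minQcov & hits$percent_identity >= minPid
  out <- hits[keep, , drop = FALSE]
  if (all(c("subject_locus", "subject_length") %in% names(out)) &&
      nrow(out) > 0) {
    best <- unlist(lapply(split(seq_len(nrow(out)), out$subject_locus),
                          function(i) i[which.max(out$subject_length[i])]))
    out <- out[sort(best), , drop = FALSE]
  }
  out
}

#' Read a 12-column BLAST tabular file (outfmt 6 dialect)
#'
#' Standard columns are mapped to named fields; an optional 13th column is
#' read as query coverage (percent). When absent, coverage must be
#' supplied or derived by the caller before filtering.
#'
#' @param path tabular BLAST output.
#' @return data.frame with `query_id`, `subject_id`, `percent_identity`,
#'   alignment statistics, and `query_coverage` when present.
#' @export
readBlastTable <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  base <- c("query_id", "subject_id", "percent_identity", "length",
            "mismatches", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (ncol(tab) < 12) stop("expected at least 12 BLAST tabular columns")
  names(tab)[seq_len(12)] <- base
  if (ncol(tab) >= 13) names(tab)[13] <- "query_coverage"
  tab
}

#' Label gene-tree nodes as duplication or speciation
#'
#' Species-overlap rule: an internal node is a duplication node exactly
#' when the species sets of its child subtrees intersect. Non-binary nodes
#' are resolved deterministically first.
#'
#' @param geneTree `phylo`.
#' @param speciesOf named character vector mapping each tip label to its
#'   species.
#' @return data.frame `node` (ape node id), `label` (`"duplication"` or
#'   `"speciation"`).
#' @export
labelDuplicationNodes <- function(geneTree, speciesOf) {
  if (!all(geneTree$tip.label %in% names(speciesOf)))
    stop("every leaf needs a species assignment")
  tr <- ensureBinary(geneTree)
  ntip <- length(tr$tip.label)
  tipSpecies <- speciesOf[tr$tip.label]
  tr2 <- ape::reorder.phylo(tr, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tipSpecies[i]
  lab <- rep(NA_character_, ntip + tr$Nnode)
  for (k in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[k, 1]; ch <- tr2$edge[k, 2]
    kidSets <- sets[[par]]
    if (is.null(kidSets)) {
      sets[[par]] <- list(sets[[ch]])
    } else {
      sets[[par]] <- c(kidSets, list(sets[[ch]]))
    }
  }
  for (nd in (ntip + 1):(ntip + tr$Nnode)) {
    kids <- sets[[nd]]
    flat <- lapply(kids, unlist)
    dup <- FALSE
    if (length(flat) >= 2)
      for (i in seq_along(flat)) for (j in seq_along(flat))
        if (i < j && length(intersect(flat[[i]], flat[[j]]))) dup <- TRUE
    lab[nd] <- if (dup) "duplication" else "speciation"
    sets[[nd]] <- unlist(flat)
  }
  data.frame(node = (ntip + 1):(ntip + tr$Nnode),
             label = lab[(ntip + 1):(ntip + tr$Nnode)])
}
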