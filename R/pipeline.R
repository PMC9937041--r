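#' @include topology.R selection.R beb.R structure-map.R simulate.R
#' @include simulate-loci.R
NULL

PIPELINE_STAGES <- c("simulate", "scan", "topotest", "seltest",
                     "structcluster")
PIPELINE_GLOBAL <- c("seed", "outDir", "logLevel")

logStage <- function(level, stage, ...) {
  if (identical(level, "quiet")) return(invisible())
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), c(PIPELINE_STAGES, PIPELINE_GLOBAL))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$outDir)) stop("config needs outDir")
  paths <- c(config$scan$hits, config$scan$loci, config$scan$groups,
             config$topotest$aln, unlist(config$topotest$trees),
             config$seltest$aln, config$seltest$tree,
             config$structcluster$pdb, config$structcluster$msa,
             config$structcluster$sites)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  invisible(config)
}

buildModelFromConfig <- function(spec) {
  spec <- as.list(spec)
  kind <- spec$kind %||% "siteClass"
  spec$kind <- NULL
  switch(kind,
    aa = do.call(aminoAcidModel, spec),
    codon = do.call(codonModel, spec),
    siteClass = do.call(siteClassModel, spec),
    stop("unknown model kind '", kind, "'"))
}

runSimulateStage <- function(cfg, outDir, seed, level) {
  out <- list()
  if (!is.null(cfg$alignment)) {
    a <- cfg$alignment
    tree <- readMarkedTree(text = a$tree)
    model <- buildModelFromConfig(a$model)
    aln <- simulateAlignment(tree, model, a$nSites,
                             seed = a$seed %||% childSeed(seed, "sim.aln"))
    fa <- file.path(outDir, "simulated_alignment.fasta")
    writeAlignmentFasta(aln, fa)
    truthPath <- file.path(outDir, "simulated_alignment_truth.json")
    jsonlite::write_json(attr(aln, "truth"), truthPath, dataframe = "rows")
    logStage(level, "simulate", "alignment: ", nSites(aln), " sites -> ", fa)
    out$alignment <- list(fasta = fa, truth = truthPath)
  }
  if (!is.null(cfg$loci)) {
    l <- cfg$loci
    sim <- simulateLocusTable(
      species = l$species,
      arrays = as.data.frame(do.call(rbind, lapply(l$arrays, as.data.frame))),
      absences = l$absences %||% list(),
      nDecoys = l$nDecoys %||% 0,
      seed = l$seed %||% childSeed(seed, "sim.loci"))
    lp <- file.path(outDir, "simulated_loci.tsv")
    writeLocusTable(sim$loci, lp)
    hp <- file.path(outDir, "simulated_hits.domtblout")
    writeLines(sim$hitText, hp)
    tp <- file.path(outDir, "simulated_loci_truth.json")
    jsonlite::write_json(list(intronLoss = sim$truth$intronLoss,
                              absences = sim$truth$absences),
                         tp, auto_unbox = FALSE)
    logStage(level, "simulate", "loci: ", nrow(sim$loci), " loci -> ", lp)
    out$loci <- list(loci = lp, hits = hp, truth = tp)
  }
  if (!is.null(cfg$structure)) {
    s <- cfg$structure
    sim <- simulateStructure(s$nResidues, s$clusterSize %||% 0,
                             s$clusterRadius %||% 8,
                             seed = s$seed %||% childSeed(seed, "sim.struct"))
    pp <- file.path(outDir, "simulated_structure.pdb")
    writeLines(sim$pdbText, pp)
    tp <- file.path(outDir, "simulated_structure_truth.json")
    jsonlite::write_json(list(clusterResidues = sim$clusterResidues), tp)
    logStage(level, "simulate", "structure: ", s$nResidues,
             " residues -> ", pp)
    out$structure <- list(pdb = pp, truth = tp)
  }
  out
}

runScanStage <- function(cfg, outDir, level) {
  hits <- parseDomtblout(cfg$hits)
  kept <- filterHits(hits, cfg$evalue %||% 1e-6, cfg$evalue %||% 1e-6)
  loci <- readLocusTable(cfg$loci)
  keptLoci <- loci[loci$gene_id %in% kept$gene_id, , drop = FALSE]
  names_ <- do.call(rbind, lapply(split(keptLoci, keptLoci$species),
                                  function(sub) {
    nm <- assignNames(sub, window = cfg$window %||% 100000)
    nm$species <- sub$species[1]
    nm
  }))
  rownames(names_) <- NULL
  out <- list()
  np <- file.path(outDir, "family_names.tsv")
  write.table(names_, np, sep = "\t", quote = FALSE, row.names = FALSE)
  out$names <- np
  if (!is.null(cfg$groups)) {
    groups <- read.table(cfg$groups, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    gmap <- setNames(groups$group, groups$species)
    fams <- unique(loci$family %||% "family")
    pres <- vapply(fams, function(f)
      vapply(groups$species, function(sp)
        any(keptLoci$species == sp &
              (keptLoci$family %||% "family") == f), logical(1)),
      logical(nrow(groups)))
    pres <- matrix(pres, nrow = nrow(groups),
                   dimnames = list(groups$species, fams))
    losses <- inferLoss(pres, gmap)
    lp <- file.path(outDir, "loss_claims.tsv")
    write.table(losses, lp, sep = "\t", quote = FALSE, row.names = FALSE)
    out$losses <- lp
    logStage(level, "scan", nrow(losses), " loss claim(s)")
  }
  logStage(level, "scan", nrow(kept), "/", nrow(hits), " hits retained")
  out$retained <- kept
  out$assignments <- names_
  out
}

runTopotestStage <- function(cfg, outDir, level) {
  aln <- readAlignmentFasta(cfg$aln, flavor = cfg$flavor %||% "protein")
  trees <- lapply(cfg$trees, function(f) ape::read.tree(f))
  names(trees) <- names(cfg$trees) %||% basename(unlist(cfg$trees))
  model <- buildModelFromConfig(cfg$model %||%
                                  list(kind = "aa", name = "JTT",
                                       gammaShape = 1))
  free <- cfg$free %||% (if (inherits(model, "AAModel")) "gammaShape"
                         else character(0))
  cmp <- compareFixedTopologies(aln, trees, model, free = free)
  rp <- file.path(outDir, "topotest_report.json")
  jsonlite::write_json(
    list(logLik = as.list(cmp$logLik), best = cmp$best,
         ranking = cmp$ranking, pairs = cmp$pairs),
    rp, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  logStage(level, "topotest", "best topology: ", cmp$best)
  list(report = rp, comparison = cmp)
}

runSeltestStage <- function(cfg, outDir, level) {
  aln <- readAlignmentFasta(cfg$aln, flavor = "codon")
  tree <- readMarkedTree(cfg$tree)
  test <- cfg$test %||% "branch-site"
  bl <- cfg$branchLengths %||% "optimize"
  if (test == "branch-site") {
    pair <- fitBranchSitePair(aln, tree, branchLengths = bl)
    rep <- selectionReport(pair$null, pair$alt,
                           threshold = cfg$threshold %||% 0.5)
  } else {
    nullFit <- fitSiteModel(aln, tree, "M1a", branchLengths = bl)
    altFit <- fitSiteModel(aln, tree, "M2a", branchLengths = bl)
    rep <- selectionReport(nullFit, altFit,
                           threshold = cfg$threshold %||% 0.5)
  }
  sp <- file.path(outDir, "selected_sites.tsv")
  write.table(rep@sites, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  rp <- file.path(outDir, "selection_report.json")
  jsonlite::write_json(
    list(test = test, logLikNull = rep@nullFit@logLik,
         logLikAlt = rep@altFit@logLik, lrt = rep@lrt,
         proportionSelected = rep@proportionSelected,
         nSelected = sum(rep@sites$selected),
         caveat = paste("synonymous-rate variation and multinucleotide",
                        "substitutions are not modeled and can inflate",
                        "branch-site signals")),
    rp, auto_unbox = TRUE, digits = NA)
  logStage(level, "seltest", "LRT p = ", signif(rep@lrt$p, 3))
  list(report = rp, sites = sp, selection = rep)
}

runStructclusterStage <- function(cfg, outDir, seed, level) {
  struct <- parseStructure(cfg$pdb)
  struct <- computeAsa(struct, probeRadius = cfg$probeRadius %||% 1.4,
                       nPoints = cfg$nPoints %||% 960L)
  struct <- classifyExposed(struct,
                            ratioThreshold = cfg$ratioThreshold %||% 0.2)
  sites <- read.table(cfg$sites, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  selectedCols <- sites$site[sites$selected %in% c(TRUE, "TRUE")]
  if (!is.null(cfg$msa) && !is.null(cfg$query)) {
    msa <- readAlignmentFasta(cfg$msa, flavor = "protein")
    seqChars <- struct$residues$resname[struct$residues$hasCa]
    structSeq <- paste(ifelse(is.na(AA3[seqChars]), "X", AA3[seqChars]),
                      collapse = "")
    map <- mapAlignmentToStructure(msa, cfg$query, structSeq,
                                   struct$residues$resnum[
                                     struct$residues$hasCa])
    selected <- map$resnum[match(selectedCols, map$column)]
    unmapped <- sum(is.na(selected))
    if (unmapped) logStage(level, "structcluster", unmapped,
                           " selected site(s) not mappable to the structure")
    selected <- selected[!is.na(selected)]
  } else {
    selected <- selectedCols
  }
  res <- clusteringPermutationTest(
    selected, struct, restrictToExposed = cfg$restrictToExposed %||% TRUE,
    nPerm = cfg$nPerm %||% 1e4,
    seed = cfg$seed %||% childSeed(seed, "structcluster"))
  tp <- file.path(outDir, "residue_table.tsv")
  rt <- struct$residues
  rt$selected <- rt$resnum %in% selected
  write.table(rt[, c("resnum", "resname", "asa", "exposed", "selected")],
              tp, sep = "\t", quote = FALSE, row.names = FALSE)
  rp <- file.path(outDir, "cluster_test.json")
  jsonlite::write_json(
    list(observed = res@observed, nPerm = res@nPerm, b = res@nAsExtreme,
         p = res@p, seed = res@seed, statistic = res@statistic),
    rp, auto_unbox = TRUE, digits = NA)
  logStage(level, "structcluster", "permutation p = ", signif(res@p, 3))
  list(report = rp, residues = tp, result = res)
}

#' Run the analysis pipeline from a declarative config
#'
#' Stages (any subset): `simulate`, `scan`, `topotest`, `seltest`,
#' `structcluster`, executed in that dependency order. Every input path is
#' validated before any stage runs; unknown keys are rejected; each
#' stage's JSON output is embedded in the consolidated report; every
#' random operation derives its seed from the global `seed` unless a
#' per-stage seed is given. Rerunning an identical config reproduces the
#' deterministic outputs byte for byte.
#'
#' @param config a named list, or the path of a YAML file with the same
#'   structure. Top-level keys: stage blocks plus `seed`, `outDir`,
#'   `logLevel` (`"info"` or `"quiet"`).
#' @return the consolidated report (list), invisibly written to
#'   `outDir/report.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  validatePipelineConfig(config)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  level <- config$logLevel %||% "info"
  report <- list(seed = seed)
  for (stage in intersect(PIPELINE_STAGES, names(config))) {
    logStage(level, stage, "starting")
    report[[stage]] <- tryCatch(
      switch(stage,
        simulate = runSimulateStage(config$simulate, outDir, seed, level),
        scan = runScanStage(config$scan, outDir, level),
        topotest = runTopotestStage(config$topotest, outDir, level),
        seltest = runSeltestStage(config$seltest, outDir, level),
        structcluster = runStructclusterStage(config$structcluster, outDir,
                                              seed, level)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
  }
  jsonPath <- file.path(outDir, "report.json")
  serializable <- rapply(report, function(x)
    if (isVirtualClass(class(x)) || isS4(x) || is.function(x)) NULL else x,
    how = "replace")
  jsonlite::write_json(serializable, jsonPath, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  report$reportPath <- jsonPath
  invisible(report)
}

#' Render a pipeline report as human-readable text
#'
#' @param report list returned by [runPipeline()].
#' @return character vector of lines.
#' @export
renderReport <- function(report) {
  lines <- c("ponevo pipeline report",
             "======================")
  if (!is.null(report$seed)) lines <- c(lines, paste0("seed: ", report$seed))
  tt <- report$topotest$comparison
  if (!is.null(tt)) {
    lines <- c(lines, "", "Topology comparison (fixed candidate trees)",
               sprintf("  %-12s %14s  %s", "model", "logLik", "best"))
    for (nm in names(tt$logLik))
      lines <- c(lines, sprintf("  %-12s %14.4f  %s", nm, tt$logLik[[nm]],
                                if (nm == tt$best) "*" else ""))
    if (!is.null(tt$pairs))
      for (r in seq_len(nrow(tt$pairs)))
        lines <- c(lines, sprintf("  %s vs %s: 2dlnL = %.4f, p = %.4g",
                                  tt$pairs$null[r], tt$pairs$alt[r],
                                  tt$pairs$statistic[r], tt$pairs$p[r]))
  }
  sel <- report$seltest$selection
  if (!is.null(sel)) {
    lines <- c(lines, "", "Positive-selection test",
               sprintf("  lnL null: %.4f  lnL alt: %.4f", sel@nullFit@logLik,
                       sel@altFit@logLik),
               sprintf("  2dlnL = %.4f (df = %d), p = %.4g",
                       sel@lrt$statistic, sel@lrt$df, sel@lrt$p),
               sprintf("  proportion under selection: %.3f",
                       sel@proportionSelected),
               sprintf("  %d site(s) with BEB posterior > threshold",
                       sum(sel@sites$selected)))
  }
  cl <- report$structcluster$result
  if (!is.null(cl)) {
    lines <- c(lines, "", "Structural clustering of selected sites",
               sprintf("  observed %s = %.3f A", cl@statistic, cl@observed),
               sprintf("  permutation p = %.4g (N = %d)", cl@p,
                       as.integer(cl@nPerm)))
  }
  lines
}
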