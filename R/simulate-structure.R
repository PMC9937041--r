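#' @include ponevo-package.R
NULL

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Simulate a pseudo-structure with an optional planted residue cluster
#'
#' Places C-alpha atoms on a self-avoiding random walk with ~3.8 Angstrom
#' steps; if a cluster is requested, the chosen residues are re-placed
#' inside a sphere of radius `clusterRadius` around a random walk point, so
#' the truth set is spatially compact. Emits PDB-format ATOM records
#' (C-alpha only) plus the truth set of clustered residue indices.
#'
#' @param nResidues number of residues (>= 2).
#' @param clusterSize number of clustered residues (0 for none).
#' @param clusterRadius cluster sphere radius in Angstrom.
#' @param seed integer seed.
#' @return list with `pdbText` (character lines), `coords` (n x 3 matrix),
#'   `clusterResidues` (integer truth set, possibly empty), `sequence`
#'   (one-letter).
#' @export
simulateStructure <- function(nResidues, clusterSize = 0, clusterRadius = 8,
                              seed = 1) {
  nResidues <- as.integer(nResidues)
  if (nResidues < 2) stop("need at least 2 residues")
  if (clusterSize > nResidues)
    stop("clusterSize cannot exceed nResidues")
  if (clusterSize > 0) {
    # sphere packing sanity: ~3.3 A minimum separation inside the sphere
    cap <- floor((clusterRadius / 3.3 + 1)^3)
    if (clusterSize > cap)
      stop("infeasible geometry: ", clusterSize, " residues cannot fit in ",
           clusterRadius, " Angstrom radius")
  }
  withStream(seed, "structure", {
    step <- 3.8
    minSep <- 3.5
    coords <- matrix(NA_real_, nResidues, 3)
    coords[1, ] <- 0
    for (i in 2:nResidues) {
      placed <- FALSE
      for (try in 1:200) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- coords[i - 1, ] + step * u
        d2 <- rowSums((coords[seq_len(i - 2), , drop = FALSE] -
                         rep(cand, each = max(0, i - 2)))^2)
        if (i == 2 || all(d2 >= minSep^2)) {
          coords[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) coords[i, ] <- coords[i - 1, ] + step * u  # give up cleanly
    }
    clusterResidues <- integer(0)
    if (clusterSize > 0) {
      clusterResidues <- sort(sample.int(nResidues, clusterSize))
      center <- coords[sample.int(nResidues, 1), ]
      for (ri in clusterResidues) {
        repeat {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          r <- clusterRadius * runif(1)^(1 / 3)
          cand <- center + r * u
          others <- setdiff(clusterResidues[clusterResidues < ri], ri)
          if (!length(others) ||
              min(rowSums((coords[others, , drop = FALSE] -
                             rep(cand, each = length(others)))^2)) >= 1.0) {
            coords[ri, ] <- cand; break
          }
        }
      }
    }
    resNames <- sample(names(AA3), nResidues, replace = TRUE)
    pdbText <- vapply(seq_len(nResidues), function(i)
      sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
              i, resNames[i], i, coords[i, 1], coords[i, 2], coords[i, 3],
              1.00, 20.00), character(1))
    pdbText <- c(pdbText, "TER", "END")
    list(pdbText = pdbText, coords = coords,
         clusterResidues = clusterResidues,
         sequence = paste(AA3[resNames], collapse = ""))
  })
}
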