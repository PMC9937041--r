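#' @include simulate-structure.R
NULL

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# theoretical maximum accessible surface areas per residue type (Angstrom^2),
# used to turn absolute ASA into an exposure ratio
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Parse ATOM records of a PDB file into residues
#'
#' Reads coordinates with `bio3d`, keeps ATOM records only, resolves
#' alternate locations by highest occupancy (ties: first seen), assigns
#' van der Waals radii by element, and groups atoms by (chain, residue
#' number). Residues without a C-alpha are retained but flagged, and are
#' excluded from distance-based statistics downstream.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @return list with `residues` (data.frame: chain, resnum, resname,
#'   hasCa, cax, cay, caz, asa, exposed) and `atoms` (data.frame with
#'   element, radius, coordinates, residue keys).
#' @export
parseStructure <- function(pdb) {
  if (length(pdb) > 1 || grepl("\n", pdb) || !file.exists(pdb)) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(pdb, tf)
    on.exit(unlink(tf))
    pdb <- tf
  }
  p <- bio3d::read.pdb(pdb, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found")
  # altloc resolution: best occupancy, then first occurrence
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -replace(at$o, is.na(at$o), 1), seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                         substr(trimws(at$elety), 1, 1), trimws(at$elesy)))
  radius <- unname(VDW_RADII[elem])
  radius[is.na(radius)] <- 1.70
  atoms <- data.frame(chain = at$chain, resnum = at$resno,
                      resname = trimws(at$resid), name = trimws(at$elety),
                      element = elem, radius = radius,
                      x = at$x, y = at$y, z = at$z)
  atoms <- atoms[order(atoms$chain, atoms$resnum), , drop = FALSE]
  resKey <- paste(atoms$chain, atoms$resnum)
  resIdx <- split(seq_len(nrow(atoms)), factor(resKey, unique(resKey)))
  residues <- do.call(rbind, lapply(resIdx, function(i) {
    ca <- i[atoms$name[i] == "CA"]
    data.frame(chain = atoms$chain[i[1]], resnum = atoms$resnum[i[1]],
               resname = atoms$resname[i[1]],
               hasCa = length(ca) > 0,
               cax = if (length(ca)) atoms$x[ca[1]] else NA_real_,
               cay = if (length(ca)) atoms$y[ca[1]] else NA_real_,
               caz = if (length(ca)) atoms$z[ca[1]] else NA_real_,
               asa = NA_real_, exposed = NA)
  }))
  rownames(residues) <- NULL
  if (any(!residues$hasCa))
    message(sum(!residues$hasCa),
            " residue(s) without C-alpha retained but excluded from ",
            "distance statistics")
  list(residues = residues, atoms = atoms)
}

# deterministic near-uniform points on the unit sphere (golden spiral)
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Samples a deterministic golden-spiral point set on each atom's solvent
#' sphere (atom radius + probe radius) and counts the fraction of points
#' not buried inside any neighboring atom's solvent sphere; per-atom areas
#' are summed per residue into `residues$asa`.
#'
#' @param structure list from [parseStructure()].
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints sphere sample points per atom (>= 10).
#' @return the structure with `residues$asa` filled.
#' @export
computeAsa <- function(structure, probeRadius = 1.4, nPoints = 960L) {
  if (nPoints < 10) stop("nPoints must be >= 10")
  atoms <- structure$atoms
  n <- nrow(atoms)
  pts <- goldenSpiralPoints(nPoints)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rs <- atoms$radius + probeRadius
  asa <- numeric(n)
  maxR <- max(rs)
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - rep(xyz[i, ], each = n))^2)
    nb <- which(d2 < (rs[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rs[i] + rs[nb])^2]
    sp <- pts * rs[i] + rep(xyz[i, ], each = nPoints)
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dj <- rowSums((sp - rep(xyz[j, ], each = nPoints))^2)
        free <- free & dj >= rs[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    asa[i] <- 4 * pi * rs[i]^2 * frac
  }
  key <- paste(atoms$chain, atoms$resnum)
  resAsa <- tapply(asa, factor(key, unique(key)), sum)
  residues <- structure$residues
  rKey <- paste(residues$chain, residues$resnum)
  residues$asa <- as.numeric(resAsa[rKey])
  structure$residues <- residues
  structure$atomAsa <- asa
  structure
}

#' Classify residues as solvent-exposed
#'
#' A residue is exposed when its ASA is at least `ratioThreshold` times the
#' theoretical maximum ASA of its residue type (inclusive boundary).
#' Unknown residue types are treated as exposed and reported.
#'
#' @param structure list from [computeAsa()].
#' @param ratioThreshold exposure cutoff on asa / maxASA (default 0.2).
#' @return the structure with `residues$exposed` filled.
#' @export
classifyExposed <- function(structure, ratioThreshold = 0.2) {
  residues <- structure$residues
  if (all(is.na(residues$asa))) stop("run computeAsa() first")
  ref <- MAX_ASA[residues$resname]
  unknown <- is.na(ref)
  if (any(unknown))
    message("unknown residue type(s) treated as exposed: ",
            paste(unique(residues$resname[unknown]), collapse = ", "))
  residues$exposed <- unknown | (residues$asa / ref >= ratioThreshold)
  structure$residues <- residues
  structure
}
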