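test_that("pseudo-structures are deterministic and re-parse exactly", {
  s1 <- simulateStructure(100, clusterSize = 10, clusterRadius = 8, seed = 4)
  s2 <- simulateStructure(100, clusterSize = 10, clusterRadius = 8, seed = 4)
  expect_identical(s1$pdbText, s2$pdbText)
  expect_identical(s1$clusterResidues, s2$clusterResidues)
  expect_length(s1$clusterResidues, 10)
  parsed <- parseStructure(s1$pdbText)
  expect_identical(nrow(parsed$residues), 100L)
  expect_true(all(parsed$residues$hasCa))
  expect_lt(max(abs(as.matrix(parsed$residues[, c("cax", "cay", "caz")]) -
                      round(s1$coords, 3))), 1e-9)
  none <- simulateStructure(40, clusterSize = 0, seed = 4)
  expect_length(none$clusterResidues, 0)
  expect_error(simulateStructure(50, clusterSize = 60), "exceed")
  expect_error(simulateStructure(50, clusterSize = 40, clusterRadius = 2),
               "infeasible")
})

test_that("planted clusters are more compact than random subsets across seeds", {
  hits <- 0
  for (seed in 1:40) {
    s <- simulateStructure(100, clusterSize = 10, clusterRadius = 8,
                           seed = seed)
    planted <- bruteMeanPairwise(s$coords, s$clusterResidues)
    set.seed(seed + 1000)
    rand <- bruteMeanPairwise(s$coords, sample.int(100, 10))
    if (planted < rand) hits <- hits + 1
  }
  expect_gte(hits, 38)  # >= 95% of seeds
})

test_that("PDB parsing resolves altlocs by occupancy and rejects HETATM-only input", {
  pdb <- c(
    "ATOM      1  CA AALA A   1      11.000  10.000  10.000  0.60 20.00           C",
    "ATOM      2  CA BALA A   1      99.000  99.000  99.000  0.40 20.00           C",
    "ATOM      3  CA  GLY A   2      13.800  10.000  10.000  1.00 20.00           C",
    "END")
  parsed <- parseStructure(pdb)
  expect_identical(nrow(parsed$residues), 2L)
  expect_equal(parsed$residues$cax[1], 11.0)
  # when the B conformer has the higher occupancy it wins
  pdbB <- sub("0.60", "0.30", pdb, fixed = TRUE)
  expect_equal(parseStructure(pdbB)$residues$cax[1], 99.0)
  het <- c(paste0("HETATM    1  O   HOH A   1      ",
                  "10.000  10.000  10.000  1.00 20.00           O"), "END")
  expect_error(parseStructure(het), "ATOM")
})

test_that("Shrake-Rupley ASA matches analytic spheres", {
  mk <- function(lines) computeAsa(parseStructure(c(lines, "END")))
  atomLine <- function(serial, res, resno, x, y, z)
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, res, resno, x, y, z, 1.0, 20.0)
  # single isolated atom: full solvent sphere
  s1 <- mk(atomLine(1, "ALA", 1, 0, 0, 0))
  full <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s1$residues$asa, full, tolerance = 0.01 * full)
  # two atoms far apart: two full spheres
  s2 <- mk(c(atomLine(1, "ALA", 1, 0, 0, 0), atomLine(2, "GLY", 2, 50, 0, 0)))
  expect_equal(sum(s2$residues$asa), 2 * full, tolerance = 0.01 * 2 * full)
  # two coincident atoms: the pair exposes one sphere in total
  s3 <- mk(c(atomLine(1, "ALA", 1, 0, 0, 0), atomLine(2, "GLY", 2, 0, 0, 0)))
  expect_equal(sum(s3$residues$asa), full, tolerance = 0.02 * full)
  expect_error(computeAsa(parseStructure(atomLine(1, "ALA", 1, 0, 0, 0)),
                          nPoints = 5), "nPoints")
})

test_that("ASA is invariant under rigid-body motion", {
  s <- simulateStructure(60, seed = 8)
  a1 <- computeAsa(parseStructure(s$pdbText))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  moved <- s$coords %*% R + rep(c(5, -3, 11), each = 60)
  pdb2 <- vapply(seq_len(60), function(i)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, i, moved[i, 1], moved[i, 2], moved[i, 3], 1.0, 20.0),
    character(1))
  a2 <- computeAsa(parseStructure(c(pdb2, "END")))
  # total ASA within the 0.5% sampling tolerance; per-residue deviations
  # are bounded by the per-atom sampling error of the point set
  expect_lt(abs(sum(a1$residues$asa) - sum(a2$residues$asa)) /
              sum(a1$residues$asa), 0.005)
  expect_lt(max(abs(a1$residues$asa - a2$residues$asa)) /
              mean(a1$residues$asa), 0.05)
})

test_that("exposure classification is an inclusive ratio threshold", {
  s <- simulateStructure(30, seed = 12)
  s <- computeAsa(parseStructure(s$pdbText))
  s <- classifyExposed(s, ratioThreshold = 0.2)
  ref <- ponevo:::MAX_ASA[s$residues$resname]
  brute <- (s$residues$asa / ref) >= 0.2
  expect_identical(s$residues$exposed, unname(brute))
  # an isolated residue is exposed
  iso <- computeAsa(parseStructure(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 20.00           C",
    "END")))
  expect_true(classifyExposed(iso)$residues$exposed)
  # boundary inclusivity: threshold exactly at the ratio keeps the residue
  ratio <- iso$residues$asa / ponevo:::MAX_ASA["ALA"]
  expect_true(classifyExposed(iso, ratioThreshold = ratio)$residues$exposed)
})

test_that("alignment-to-structure mapping walks gaps correctly", {
  msa <- phyloAlignment(c(query = "AR-ND", other = "ARKND"), "protein")
  map <- mapAlignmentToStructure(msa, "query", "ARND")
  expect_identical(map$column, c(1L, 2L, 4L, 5L))
  expect_identical(map$resnum, 1:4)
  # identity when ungapped
  msa2 <- phyloAlignment(c(query = "ARND", o = "ARNE"), "protein")
  map2 <- mapAlignmentToStructure(msa2, "query", "ARND")
  expect_identical(map2$column, map2$resnum)
  expect_error(mapAlignmentToStructure(msa, "absent", "ARND"), "not in")
  expect_error(mapAlignmentToStructure(msa, "query", "WWWW"), "disagree")
  # planted random offsets are recovered
  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    seqChars <- sample(ponevo:::AA_ALPHABET, n, replace = TRUE)
    gapCols <- sort(sample(seq_len(n + 10), 10))
    row <- character(n + 10); row[] <- NA
    row[gapCols] <- "-"
    row[setdiff(seq_len(n + 10), gapCols)] <- seqChars
    msa3 <- phyloAlignment(c(query = paste(row, collapse = ""),
                             o = paste(rep("A", n + 10), collapse = "")),
                           "protein")
    m3 <- mapAlignmentToStructure(msa3, "query", paste(seqChars,
                                                       collapse = ""))
    expect_identical(m3$column, setdiff(seq_len(n + 10), gapCols))
    expect_identical(m3$resnum, seq_len(n))
  }
})

test_that("the clustering permutation test behaves at its boundaries", {
  s <- simulateStructure(30, seed = 14)
  st <- classifyExposed(computeAsa(parseStructure(s$pdbText)))
  pool <- st$residues$resnum[st$residues$exposed]
  # selected = whole pool: every draw reproduces the same set, p = 1
  r <- clusteringPermutationTest(pool, st, nPerm = 200, seed = 3)
  expect_equal(r@p, 1)
  expect_gte(r@p, 1 / (r@nPerm + 1))
  expect_error(clusteringPermutationTest(pool[1], st, nPerm = 10, seed = 1),
               "at least 2")
  expect_error(clusteringPermutationTest(pool, st, nPerm = 10),
               "seed")
})

test_that("permutation p-values are invariant to rigid motion and relabeling", {
  s <- simulateStructure(80, clusterSize = 8, clusterRadius = 6, seed = 21)
  st <- classifyExposed(computeAsa(parseStructure(s$pdbText)))
  sel <- intersect(s$clusterResidues,
                   st$residues$resnum[st$residues$exposed])
  if (length(sel) >= 2) {
    p1 <- clusteringPermutationTest(sel, st, nPerm = 500, seed = 9)@p
    # rigid motion of all coordinates
    st2 <- st
    xyz <- as.matrix(st2$residues[, c("cax", "cay", "caz")])
    theta <- 1.1
    R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                  -sin(theta), 0, cos(theta)), 3, 3)
    xyz <- xyz %*% R + rep(c(-4, 2, 7), each = nrow(xyz))
    st2$residues[, c("cax", "cay", "caz")] <- xyz
    p2 <- clusteringPermutationTest(sel, st2, nPerm = 500, seed = 9)@p
    expect_equal(p1, p2)
  } else succeed("planted cluster fell outside the exposed pool")
})
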