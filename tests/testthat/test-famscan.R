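domLine <- function(target, fullE, domE) {
  paste(target, "-", 400, "arylesterase", "PF01731.21", 243, fullE, 100.0,
        0.1, 1, 1, domE, domE, 95.0, 0.1, 5, 240, 20, 260, 10, 270, 0.95,
        "-", sep = " ")
}

test_that("domtblout parsing aggregates domains per gene", {
  expect_identical(nrow(parseDomtblout(c("# comment", "# another"))), 0L)
  hits <- parseDomtblout(c(
    "# header",
    domLine("sp1|g1", "1e-10", "1e-8"),
    domLine("sp1|g1", "1e-10", "1e-3"),
    domLine("sp2|g2", "1e-12", "1e-11")))
  g1 <- hits[hits$gene_id == "g1", ]
  expect_equal(g1$best_domain_evalue, 1e-8)
  expect_identical(g1$n_domains, 2L)
  expect_identical(hits$species[hits$gene_id == "g2"], "sp2")
  expect_error(parseDomtblout("too few columns"), "line 1")
})

test_that("e-value filter applies both thresholds inclusively, ignoring domain count", {
  hits <- data.frame(
    species = "s", gene_id = c("reject", "boundary", "pass"),
    full_seq_evalue = c(1e-7, 1e-6, 1e-9),
    best_domain_evalue = c(1e-5, 1e-6, 1e-9),
    n_domains = c(1L, 5L, 2L))
  kept <- filterHits(hits)
  expect_identical(kept$gene_id, c("boundary", "pass"))
  # idempotent and order-preserving
  expect_identical(filterHits(kept), kept)
  expect_error(filterHits(hits, fullThresh = 0), "> 0")
})

test_that("filterHits matches a brute-force set comprehension on straddling hits", {
  set.seed(77)
  n <- 500
  hits <- data.frame(
    species = "s", gene_id = paste0("g", 1:n),
    full_seq_evalue = 10^runif(n, -8, -4),
    best_domain_evalue = 10^runif(n, -8, -4),
    n_domains = sample(1:4, n, TRUE))
  kept <- filterHits(hits)
  brute <- hits[hits$full_seq_evalue <= 1e-6 &
                  hits$best_domain_evalue <= 1e-6, ]
  expect_identical(kept, brute)
})

locusRow <- function(id, sc, start, end, exons = 9) {
  data.frame(species = "sp", gene_id = id, scaffold = sc, start = start,
             end = end, strand = "+", exon_count = exons)
}

test_that("tandem-array naming follows the 100-kb single-linkage convention", {
  # two loci 50 kb apart on one scaffold -> one lettered, numbered array
  two <- rbind(locusRow("g1", "sc1", 1, 2000),
               locusRow("g2", "sc1", 52000, 54000))
  nm <- assignNames(two)
  expect_identical(nm$name, c("A1", "A2"))
  # different scaffolds -> different letters, no numbers
  sep <- rbind(locusRow("g1", "sc1", 1, 2000),
               locusRow("g2", "sc2", 1, 2000))
  expect_identical(assignNames(sep)$name, c("A", "B"))
  # chaining: pairwise gaps of 90 kb each link A1-A3 even though the ends
  # are 180 kb apart
  chain <- rbind(locusRow("g1", "sc1", 1, 10000),
                 locusRow("g2", "sc1", 100000, 110000),
                 locusRow("g3", "sc1", 200000, 210000))
  expect_identical(assignNames(chain)$name, c("A1", "A2", "A3"))
  # beyond the window: split arrays
  apart <- rbind(locusRow("g1", "sc1", 1, 2000),
                 locusRow("g2", "sc1", 150000, 152000))
  expect_identical(assignNames(apart)$name, c("A", "B"))
  # invariant to input order
  shuffled <- chain[c(3, 1, 2), ]
  expect_identical(assignNames(shuffled), assignNames(chain))
  expect_error(assignNames(rbind(two, two)), "duplicate")
})

test_that("loss calls are conservative: all species of a group must lack the family", {
  pres <- matrix(c(FALSE, FALSE, FALSE,
                   TRUE, FALSE, FALSE), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("famA", "famB")))
  groups <- c(s1 = "G", s2 = "G", s3 = "G")
  claims <- inferLoss(pres, groups)
  expect_identical(claims$family, "famA")
  # randomized tables vs brute force
  set.seed(99)
  for (rep in 1:20) {
    ns <- 50
    sp <- paste0("s", 1:ns)
    gr <- setNames(sample(paste0("G", 1:8), ns, TRUE), sp)
    pres <- matrix(runif(ns * 4) < 0.15, ns, 4,
                   dimnames = list(sp, paste0("f", 1:4)))
    claims <- inferLoss(pres, gr)
    brute <- expand.grid(group = unique(gr), family = colnames(pres),
                         stringsAsFactors = FALSE)
    brute <- brute[apply(brute, 1, function(r)
      !any(pres[gr[rownames(pres)] == r[1], r[2]])), ]
    expect_identical(nrow(claims), nrow(brute))
    expect_setequal(paste(claims$group, claims$family),
                    paste(brute$group, brute$family))
  }
})

test_that("retroduplication flags require intron loss against an intron-rich clade", {
  clade <- data.frame(gene_id = paste0("g", 1:4),
                      exon_count = c(9, 9, 9, 1))
  expect_identical(flagRetroduplication(clade), "g4")
  allOne <- data.frame(gene_id = paste0("g", 1:3), exon_count = c(1, 1, 1))
  expect_length(flagRetroduplication(allOne), 0)
  allMulti <- data.frame(gene_id = paste0("g", 1:3), exon_count = c(4, 9, 2))
  expect_length(flagRetroduplication(allMulti), 0)
  expect_error(flagRetroduplication(clade[1, , drop = FALSE]), "at least 2")
})

test_that("BLAST filter applies inclusive thresholds and keeps the longest isoform", {
  hits <- data.frame(
    query_id = "q", subject_id = paste0("iso", 1:4),
    percent_identity = c(49, 50, 80, 85),
    query_coverage = c(95, 90, 92, 96),
    subject_locus = c("L1", "L1", "L2", "L2"),
    subject_length = c(300, 355, 300, 355))
  kept <- filterBlastHits(hits)
  # (95, 49) rejected by identity; (90, 50) retained at the boundary;
  # L2's two passing isoforms collapse to the longest
  expect_setequal(kept$subject_id, c("iso2", "iso4"))
  expect_identical(filterBlastHits(kept), kept)
})

test_that("species-overlap rule labels duplication nodes", {
  spOf <- c(spA_1 = "A", spB_1 = "B", spA_2 = "A", spB_2 = "B")
  tr <- ape::read.tree(text = "((spA_1:1,spB_1:1):1,(spA_2:1,spB_2:1):1);")
  lab <- labelDuplicationNodes(tr, spOf)
  root <- length(tr$tip.label) + 1
  expect_identical(lab$label[lab$node == root], "duplication")
  expect_identical(lab$label[lab$node != root],
                   c("speciation", "speciation"))
  # one gene per species, congruent with the species tree: no duplications
  tr2 <- ape::read.tree(text = "((x_A:1,x_B:1):1,x_C:1);")
  lab2 <- labelDuplicationNodes(tr2, c(x_A = "A", x_B = "B", x_C = "C"))
  expect_true(all(lab2$label == "speciation"))
  # two same-species leaves: the root is a duplication
  tr3 <- ape::read.tree(text = "(g1:1,g2:1);")
  lab3 <- labelDuplicationNodes(tr3, c(g1 = "A", g2 = "A"))
  expect_identical(lab3$label, "duplication")
})

test_that("synthetic locus tables round-trip through the parser and recover plants", {
  arrays <- data.frame(species = c("sp1", "sp1", "sp2"),
                       family = c("fam", "fam2", "fam"),
                       scaffold = c("sc1", "sc2", "sc1"),
                       nGenes = c(3L, 1L, 2L), gapBp = c(50000, 0, 20000),
                       intronLoss = c(TRUE, FALSE, FALSE))
  sim <- simulateLocusTable(c("sp1", "sp2", "sp3"), arrays,
                            absences = list(fam = "sp3"), nDecoys = 40,
                            seed = 5)
  hits <- parseDomtblout(sim$hitText)
  expect_identical(nrow(hits), nrow(sim$loci) + 40L)
  # planted genes all survive the e-value filter; decoys match their truth
  kept <- filterHits(hits)
  expect_true(all(sim$loci$gene_id %in% kept$gene_id))
  decoys <- hits[grepl("decoy", hits$gene_id), ]
  pass <- decoys$gene_id %in% kept$gene_id
  expect_identical(unname(pass[order(decoys$gene_id)]),
                   unname(sim$truth$decoyPass[order(names(
                     sim$truth$decoyPass))]))
  # the 3-gene 50-kb array is named as one tandem array
  sp1 <- sim$loci[sim$loci$species == "sp1", ]
  nm <- assignNames(sp1)
  famGenes <- sp1$gene_id[sp1$family == "fam"]
  expect_identical(nm$name[match(famGenes, nm$gene_id)],
                   c("A1", "A2", "A3"))
  # intron-loss plant is flagged
  clade <- sp1[sp1$family == "fam", ]
  expect_identical(flagRetroduplication(clade), sim$truth$intronLoss)
  # determinism
  sim2 <- simulateLocusTable(c("sp1", "sp2", "sp3"), arrays,
                             absences = list(fam = "sp3"), nDecoys = 40,
                             seed = 5)
  expect_identical(sim$hitText, sim2$hitText)
  expect_error(simulateLocusTable("sp1",
    data.frame(species = "sp1", family = "f", scaffold = "s",
               nGenes = 2L, gapBp = -5)), "gaps")
})
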