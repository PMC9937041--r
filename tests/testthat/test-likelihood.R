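test_that("two-leaf likelihoods match the 20-state closed form", {
  # single site, zero total branch length, identical residues -> log(pi)
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  aln1 <- phyloAlignment(c(a = "R", b = "R"), "protein")
  m <- aminoAcidModel("Poisson")
  expect_equal(treeLogLikelihood(aln1, tr0, m)@logLik, log(1 / 20),
               tolerance = 1e-12)
  # n sites with d differences at distance t: analytic 20-state formula
  tr <- ape::read.tree(text = "(a:0.08,b:0.17);")
  t <- 0.25; n <- 40; d <- 7
  aln <- phyloAlignment(c(
    a = paste(rep("A", n), collapse = ""),
    b = paste(c(rep("C", d), rep("A", n - d)), collapse = "")), "protein")
  psame <- (1 / 20) * (1 / 20 + 19 / 20 * exp(-20 * t / 19))
  pdiff <- (1 / 20) * (1 / 20 - 1 / 20 * exp(-20 * t / 19))
  expect_equal(treeLogLikelihood(aln, tr, m)@logLik,
               (n - d) * log(psame) + d * log(pdiff), tolerance = 1e-8)
})

test_that("pruning equals exhaustive interior-state enumeration", {
  set.seed(42)
  qm <- buildRateMatrix(aminoAcidModel("Poisson"))
  qmJ <- buildRateMatrix(aminoAcidModel("JTT"))
  for (rep in 1:12) {
    ntip <- sample(2:5, 1)
    tr <- ape::rtree(ntip, br = function(n) runif(n, 0.02, 0.6))
    states <- randomProteinStates(ntip, sample(1:6, 1))
    rownames(states) <- tr$tip.label
    aln <- statesToAlignment(states, tr$tip.label)
    use <- if (rep %% 2) qm else qmJ
    model <- if (rep %% 2) aminoAcidModel("Poisson") else aminoAcidModel("JTT")
    expect_equal(treeLogLikelihood(aln, tr, model)@logLik,
                 enumLogLikOneClass(tr, states, use$Q, use$freqs),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  tr <- treeSix()
  m <- aminoAcidModel("LG", gammaShape = 1.1)
  aln <- simulateAlignment(tr, m, 200, seed = 31)
  base <- treeLogLikelihood(aln, tr, m)@logLik
  for (node in c("a", "d", "f")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(treeLogLikelihood(aln, rerooted, m)@logLik, base,
                 tolerance = 1e-8)
  }
})

test_that("pruning matches an independent implementation on +G and +G+I models", {
  tr <- treeQuartet()
  m <- aminoAcidModel("JTT", gammaShape = 0.8)
  aln <- simulateAlignment(tr, m, 300, seed = 5)
  chars <- alignmentCharacters(aln)
  pd <- phangorn::phyDat(t(sapply(strsplit(chars, ""), identity)),
                         type = "AA")
  expect_equal(treeLogLikelihood(aln, tr, m)@logLik,
               phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 0.8)$logLik,
               tolerance = 1e-6)
  mI <- aminoAcidModel("JTT", gammaShape = 1.29, pInvariant = 0.068)
  expect_equal(treeLogLikelihood(aln, tr, mI)@logLik,
               phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 1.29,
                             inv = 0.068)$logLik,
               tolerance = 1e-6)
})

test_that("gaps are missing data: all-gap columns contribute zero log-likelihood", {
  tr <- treeQuartet()
  m <- aminoAcidModel("Poisson")
  aln <- phyloAlignment(c(a = "AR-", b = "AR-", c = "AV-", d = "A--"),
                        "protein")
  fit <- treeLogLikelihood(aln, tr, m)
  expect_equal(fit@siteLogLik[3], 0, tolerance = 1e-12)
  aln2 <- phyloAlignment(c(a = "AR", b = "AR", c = "AV", d = "A-"),
                         "protein")
  expect_equal(treeLogLikelihood(aln2, tr, m)@logLik, fit@logLik,
               tolerance = 1e-12)
})

test_that("input validation catches mismatches and bad branch lengths", {
  tr <- treeQuartet()
  m <- aminoAcidModel("Poisson")
  aln <- phyloAlignment(c(a = "A", b = "A", x = "A", d = "A"), "protein")
  expect_error(treeLogLikelihood(aln, tr, m), "names")
  tr2 <- tr; tr2$edge.length[2] <- -0.1
  aln2 <- phyloAlignment(c(a = "A", b = "A", c = "A", d = "A"), "protein")
  expect_error(treeLogLikelihood(aln2, tr2, m), "negative branch length")
})
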