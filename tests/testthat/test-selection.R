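# The heavier replicated calibrations live in test-acceptance.R; these
# blocks check the structural properties of the site and branch-site
# machinery on single seeded datasets.

test_that("site-class models validate their parameter domains", {
  expect_error(siteClassModel("M1a", p0 = 0.5, omega0 = 1.2), "omega0")
  expect_error(siteClassModel("M2a", p0 = 0.7, p1 = 0.5, omega0 = 0.5,
                              omega2 = 2), "p0 \\+ p1")
  expect_error(siteClassModel("M2a", p0 = 0.6, p1 = 0.2, omega0 = 0.5,
                              omega2 = 0.5), "omega2")
  m <- siteClassModel("M8", p0 = 0.9, p = 0.5, q = 1.5, omegaS = 3)
  cls <- ponevo:::siteClasses(m)
  expect_equal(sum(cls$weight), 1, tolerance = 1e-9)
  expect_equal(nrow(cls), 11)
})

test_that("beta discretization matches a quadrature oracle and converges in k", {
  p <- 0.6; q <- 1.8; k <- 10
  om <- ponevo:::discretizeBeta(p, q, k)
  breaks <- qbeta(seq(0, 1, length.out = k + 1), p, q)
  oracle <- vapply(seq_len(k), function(i)
    integrate(function(x) x * dbeta(x, p, q), breaks[i], breaks[i + 1],
              rel.tol = 1e-10)$value * k, numeric(1))
  expect_equal(om, oracle, tolerance = 1e-6)
  # M7 likelihood stabilizes as the discretization refines
  tr <- treeQuartet()
  aln <- simulateAlignment(tr, siteClassModel("M7", kappa = 2, p = 0.4,
                                              q = 1.2),
                           300, seed = 51)
  ll10 <- treeLogLikelihood(aln, tr, siteClassModel("M7", kappa = 2, p = 0.4,
                                                    q = 1.2, kBeta = 10))
  ll50 <- treeLogLikelihood(aln, tr, siteClassModel("M7", kappa = 2, p = 0.4,
                                                    q = 1.2, kBeta = 50))
  expect_lt(abs(ll10@logLik - ll50@logLik) / 300, 1e-3)
})

test_that("per-site class posteriors are normalized and match Bayes' rule", {
  tr <- treeQuartet()
  m <- siteClassModel("M1a", kappa = 2, p0 = 0.7, omega0 = 0.2)
  aln <- simulateAlignment(tr, m, 200, seed = 52)
  fit <- treeLogLikelihood(aln, tr, m)
  expect_true(all(abs(rowSums(fit@posteriors) - 1) < 1e-9))
  # brute-force Bayes rule on the two-class mixture, site by site
  f0 <- treeLogLikelihood(aln, tr, siteClassModel("M0", kappa = 2,
                                                  omega = 0.2))
  f1 <- treeLogLikelihood(aln, tr, siteClassModel("M0", kappa = 2,
                                                  omega = 1))
  # M0 scales its one-class mixture to mean rate 1, which rescales branch
  # lengths relative to the M1a mixture; recompute the class likelihoods
  # with the M1a scaling for an exact check
  cls <- ponevo:::siteClasses(m)
  prep <- ponevo:::prepLikelihood(aln, tr)
  sl <- ponevo:::siteClassLikList(prep, m)
  L <- do.call(cbind, sl$liks)
  post <- (L * rep(cls$weight, each = nrow(L))) /
    rowSums(L * rep(cls$weight, each = nrow(L)))
  expect_equal(unname(fit@posteriors[, 1]), unname(post[prep$map, 1]),
               tolerance = 1e-9)
})

test_that("M2a collapses to M1a at the p2 -> 0 boundary", {
  tr <- treeQuartet()
  aln <- simulateAlignment(tr, siteClassModel("M1a", kappa = 2, p0 = 0.7,
                                              omega0 = 0.2),
                           300, seed = 53)
  m1 <- siteClassModel("M1a", kappa = 2.3, p0 = 0.65, omega0 = 0.25)
  m2 <- siteClassModel("M2a", kappa = 2.3, p0 = 0.65, p1 = 0.35 - 1e-9,
                       omega0 = 0.25, omega2 = 3)
  l1 <- treeLogLikelihood(aln, tr, m1)@logLik
  l2 <- treeLogLikelihood(aln, tr, m2)@logLik
  expect_equal(l1, l2, tolerance = 1e-4)
})

test_that("site-model LRT accepts only nested pairs and detects planted selection", {
  tr <- treeSix()
  truthSel <- siteClassModel("M2a", kappa = 2, p0 = 0.6, p1 = 0.25,
                             omega0 = 0.2, omega2 = 4)
  aln <- simulateAlignment(tr, truthSel, 1000, seed = 54)
  f1 <- fitSiteModel(aln, tr, "M1a", branchLengths = "m0")
  f2 <- fitSiteModel(aln, tr, "M2a", branchLengths = "m0")
  expect_error(siteModelLrt(f2, f1), "nested")
  r <- siteModelLrt(f1, f2)
  expect_identical(r$df, 2L)
  # nesting invariant within optimizer tolerance
  expect_gte(f2@logLik, f1@logLik - 1e-4)
  # planted p2 = 0.15 at omega2 = 4 is detected
  expect_lt(r$p, 0.05)
  # recovered selection class is in the right region
  expect_gt(f2@parameters$omega2, 1.5)
})

test_that("branch-site alternative equals its null when omega2 is forced to 1", {
  tr <- markForeground(treeSix(), c("a", "b"))
  aln <- simulateAlignment(tr, siteClassModel("BranchSiteA_null", kappa = 2,
                                              p0 = 0.6, p1 = 0.3,
                                              omega0 = 0.3),
                           250, seed = 55)
  mNull <- siteClassModel("BranchSiteA_null", kappa = 2, p0 = 0.55,
                          p1 = 0.3, omega0 = 0.25)
  mAlt1 <- siteClassModel("BranchSiteA", kappa = 2, p0 = 0.55, p1 = 0.3,
                          omega0 = 0.25, omega2 = 1)
  expect_equal(treeLogLikelihood(aln, tr, mNull)@logLik,
               treeLogLikelihood(aln, tr, mAlt1)@logLik, tolerance = 1e-9)
})

test_that("with all branches foreground the branch-site model degenerates to M2a", {
  tr <- treeSix()
  attr(tr, "foreground") <- rep(TRUE, nrow(tr$edge))
  aln <- simulateAlignment(treeSix(), siteClassModel("M0", kappa = 2,
                                                     omega = 0.5),
                           200, seed = 56)
  p0 <- 0.5; p1 <- 0.3; w0 <- 0.2; w2 <- 3
  rest <- 1 - p0 - p1
  bs <- siteClassModel("BranchSiteA", kappa = 2, p0 = p0, p1 = p1,
                       omega0 = w0, omega2 = w2)
  # matched M2a with classes 2a and 2b merged at omega2; the two models
  # normalize their mean rate over different class omegas (the branch-site
  # scale uses background omegas), so equate the effective branch lengths
  # before comparing
  m2a <- siteClassModel("M2a", kappa = 2, p0 = p0, p1 = p1, omega0 = w0,
                        omega2 = w2)
  sBs <- ponevo:::siteClassEigens(bs, ponevo:::siteClasses(bs))$scale
  sM2a <- ponevo:::siteClassEigens(m2a, ponevo:::siteClasses(m2a))$scale
  trScaled <- tr
  trScaled$edge.length <- tr$edge.length * sM2a / sBs
  llBs <- treeLogLikelihood(aln, tr, bs)@logLik
  llM2a <- treeLogLikelihood(aln, trScaled, m2a)@logLik
  expect_equal(llBs, llM2a, tolerance = 1e-6)
})

test_that("branch-site pair fitting preserves nesting and finds planted selection", {
  tr <- markForeground(treeSix(), c("a", "b"))
  truth <- siteClassModel("BranchSiteA", kappa = 2, p0 = 0.58, p1 = 0.30,
                          omega0 = 0.2, omega2 = 5)
  aln <- simulateAlignment(tr, truth, 352, seed = 101)
  pair <- fitBranchSitePair(aln, tr, branchLengths = "m0")
  expect_gte(pair$alt@logLik, pair$null@logLik - 1e-4)
  expect_identical(pair$lrt$df, 1L)
  expect_lt(pair$lrt$p, 0.01)
  expect_gt(pair$alt@parameters$proportionSelected, 0.01)
  expect_error(branchSiteLrt(pair$alt, pair$alt), "pair")
})

test_that("selected-site identification follows the posterior threshold", {
  tr <- markForeground(treeSix(), c("a", "b"))
  truth <- siteClassModel("BranchSiteA", kappa = 2, p0 = 0.58, p1 = 0.30,
                          omega0 = 0.2, omega2 = 5)
  aln <- simulateAlignment(tr, truth, 352, seed = 101)
  pair <- fitBranchSitePair(aln, tr, branchLengths = "m0")
  rep <- selectionReport(pair$null, pair$alt)
  expect_true(all(abs(rowSums(pair$alt@posteriors) - 1) < 1e-9))
  expect_identical(rep@sites$selected, rep@sites$bebPosterior > 0.5)
  # truth enrichment: BEB posteriors concentrate on genuinely selected sites
  sel <- attr(aln, "truth")$class %in% c("2a", "2b")
  expect_gt(mean(rep@sites$bebPosterior[sel]),
            mean(rep@sites$bebPosterior[!sel]) + 0.2)
  hi <- rep@sites$bebPosterior > 0.95
  expect_gte(mean(sel[hi]), 0.8)
  expect_error(identifySelectedSites(pair$alt, threshold = 1.5), "threshold")
  expect_error(identifySelectedSites(pair$null), "selection class")
})
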