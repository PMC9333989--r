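test_that("codon frequency estimators behave on constructed compositions", {
  # equal nucleotide counts: F1x4 gives equal frequencies over 61 codons
  aln <- codonAln(c(a = paste(rep("ACGT", 3), collapse = ""),
                    b = paste(rep("ACGT", 3), collapse = "")))
  fr <- EvoMotif:::codonFrequencies(alnMatrix(aln), "F1x4")
  expect_equal(unname(fr$nucFreqs), rep(0.25, 4))
  expect_equal(fr$codonFreqs, rep(1 / 61, 61))
  expect_equal(sum(fr$codonFreqs), 1, tolerance = 1e-12)
})

test_that("the MG94xHKY generator is reversible and scaled consistently", {
  params <- codonModelParams(kappa = 3)
  norm <- EvoMotif:::codonNormalizer(params@kappa, params@nucFreqs,
                                     params@codonFreqs)
  Q <- EvoMotif:::buildCodonQ(params@kappa, 0.7, 1.9, params@nucFreqs) / norm
  pi <- params@codonFreqs
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # detailed balance
  D <- diag(pi)
  expect_lt(max(abs(D %*% Q - t(D %*% Q))), 1e-12)
  # neutral matrix has mean rate 1 after normalization
  Q1 <- EvoMotif:::buildCodonQ(params@kappa, 1, 1, params@nucFreqs) / norm
  expect_equal(-sum(pi * diag(Q1)), 1, tolerance = 1e-12)
})

test_that("site likelihood equals brute-force enumeration on a quartet", {
  tr <- quartetTree()
  params <- codonModelParams(kappa = 2.5)
  cod <- EvoMotif:::senseCodons()
  set.seed(31)
  for (rep in 1:3) {
    col <- sample(cod, 4)
    aln <- codonAln(setNames(col, c("A", "B", "C", "D")))
    ll <- siteLogLikelihood(aln, tr, 1, params, alpha = 0.8, beta = 1.4)
    norm <- EvoMotif:::codonNormalizer(params@kappa, params@nucFreqs,
                                       params@codonFreqs)
    Q <- EvoMotif:::buildCodonQ(params@kappa, 0.8, 1.4, params@nucFreqs) /
      norm
    eig <- EvoMotif:::reversibleEigen(Q, params@codonFreqs)
    brute <- bruteSiteLik(tr, match(col, cod)[match(tr$tip.label,
                                                    c("A", "B", "C", "D"))],
                          function(t) EvoMotif:::probMatrix(eig, t),
                          params@codonFreqs)
    expect_equal(ll, log(brute), tolerance = 1e-8)
  }
})

test_that("gaps are missing data and extreme rates drive the likelihood down", {
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  params <- codonModelParams()
  aln <- codonAln(c(A = "AAAAAG", B = "AAA---"))
  # site 2 is missing in B: likelihood reduces to the stationary frequency
  ll2 <- siteLogLikelihood(aln, tr, 2, params, 1, 1)
  expect_equal(ll2, log(1 / 61), tolerance = 1e-9)
  # two differing leaves with alpha = beta ~ 0: log-likelihood collapses
  aln2 <- codonAln(c(A = "AAA", B = "CCC"))
  llLow <- siteLogLikelihood(aln2, tr, 1, params, 1e-6, 1e-6)
  llOne <- siteLogLikelihood(aln2, tr, 1, params, 1, 1)
  expect_lt(llLow, llOne - 10)
})

test_that("invariant columns yield a null FEL result", {
  tr <- quartetTree()
  params <- codonModelParams()
  aln <- codonAln(c(A = "ATG", B = "ATG", C = "ATG", D = "ATG"))
  res <- felSiteTest(aln, tr, 1, params)
  expect_equal(res$lrt, 0)
  expect_equal(res$p, 1)
  expect_equal(res$class, "ns")
  expect_equal(res$alpha, 1e-6)
  expect_equal(res$beta, 1e-6)
})

test_that("a synonymous-only column is classified purifying with beta < alpha", {
  # AAA/AAG (both Lys) alternating across an 8-taxon balanced tree with
  # appreciable branch lengths: plenty of synonymous signal, none
  # nonsynonymous
  tr <- simulateTree(8, "balanced", height = 1.5)
  cods <- rep(c("AAA", "AAG"), 4)
  aln <- codonAln(setNames(cods, tr$tip.label))
  ng <- ngProportions(cods)
  expect_gt(ng["syn"], 0)
  expect_equal(unname(ng["nonsyn"]), 0L)
  params <- codonModelParams()
  res <- felSiteTest(aln, tr, 1, params)
  expect_lt(res$beta, res$alpha)   # sign agrees with the counting oracle
  expect_equal(res$class, "purifying")
  expect_lt(res$p, 0.1)
})

test_that("foreground = all branches matches the unpartitioned test", {
  tr <- quartetTree()
  params <- codonModelParams()
  aln <- codonAln(c(A = "ATGAAA", B = "ATGAAG", C = "ATAAAA", D = "ATGACA"))
  r1 <- felSiteTest(aln, tr, 2, params)
  r2 <- felSiteTest(aln, tr, 2, params,
                    foreground = seq_len(nrow(tr$edge)))
  expect_equal(r1$lrt, r2$lrt, tolerance = 1e-5)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-3)
  expect_true(is.na(r2$beta_bg) || r1$class == r2$class)
})

test_that("leaf relabeling with a matching tree relabeling changes nothing", {
  tr <- quartetTree()
  params <- codonModelParams()
  aln <- codonAln(c(A = "ATGAAA", B = "ATGAAG", C = "ATAAAA", D = "ATGACA"))
  res <- felSiteTest(aln, tr, 2, params)
  tr2 <- tr
  tr2$tip.label <- c("W", "X", "Y", "Z")[match(tr$tip.label,
                                               c("A", "B", "C", "D"))]
  rows <- apply(alnMatrix(aln), 1, paste0, collapse = "")
  aln2 <- codonAln(setNames(unname(rows),
                            c("W", "X", "Y", "Z")[match(alnIds(aln),
                                                        c("A", "B", "C",
                                                          "D"))]))
  res2 <- felSiteTest(aln2, tr2, 2, params)
  expect_equal(res$lrt, res2$lrt, tolerance = 1e-8)
  expect_equal(res$p, res2$p, tolerance = 1e-8)
})

test_that("global parameter estimation recovers kappa and finds the ts/tv floor", {
  # transversion-only divergence drives kappa to its floor
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  aln <- codonAln(c(A = "AAAACATTTCCCGGG", B = "ACAACTTTACCAGGC"))
  p <- estimateGlobalParams(aln, tr, "equal")
  expect_lte(p@kappa, 0.11)

  # simulated recovery within +/- 25 percent at 300 codons
  tr8 <- simulateTree(8, "yule", height = 0.8, seed = 21)
  sim <- simulateCodonAlignment(tr8, 300, codonModelParams(kappa = 2),
                                data.frame(fraction = 1, omega = 1),
                                seed = 22)
  fit <- estimateGlobalParams(sim$alignment, tr8, "F1x4")
  expect_gt(fit@kappa, 2 * 0.75)
  expect_lt(fit@kappa, 2 * 1.25)
  expect_gt(fit@treeScale, 0.75)
  expect_lt(fit@treeScale, 1.25)
})

test_that("felScan aggregates classes, reports reference numbering, and is deterministic", {
  tr <- simulateTree(8, "yule", height = 0.8, seed = 41)
  sim <- simulateCodonAlignment(tr, 12, codonModelParams(kappa = 2),
                                data.frame(fraction = 1, omega = 1),
                                seed = 42)
  params <- estimateGlobalParams(sim$alignment, tr, "F1x4")
  prof1 <- felScan(sim$alignment, tr, params)
  prof2 <- felScan(sim$alignment, tr, params)
  expect_identical(prof1@sites, prof2@sites)
  expect_equal(sum(prof1@counts), 12L)
  expect_true(all(prof1@sites$lrt >= -1e-6))
  expect_true(all(prof1@sites$lnl_null <= prof1@sites$lnl_alt + 1e-6))
  # all-invariant alignment: no significant sites
  alnInv <- codonAln(setNames(rep(paste(rep("ATG", 3), collapse = ""), 8),
                              tr$tip.label))
  profInv <- felScan(alnInv, tr, params)
  expect_equal(sum(profInv@sites$significant), 0L)
})
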