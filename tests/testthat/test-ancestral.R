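test_that("discrete-gamma categories have unit mean and sensible spread", {
  for (shape in c(0.3, 1, 4)) {
    r <- gammaCategoryRates(shape, 20)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
    # smaller shape = more heterogeneity
  }
  expect_gt(stats::sd(gammaCategoryRates(0.3, 20)),
            stats::sd(gammaCategoryRates(4, 20)))
  expect_equal(gammaCategoryRates(1.7, 1), 1)
})

test_that("the JTT generator is a proper reversible rate matrix", {
  model <- jttModel()
  Q <- EvoMotif:::aaRateMatrix(model)
  pi <- model@freqs
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(sum(pi), 1, tolerance = 1e-9)
  expect_lt(max(abs(diag(pi) %*% Q - t(diag(pi) %*% Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("tree likelihood agrees with phangorn and is root-invariant", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  tr <- ape::rtree(6)
  sim <- simulateProteinAlignment(tr, 40, jttModel(0.8, 4), seed = 2)
  aln <- sim$alignment
  ll <- EvoMotif:::aaLogLikelihood(aln, tr, jttModel(0.8, 4))
  rows <- apply(alnMatrix(aln), 1, paste0, collapse = "")
  tmp <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(rows), "\n", rows), tmp)
  dat <- phangorn::read.phyDat(tmp, format = "fasta", type = "AA")
  fit <- phangorn::pml(tr, dat, model = "JTT", k = 4, shape = 0.8)
  expect_equal(ll, as.numeric(fit$logLik), tolerance = 1e-4)

  # pulley principle: rerooting does not change the likelihood
  tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                   resolve.root = TRUE)
  ll2 <- EvoMotif:::aaLogLikelihood(aln, tr2, jttModel(0.8, 4))
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("marginal posteriors equal brute-force Bayes sums on a quartet", {
  tr <- quartetTree()
  model <- jttModel(0.7, 4)
  aln <- protAln(c(A = "GW", B = "GY", C = "AW", D = "SW"))
  asr <- marginalASR(aln, tr, model)
  eig <- EvoMotif:::aaEigen(model)
  rates <- gammaCategoryRates(0.7, 4)
  s <- EvoMotif:::aaStates(aln, tr$tip.label)
  for (site in 1:2) {
    for (node in 5:7) {
      post <- rep(0, 20)
      tot <- 0
      for (r in rates) {
        Pf <- function(t) EvoMotif:::probMatrix(eig, t * r)
        pr <- brutePosterior(tr, s[, site], Pf, model@freqs, node)
        lik <- bruteSiteLik(tr, s[, site], Pf, model@freqs)
        post <- post + pr * lik
        tot <- tot + lik
      }
      post <- post / tot
      expect_equal(unname(asr[[as.character(node)]]@posterior[, site]),
                   post, tolerance = 1e-8)
    }
  }
})

test_that("identity and limit cases of ancestral reconstruction", {
  # identical leaves: ancestor reproduces them, ambiguous sites stay X
  tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
  aln <- protAln(c(A = "GGXXG", B = "GGXXG"))
  a <- marginalASR(aln, tr, jttModel(1, 4))
  expect_equal(paste(a[["3"]]@mapSequence, collapse = ""), "GGXXG")
  expect_true(all(a[["3"]]@maxPosterior[c(1, 2, 5)] > 0.99))

  # all-gap columns under a node are reported as gaps
  alnG <- protAln(c(A = "G-", B = "G-"))
  aG <- marginalASR(alnG, tr, jttModel(1, 4))
  expect_equal(aG[["3"]]@mapSequence[2], "-")
  expect_true(is.na(aG[["3"]]@maxPosterior[2]))

  # near-zero terminal branch: node posterior concentrates on the leaf state
  tr2 <- ape::read.tree(text = "(A:1e-9,B:0.4);")
  aln2 <- protAln(c(A = "W", B = "A"))
  a2 <- marginalASR(aln2, tr2, jttModel(1, 1))
  expect_gt(a2[["3"]]@posterior["W", 1], 0.999)

  # posteriors sum to one everywhere informative
  expect_equal(colSums(a[["3"]]@posterior[, c(1, 2, 5)]), rep(1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gamma shape estimation recovers the simulating value", {
  tr <- simulateTree(16, "yule", height = 0.9, seed = 51)
  sim <- simulateProteinAlignment(tr, 200, jttModel(0.5, 8), seed = 52)
  shape <- estimateGammaShape(sim$alignment, tr, jttModel(1, 8))
  expect_gt(shape, 0.3)
  expect_lt(shape, 0.8)
  # invariant alignment: flat surface, default with warning
  alnInv <- protAln(setNames(rep("AAAA", 16), tr$tip.label))
  expect_warning(s0 <- estimateGammaShape(alnInv, tr, jttModel(1, 4)),
                 "flat")
  expect_equal(s0, 1.0)
})

test_that("neighbor joining recovers additive topologies and is equivariant", {
  # additive distances on a quartet: ((A,B),(C,D))
  tr <- quartetTree()
  d <- ape::cophenetic.phylo(tr)
  nj <- njTree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  expect_true(all(nj$edge.length >= 0))

  # ultrametric 3-taxon input pairs the close pair
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nj3 <- njTree(d3)
  expect_equal(sort(ape::cophenetic.phylo(nj3)["x", c("y", "z")]),
               sort(c(2, 8)), ignore_attr = TRUE)

  # label permutation permutes labels only
  perm <- c("C", "A", "D", "B")
  dP <- d[perm, perm]
  njP <- njTree(dP)
  expect_equal(ape::dist.topo(ape::unroot(njP), ape::unroot(nj)), 0,
               ignore_attr = TRUE)

  # 2-taxon degenerate input
  nj2 <- njTree(matrix(c(0, 3, 3, 0), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(length(nj2$tip.label), 2L)
})
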