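test_that("mutual information matches closed forms and the brute-force oracle", {
  # perfectly correlated 2-state columns at lambda = 0: exactly 1 bit
  rows <- c(rep("AA", 4), rep("CC", 4))
  aln <- protAln(setNames(rows, paste0("s", 1:8)))
  mi <- pairMutualInformation(aln, unitWeights(aln), pseudocount = 0,
                              minOccupancy = 0)
  expect_equal(mi[1, 2], 1.0, tolerance = 1e-12)
  expect_true(is.nan(mi[1, 1]))

  # joint counts exactly the product of marginals: MI = 0
  rows2 <- c("AA", "AC", "CA", "CC")
  aln2 <- protAln(setNames(rows2, paste0("s", 1:4)))
  mi2 <- pairMutualInformation(aln2, unitWeights(aln2), pseudocount = 0,
                               minOccupancy = 0)
  expect_equal(mi2[1, 2], 0, tolerance = 1e-12)

  # 6-sequence 3-column toy with pseudocount and non-unit weights vs the
  # independent double-loop oracle
  rows3 <- c("ACD", "ADD", "CCE", "CDE", "ADA", "CCD")
  aln3 <- protAln(setNames(rows3, paste0("s", 1:6)))
  wv <- c(s1 = 1, s2 = 0.5, s3 = 1.5, s4 = 1, s5 = 2, s6 = 0.8)
  w <- new("SequenceWeights", weights = wv, scheme = "unit")
  mi3 <- pairMutualInformation(aln3, w, pseudocount = 0.05,
                               minOccupancy = 0)
  m <- alnMatrix(aln3)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(mi3[i, j], bruteMI(m[, i], m[, j], unname(wv), 0.05),
                 tolerance = 1e-12)
  }

  # symmetry and nonnegativity at exact counts
  expect_equal(mi3, t(mi3))
  expect_true(all(mi3[upper.tri(mi3)] >= -1e-12))

  # duplicated column: MI equals the column entropy
  rows4 <- c("AA", "AA", "CC", "GG")
  aln4 <- protAln(setNames(rows4, paste0("s", 1:4)))
  mi4 <- pairMutualInformation(aln4, unitWeights(aln4), pseudocount = 0,
                               minOccupancy = 0)
  H <- -sum(c(.5, .25, .25) * log2(c(.5, .25, .25)))
  expect_equal(mi4[1, 2], H, tolerance = 1e-12)

  expect_error(pairMutualInformation(protAln(c(a = "A", b = "C")),
                                     pseudocount = 0),
               "insufficient-data")
})

test_that("APC correction matches hand arithmetic and edge cases", {
  # constant off-diagonal matrix: APC removes everything
  m <- matrix(2, 4, 4); diag(m) <- NaN
  a <- apcCorrect(m)
  expect_true(all(abs(a[upper.tri(a)]) < 1e-12))

  # 3-column matrix, hand-computed APC terms
  m2 <- matrix(NaN, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 1.0
  m2[1, 3] <- m2[3, 1] <- 0.0
  m2[2, 3] <- m2[3, 2] <- 0.0
  # row means: (.5, .5, 0); grand mean = 1/3
  # apc(1,2) = .5*.5/(1/3) = 0.75 ; apc(1,3) = .5*0/(1/3) = 0
  a2 <- apcCorrect(m2)
  expect_equal(a2[1, 2], 1.0 - 0.75, tolerance = 1e-12)
  expect_equal(a2[1, 3], 0.0, tolerance = 1e-12)
  expect_equal(a2[2, 3], 0.0, tolerance = 1e-12)

  # two columns: correction equals the single value, result 0
  m3 <- matrix(NaN, 2, 2); m3[1, 2] <- m3[2, 1] <- 0.7
  a3 <- apcCorrect(m3)
  expect_equal(a3[1, 2], 0, tolerance = 1e-12)

  # degenerate background skips with a warning
  m4 <- matrix(NaN, 2, 2); m4[1, 2] <- m4[2, 1] <- 0
  expect_warning(apcCorrect(m4), "degenerate")
})

test_that("permutation z is deterministic and ranks a planted pair first", {
  set.seed(99)
  n <- 24; L <- 20
  base <- matrix(sample(c("A", "C", "D", "E", "F", "G"), n * L, TRUE), n, L)
  # plant a perfectly covarying pair in columns 3 and 11
  key <- sample(c("K", "R", "H", "W"), n, TRUE)
  map <- c(K = "Y", R = "S", H = "T", W = "V")
  base[, 3] <- key
  base[, 11] <- map[key]
  rows <- apply(base, 1, paste0, collapse = "")
  aln <- protAln(setNames(rows, paste0("s", 1:n)))
  w <- unitWeights(aln)
  cov <- permutationZ(aln, w, nPerm = 100, seed = 5)
  p <- cov@pairs
  top <- p[which.max(p$z), ]
  expect_equal(sort(c(top$pos_i, top$pos_j)), c(3, 11))

  cov2 <- permutationZ(aln, w, nPerm = 100, seed = 5)
  expect_identical(cov@z, cov2@z)
  expect_error(permutationZ(aln, w, nPerm = 10), ">= 50")
})

test_that("calls are invariant to sequence order and residue recoding", {
  set.seed(7)
  n <- 16; L <- 12
  base <- matrix(sample(EvoMotif:::AA_ALPHABET[1:8], n * L, TRUE), n, L)
  rows <- apply(base, 1, paste0, collapse = "")
  aln <- protAln(setNames(rows, paste0("s", 1:n)))
  w <- unitWeights(aln)
  mi <- pairMutualInformation(aln, w, 0.05, minOccupancy = 0)

  # sequence order
  perm <- sample(n)
  alnP <- protAln(setNames(rows[perm], paste0("s", 1:n)[perm]))
  miP <- pairMutualInformation(alnP, unitWeights(alnP), 0.05,
                               minOccupancy = 0)
  expect_equal(unname(mi), unname(miP), tolerance = 1e-12)

  # bijective residue recoding
  recode <- setNames(EvoMotif:::AA_ALPHABET[c(20:13, 12:1)],
                     EvoMotif:::AA_ALPHABET[c(1:8, 9:20)])
  rowsR <- vapply(rows, function(r)
    paste0(recode[strsplit(r, "")[[1]]], collapse = ""), character(1))
  alnR <- protAln(setNames(unname(rowsR), paste0("s", 1:n)))
  miR <- pairMutualInformation(alnR, unitWeights(alnR), 0.05,
                               minOccupancy = 0)
  expect_equal(unname(mi), unname(miR), tolerance = 1e-12)
})

test_that("the two-tier conservation-gated calling rule applies its thresholds", {
  mkCov <- function(z, pos = c(10L, 20L)) {
    zm <- matrix(NaN, 2, 2); zm[1, 2] <- zm[2, 1] <- z
    mi <- matrix(NaN, 2, 2); mi[1, 2] <- mi[2, 1] <- 1
    dimnames(zm) <- dimnames(mi) <- list(pos, pos)
    new("CovariationResult", position = pos, mi = mi, miApc = mi, z = zm,
        pairs = data.frame(pos_i = pos[1], pos_j = pos[2], mi = 1,
                           mi_apc = 1, z = z),
        nPerm = 100L, seed = 1L)
  }
  # scored = FALSE sidesteps the mean-0/SD-1 validity that real profiles
  # carry; the caller reads zScore values directly.
  mkCons <- function(z1, z2, pos = c(10L, 20L)) {
    new("ConservationProfile", position = pos, rawScore = c(z1, z2),
        zScore = c(z1, z2), nEffective = c(10, 10),
        scored = c(FALSE, FALSE), method = "jsd")
  }
  # z = 5.0, cons (-0.9, -0.7): tier 1
  r1 <- callCovaryingPairs(mkCov(5), mkCons(-0.9, -0.7))
  expect_equal(nrow(r1@calls), 1L)
  expect_equal(r1@calls$tier, 1L)

  # z = 5.0, cons (-0.9, -0.2): tier 1 fails on the second residue and
  # z <= 8 blocks tier 2
  r2 <- callCovaryingPairs(mkCov(5), mkCons(-0.9, -0.2))
  expect_equal(nrow(r2@calls), 0L)

  # z = 9.0, cons (-0.4, -0.35): tier 2
  r3 <- callCovaryingPairs(mkCov(9), mkCons(-0.4, -0.35))
  expect_equal(nrow(r3@calls), 1L)
  expect_equal(r3@calls$tier, 2L)
})

test_that("the selection cap keeps only the top-z pairs", {
  set.seed(11)
  pos <- as.integer(1:30)
  zm <- matrix(NaN, 30, 30)
  vals <- runif(sum(upper.tri(zm)), 4.5, 12)
  zm[upper.tri(zm)] <- vals
  zm[lower.tri(zm)] <- t(zm)[lower.tri(zm)]
  mi <- zm
  dimnames(zm) <- dimnames(mi) <- list(pos, pos)
  ut <- which(upper.tri(zm), arr.ind = TRUE)
  pairs <- data.frame(pos_i = pos[ut[, 1]], pos_j = pos[ut[, 2]],
                      mi = mi[ut], mi_apc = mi[ut], z = zm[ut])
  cov <- new("CovariationResult", position = pos, mi = mi, miApc = mi,
             z = zm, pairs = pairs, nPerm = 100L, seed = 1L)
  cons <- new("ConservationProfile", position = pos,
              rawScore = rep(-1, 30), zScore = rep(-1, 30),
              nEffective = rep(10, 30), scored = rep(FALSE, 30),
              method = "jsd")
  # every pair passes tier 1, so the 5% cap binds: top-z pairs only
  res <- callCovaryingPairs(cov, cons, cap = 0.05)
  capN <- floor(0.05 * nrow(pairs))
  expect_equal(nrow(res@calls), capN)
  expect_equal(res@calls$z, sort(pairs$z, decreasing = TRUE)[seq_len(capN)])
  expect_lte(res@selectionFraction, 0.05)
})
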