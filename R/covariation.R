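# Integer-encode a protein alignment: 1..20 per AA_ALPHABET, NA for gaps and
# ambiguous residues.
encodeAlignment <- function(aln) {
  mat <- alnMatrix(aln)
  matrix(match(mat, AA_ALPHABET), nrow = nrow(mat),
         dimnames = list(alnIds(aln), NULL))
}

# Core weighted pairwise MI in bits over an integer-coded alignment.
# idx: nseq x ncol integer matrix (NA = missing); wv: per-sequence weights;
# lambda: additive pseudocount per joint cell (20x20 cells per pair).
# Marginals are derived from the pseudocounted joint table, so MI is exact
# for lambda = 0 and shrunk toward independence for lambda > 0.
miCore <- function(idx, wv, lambda) {
  n <- ncol(idx)
  obs <- !is.na(idx)
  S0 <- matrix(as.numeric(obs), nrow = nrow(idx))
  S0w <- S0 * wv
  Tm <- crossprod(S0w, S0) + 400 * lambda
  Ia <- vector("list", 20L)
  Wa <- vector("list", 20L)
  for (a in 1:20) {
    m <- matrix(as.numeric(obs & idx == a), nrow = nrow(idx))
    Ia[[a]] <- m
    Wa[[a]] <- m * wv
  }
  Ra <- lapply(1:20, function(a) crossprod(Wa[[a]], S0) + 20 * lambda)
  Cb <- lapply(1:20, function(b) crossprod(S0w, Ia[[b]]) + 20 * lambda)
  MI <- matrix(0, n, n)
  for (a in 1:20) {
    tWa <- t(Wa[[a]])
    for (b in 1:20) {
      J <- tWa %*% Ia[[b]] + lambda
      term <- (J / Tm) * log2(J * Tm / (Ra[[a]] * Cb[[b]]))
      if (lambda == 0) term[J == 0] <- 0
      MI <- MI + term
    }
  }
  MI <- (MI + t(MI)) / 2       # exact symmetry despite float noise
  diag(MI) <- NaN
  MI
}

# Columns meeting the occupancy rule shared with conservation scoring, and
# carrying at least two observed residue states: a constant column has
# identically zero mutual information under every permutation, so it cannot
# be scored for covariation.
scoredColumns <- function(aln, weights, minOccupancy = 0.5) {
  idx <- encodeAlignment(aln)
  wv <- weights@weights[alnIds(aln)]
  occ <- colSums((!is.na(idx)) * wv) / sum(wv) >= minOccupancy
  div <- apply(idx, 2L, function(s) length(unique(s[!is.na(s)]))) >= 2L
  occ & div
}

#' Pairwise column mutual information
#'
#' Weighted mutual information in bits between every pair of scored columns,
#' over the 20 amino-acid states with an additive pseudocount per joint
#' cell. Gaps and ambiguous residues are missing data; each pair uses the
#' sequences observed at both columns. Columns below the occupancy threshold
#' are excluded (NaN rows/columns in the result would be meaningless, so the
#' matrix covers scored columns only).
#'
#' @param aln protein \linkS4class{RefAlignment} with at least two scored
#'   columns.
#' @param weights \linkS4class{SequenceWeights}.
#' @param pseudocount additive pseudocount lambda per joint cell.
#' @param minOccupancy occupancy threshold for a column to be scored.
#' @return symmetric MI matrix (bits) with NaN diagonal; dimnames are
#'   reference positions; attribute \code{position} holds them as integers.
#' @export
pairMutualInformation <- function(aln, weights = sequenceWeights(aln),
                                  pseudocount = 0.05, minOccupancy = 0.5) {
  stopifnot(alnAlphabet(aln) == "protein")
  keep <- scoredColumns(aln, weights, minOccupancy)
  if (sum(keep) < 2L)
    stop("insufficient-data: fewer than 2 scored columns")
  idx <- encodeAlignment(aln)[, keep, drop = FALSE]
  wv <- weights@weights[alnIds(aln)]
  mi <- miCore(idx, wv, pseudocount)
  pos <- colToRef(aln)
  pos[is.na(pos)] <- seq_along(pos)[is.na(pos)]
  pos <- pos[keep]
  dimnames(mi) <- list(pos, pos)
  structure(mi, position = as.integer(pos))
}

#' Average-product correction (APC)
#'
#' Subtracts the product of row and column means divided by the grand mean
#' (diagonal and NaN entries excluded from the means), removing the shared
#' entropic/phylogenetic background that inflates raw MI.
#'
#' @param mi square symmetric MI matrix (NaN diagonal allowed).
#' @return corrected matrix of the same shape.
#' @export
apcCorrect <- function(mi) {
  stopifnot(nrow(mi) == ncol(mi))
  m <- mi
  diag(m) <- NA_real_
  rowMean <- rowMeans(m, na.rm = TRUE)
  grand <- mean(m[upper.tri(m)], na.rm = TRUE)
  if (!is.finite(grand) || grand <= 0) {
    warning("degenerate MI background (mean <= 0); APC skipped")
    return(mi)
  }
  apc <- outer(rowMean, rowMean) / grand
  out <- mi - apc
  diag(out) <- NaN
  out
}

#' Permutation z-scores for APC-corrected MI
#'
#' Builds a null distribution by shuffling residues (and gaps) within each
#' column independently, which destroys inter-column covariation while
#' preserving per-column composition and occupancy, recomputing MI + APC for
#' each permutation. The observed APC-corrected MI of each pair is then
#' standardized against its null mean and SD. Deterministic given
#' \code{seed}.
#'
#' @param aln protein \linkS4class{RefAlignment}.
#' @param weights \linkS4class{SequenceWeights}.
#' @param nPerm number of permutations (>= 50).
#' @param seed integer RNG seed.
#' @param pseudocount pseudocount, as in \code{\link{pairMutualInformation}}.
#' @param minOccupancy occupancy threshold.
#' @return a \linkS4class{CovariationResult} with mi, miApc, z and a long
#'   pair table.
#' @export
permutationZ <- function(aln, weights = sequenceWeights(aln), nPerm = 100L,
                         seed = 1L, pseudocount = 0.05, minOccupancy = 0.5) {
  if (nPerm < 50L) stop("nPerm must be >= 50")
  mi <- pairMutualInformation(aln, weights, pseudocount, minOccupancy)
  pos <- attr(mi, "position")
  miApc <- apcCorrect(mi)
  keep <- scoredColumns(aln, weights, minOccupancy)
  idx <- encodeAlignment(aln)[, keep, drop = FALSE]
  wv <- weights@weights[alnIds(aln)]
  n <- ncol(idx)
  nseq <- nrow(idx)
  sumX <- matrix(0, n, n)
  sumX2 <- matrix(0, n, n)
  set.seed(as.integer(seed))
  for (p in seq_len(nPerm)) {
    permIdx <- idx
    for (j in seq_len(n)) permIdx[, j] <- idx[sample.int(nseq), j]
    permApc <- apcCorrect(miCore(permIdx, wv, pseudocount))
    sumX <- sumX + permApc
    sumX2 <- sumX2 + permApc^2
  }
  nullMean <- sumX / nPerm
  nullVar <- pmax(sumX2 / nPerm - nullMean^2, 0) * nPerm / (nPerm - 1)
  nullSD <- sqrt(nullVar)
  z <- (miApc - nullMean) / nullSD
  z[nullSD <= 1e-12] <- 0
  diag(z) <- NaN
  dimnames(z) <- dimnames(mi)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  pairs <- data.frame(pos_i = pos[ut[, 1]], pos_j = pos[ut[, 2]],
                      mi = mi[ut], mi_apc = miApc[ut], z = z[ut])
  mi2 <- mi; attributes(mi2) <- attributes(mi2)[c("dim", "dimnames")]
  new("CovariationResult", position = pos, mi = mi2, miApc = miApc, z = z,
      pairs = pairs, nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Call covarying residue pairs (two-tier conservation-gated rule)
#'
#' A pair is called tier 1 when its covariation score exceeds \code{t1z} and
#' both residues have conservation z-scores below \code{t1cons}; tier 2 when
#' the score exceeds \code{t2z} and both residues are below \code{t2cons}.
#' If the called set exceeds \code{cap} of all scored pairs, only the
#' top-scoring pairs up to the cap are kept (ties broken by lower positions;
#' the cap never suppresses the single best pair). Output sorted by score,
#' descending.
#'
#' @param cov a \linkS4class{CovariationResult}.
#' @param cons a \linkS4class{ConservationProfile} covering the same
#'   positions.
#' @param t1z,t1cons tier-1 score threshold and conservation bound.
#' @param t2z,t2cons tier-2 score threshold and conservation bound.
#' @param cap maximum fraction of scored pairs to retain.
#' @return a \linkS4class{CovariationCalls}.
#' @export
callCovaryingPairs <- function(cov, cons, t1z = 4, t1cons = -0.5,
                               t2z = 8, t2cons = -0.3, cap = 0.005) {
  consZ <- setNames(cons@zScore, cons@position)
  pairs <- cov@pairs
  ci <- consZ[as.character(pairs$pos_i)]
  cj <- consZ[as.character(pairs$pos_j)]
  tier1 <- pairs$z > t1z & ci < t1cons & cj < t1cons
  tier2 <- pairs$z > t2z & ci < t2cons & cj < t2cons
  tier1[is.na(tier1)] <- FALSE
  tier2[is.na(tier2)] <- FALSE
  called <- tier1 | tier2
  calls <- data.frame(pos_i = pairs$pos_i, pos_j = pairs$pos_j,
                      tier = ifelse(tier1, 1L, 2L), z = pairs$z,
                      cons_i = unname(ci), cons_j = unname(cj))[called, ]
  ord <- order(-calls$z, calls$pos_i, calls$pos_j)
  calls <- calls[ord, , drop = FALSE]
  nScored <- sum(is.finite(pairs$z))
  capN <- max(1L, floor(cap * nScored))
  if (nrow(calls) > capN) calls <- calls[seq_len(capN), , drop = FALSE]
  rownames(calls) <- NULL
  new("CovariationCalls", calls = calls,
      selectionFraction = if (nScored > 0) nrow(calls) / nScored else 0,
      cap = cap, nScoredPairs = as.integer(nScored))
}

#' Export covariation tables as TSV
#'
#' @param cov a \linkS4class{CovariationResult}.
#' @param calls optional \linkS4class{CovariationCalls}.
#' @param pairPath path for the full pair table.
#' @param callPath path for the calls table (if \code{calls} given).
#' @param matrixPath optional path for the square z matrix as CSV
#'   (positions as header and row names).
#' @export
writeCovariationTSV <- function(cov, pairPath, calls = NULL,
                                callPath = NULL, matrixPath = NULL) {
  write.table(cov@pairs, pairPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(calls) && !is.null(callPath))
    write.table(calls@calls, callPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(matrixPath))
    write.table(cov@z, matrixPath, sep = ",", quote = FALSE,
                col.names = NA)
  invisible(pairPath)
}
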