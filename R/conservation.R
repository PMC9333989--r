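# BLOSUM62 marginal amino-acid frequencies (Henikoff & Henikoff), used as the
# default background distribution for divergence-based conservation scores.
BLOSUM62_FREQS <- setNames(
  c(0.074, 0.052, 0.045, 0.054, 0.025, 0.034, 0.054, 0.074, 0.026, 0.068,
    0.099, 0.058, 0.025, 0.047, 0.039, 0.057, 0.051, 0.013, 0.032, 0.073),
  AA_ALPHABET)

#' Sequence weights for alignment column statistics
#'
#' Down-weights redundant sequences so that column statistics are not
#' dominated by densely sampled clades. Two schemes: \code{identity_cluster}
#' assigns each sequence 1/(cluster size) after single-linkage clustering at
#' a pairwise-identity threshold (default 0.62); \code{henikoff} uses
#' position-based weights. Weights are normalized to mean 1.
#'
#' @param aln a protein \linkS4class{RefAlignment}.
#' @param method weighting scheme.
#' @param threshold identity threshold for \code{identity_cluster}.
#' @return a \linkS4class{SequenceWeights}.
#' @export
sequenceWeights <- function(aln, method = c("identity_cluster", "henikoff"),
                            threshold = 0.62) {
  method <- match.arg(method)
  mat <- alnMatrix(aln)
  n <- nrow(mat)
  ids <- alnIds(aln)
  if (n == 1L) {
    warning("single sequence: weight set to 1")
    return(new("SequenceWeights", weights = setNames(1, ids),
               scheme = method))
  }
  obs <- matrix(mat %in% AA_ALPHABET, nrow = n)
  if (method == "identity_cluster") {
    parent <- seq_len(n)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      both <- obs[i, ] & obs[j, ]
      ident <- if (any(both)) mean(mat[i, both] == mat[j, both]) else 0
      if (ident >= threshold) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), findRoot, integer(1))
    size <- table(roots)
    w <- 1 / as.numeric(size[as.character(roots)])
  } else {
    w <- numeric(n)
    for (j in seq_len(ncol(mat))) {
      res <- mat[, j]
      ok <- obs[, j]
      if (!any(ok)) next
      counts <- table(res[ok])
      r <- length(counts)
      w[ok] <- w[ok] + 1 / (r * as.numeric(counts[res[ok]]))
    }
    if (all(w == 0)) w <- rep(1, n)
    w[w == 0] <- min(w[w > 0])
  }
  w <- w / mean(w)
  new("SequenceWeights", weights = setNames(w, ids), scheme = method)
}

# Weighted residue count matrix: 20 x nCol, gaps/ambiguous excluded.
weightedCounts <- function(aln, w) {
  mat <- alnMatrix(aln)
  wv <- w@weights[alnIds(aln)]
  counts <- matrix(0, nrow = 20L, ncol = ncol(mat),
                   dimnames = list(AA_ALPHABET, NULL))
  idx <- matrix(match(mat, AA_ALPHABET), nrow = nrow(mat))
  for (j in seq_len(ncol(mat))) {
    ok <- !is.na(idx[, j])
    if (any(ok))
      counts[, j] <- vapply(seq_len(20L), function(a)
        sum(wv[ok][idx[ok, j] == a]), numeric(1))
  }
  counts
}

#' Column conservation scores on the ConSurf scale convention
#'
#' Computes a raw information-theoretic score per column and z-normalizes it
#' across scored columns to mean 0 and SD 1, with the sign fixed so that
#' lower = more conserved. \code{jsd} (default) scores each column by the
#' negative Jensen-Shannon divergence between the weighted column residue
#' distribution and a background distribution (BLOSUM62 marginals);
#' \code{weighted_entropy} scores by weighted Shannon entropy in bits.
#' Columns whose weighted non-gap fraction falls below \code{minOccupancy}
#' are flagged not-scored and excluded from the normalization.
#'
#' @param aln protein \linkS4class{RefAlignment}.
#' @param weights a \linkS4class{SequenceWeights} (default identity_cluster
#'   at 0.62).
#' @param method scoring method.
#' @param background background residue frequencies for \code{jsd}.
#' @param minOccupancy minimum weighted non-gap fraction for a column to be
#'   scored.
#' @return a \linkS4class{ConservationProfile}.
#' @export
columnConservation <- function(aln, weights = sequenceWeights(aln),
                               method = c("jsd", "weighted_entropy"),
                               background = BLOSUM62_FREQS,
                               minOccupancy = 0.5) {
  method <- match.arg(method)
  stopifnot(alnAlphabet(aln) == "protein")
  counts <- weightedCounts(aln, weights)
  totW <- sum(weights@weights)
  nEff <- colSums(counts)
  scored <- nEff / totW >= minOccupancy
  bg <- background / sum(background)
  raw <- rep(NA_real_, ncol(counts))
  for (j in which(scored)) {
    p <- counts[, j] / nEff[j]
    raw[j] <- if (method == "jsd") {
      m <- (p + bg) / 2
      kl <- function(a, b) { nz <- a > 0; sum(a[nz] * log2(a[nz] / b[nz])) }
      -(0.5 * kl(p, m) + 0.5 * kl(bg, m))
    } else {
      nz <- p > 0
      -sum(p[nz] * log2(p[nz]))
    }
  }
  rs <- raw[scored]
  if (sum(scored) >= 2L) {
    s <- popSD(rs)
    if (s == 0) stop("normalization error: all scored columns identical")
    z <- (raw - mean(rs)) / s
  } else z <- rep(NA_real_, length(raw))
  z[!scored] <- NA_real_
  pos <- colToRef(aln)
  pos[is.na(pos)] <- seq_along(pos)[is.na(pos)]
  new("ConservationProfile", position = as.integer(pos), rawScore = raw,
      zScore = z, nEffective = nEff, scored = scored, method = method)
}

#' Export a conservation profile as TSV
#'
#' Columns: ref_position, raw_score, z_score, n_effective, scored.
#' @param profile a \linkS4class{ConservationProfile}.
#' @param path output path.
#' @export
writeConservationTSV <- function(profile, path) {
  df <- data.frame(ref_position = profile@position,
                   raw_score = profile@rawScore,
                   z_score = profile@zScore,
                   n_effective = profile@nEffective,
                   scored = profile@scored)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
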