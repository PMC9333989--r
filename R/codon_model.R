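# Universal genetic code machinery for the MG94xHKY codon model.
# 61 sense codons (stops excluded); single-nucleotide neighbor structure is
# precomputed once at load time.

NUCS <- c("A", "C", "G", "T")

.codonSetup <- local({
  done <- FALSE
  env <- new.env()
  function() {
    if (!done) {
      gc <- Biostrings::GENETIC_CODE
      all64 <- names(gc)
      sense <- all64[gc != "*"]
      env$codons <- sense
      env$aa <- unname(gc[sense])
      n <- length(sense)
      cm <- do.call(rbind, strsplit(sense, ""))
      # single-nt neighbor table: from, to, position, transition?, synonymous?
      from <- integer(); to <- integer(); posn <- integer()
      ts <- logical(); syn <- logical(); tnt <- integer()
      isTs <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
        (a == "C" & b == "T") | (a == "T" & b == "C")
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        diffs <- which(cm[i, ] != cm[j, ])
        if (length(diffs) == 1L) {
          from <- c(from, i); to <- c(to, j); posn <- c(posn, diffs)
          ts <- c(ts, isTs(cm[i, diffs], cm[j, diffs]))
          syn <- c(syn, env$aa[i] == env$aa[j])
          tnt <- c(tnt, match(cm[j, diffs], NUCS))
        }
      }
      env$nbr <- data.frame(from = from, to = to, pos = posn,
                            ts = ts, syn = syn, targetNuc = tnt)
      env$codonMat <- cm
      done <<- TRUE
    }
    env
  }
})

senseCodons <- function() .codonSetup()$codons

# Codon frequency estimators from a codon alignment matrix (cells = codon
# strings; "---"/"NNN" ignored).
codonFrequencies <- function(mat, freqModel = c("F1x4", "F3x4", "equal")) {
  freqModel <- match.arg(freqModel)
  env <- .codonSetup()
  ok <- grepl("^[ACGT]{3}$", mat)
  cells <- mat[ok]
  if (freqModel == "equal") {
    nucFreqs <- rep(0.25, 4)
    names(nucFreqs) <- NUCS
    codonFreqs <- rep(1 / 61, 61)
  } else if (freqModel == "F1x4") {
    nt <- unlist(strsplit(cells, ""), use.names = FALSE)
    cnt <- tabulate(match(nt, NUCS), 4L)
    nucFreqs <- setNames((cnt + 1) / (sum(cnt) + 4), NUCS)  # +1 guard
    codonFreqs <- apply(env$codonMat, 1L, function(cd)
      prod(nucFreqs[cd]))
    codonFreqs <- codonFreqs / sum(codonFreqs)
  } else {
    chars <- do.call(rbind, strsplit(cells, ""))
    nucFreqs <- sapply(1:3, function(p) {
      cnt <- tabulate(match(chars[, p], NUCS), 4L)
      (cnt + 1) / (sum(cnt) + 4)
    })
    rownames(nucFreqs) <- NUCS
    codonFreqs <- vapply(seq_len(61), function(i)
      prod(vapply(1:3, function(p) nucFreqs[env$codonMat[i, p], p],
                  numeric(1))), numeric(1))
    codonFreqs <- codonFreqs / sum(codonFreqs)
  }
  list(nucFreqs = nucFreqs, codonFreqs = unname(codonFreqs))
}

# MG94xHKY instantaneous rate matrix. Rates for single-nucleotide changes:
# kappa-weighted transitions, target-nucleotide frequency, multiplied by
# alpha (synonymous) or beta (nonsynonymous). Unnormalized; divide by
# codonNormalizer() to put branch lengths in neutral expected
# substitutions-per-codon units.
buildCodonQ <- function(kappa, alpha, beta, nucFreqs) {
  env <- .codonSetup()
  nbr <- env$nbr
  Q <- matrix(0, 61, 61)
  piT <- if (is.matrix(nucFreqs)) nucFreqs[cbind(nbr$targetNuc, nbr$pos)]
         else nucFreqs[nbr$targetNuc]
  rate <- ifelse(nbr$ts, kappa, 1) * piT * ifelse(nbr$syn, alpha, beta)
  Q[cbind(nbr$from, nbr$to)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

# Mean substitution rate of the neutral (alpha = beta = 1) model; fixed per
# parameter set so site-specific alpha/beta keep a common scale.
codonNormalizer <- function(kappa, nucFreqs, codonFreqs) {
  Q1 <- buildCodonQ(kappa, 1, 1, nucFreqs)
  -sum(codonFreqs * diag(Q1))
}

# Symmetrized eigendecomposition of a reversible rate matrix.
# P(t) = diag(1/d) U exp(L t) U' diag(d) with d = sqrt(pi).
reversibleEigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * Q
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values, U = e$vectors, d = d, dinv = 1 / d, pi = pi)
}

probMatrix <- function(eig, t) {
  P <- (eig$dinv %o% eig$d) *
    (eig$U %*% (exp(eig$vals * t) * t(eig$U)))
  P[P < 0] <- 0
  P
}

# --- Felsenstein pruning ------------------------------------------------
# Shared by the codon (61-state) and amino-acid (20-state) models.

# Single-site pruning with per-edge eigensystems. states: integer per tip
# (NA = missing). edgeEig: integer index into eigs per edge row of
# tree$edge. Returns log-likelihood. Uses delta-vector shortcuts at tips and
# per-edge rescaling; returns `floor` when the likelihood underflows to 0.
pruneSiteLogLik <- function(phy, states, eigs, edgeEig, edgeLen,
                            floor = -1e8) {
  nTip <- length(phy$tip.label)
  nstate <- length(eigs[[1]]$pi)
  po <- phy$poOrder
  cond <- phy$condTemplate
  logScale <- 0
  for (k in po) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    eig <- eigs[[edgeEig[k]]]
    ew <- exp(eig$vals * edgeLen[k])
    if (chi <= nTip) {
      s <- states[chi]
      if (is.na(s)) next          # missing tip: contribution is all-ones
      contrib <- eig$dinv * (eig$U %*% (ew * (eig$U[s, ] * eig$d[s])))
    } else {
      x <- cond[, chi - nTip]
      contrib <- eig$dinv * (eig$U %*% (ew * crossprod(eig$U, eig$d * x)))
    }
    contrib[contrib < 0] <- 0
    m <- max(contrib)
    if (m <= 0) return(floor)
    cond[, par - nTip] <- cond[, par - nTip] * (contrib / m)
    logScale <- logScale + log(m)
  }
  root <- phy$rootNode - nTip
  L <- sum(eigs[[1L]]$pi * cond[, root])
  if (L <= 0) return(floor)
  log(L) + logScale
}

# Precompute traversal order and scratch space on a tree; avoids repeating
# the reorder inside per-site optimization loops.
prepTree <- function(tree, nstate) {
  phy <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(phy$tip.label)
  phy$poOrder <- seq_len(nrow(phy$edge))
  phy$rootNode <- phy$edge[nrow(phy$edge), 1L]
  phy$condTemplate <- matrix(1, nstate, phy$Nnode)
  phy
}

# Vectorized multi-site pruning under a single eigensystem. stateMat:
# nTip x nSites integer (NA = missing). Returns per-site log-likelihoods.
pruneSitesLogLik <- function(phy, stateMat, eig, edgeLen) {
  nTip <- length(phy$tip.label)
  nstate <- length(eig$pi)
  nSites <- ncol(stateMat)
  cond <- lapply(seq_len(phy$Nnode), function(i) matrix(1, nstate, nSites))
  logScale <- numeric(nSites)
  for (k in phy$poOrder) {
    par <- phy$edge[k, 1L] - nTip; chi <- phy$edge[k, 2L]
    P <- probMatrix(eig, edgeLen[k])
    if (chi <= nTip) {
      s <- stateMat[chi, ]
      contrib <- matrix(1, nstate, nSites)
      ok <- !is.na(s)
      if (any(ok)) contrib[, ok] <- P[, s[ok], drop = FALSE]
    } else {
      contrib <- P %*% cond[[chi - nTip]]
    }
    slab <- cond[[par]] * contrib
    m <- apply(slab, 2L, max)
    m[m <= 0] <- .Machine$double.xmin
    cond[[par]] <- sweep(slab, 2L, m, "/")
    logScale <- logScale + log(m)
  }
  root <- phy$rootNode - nTip
  log(colSums(eig$pi * cond[[root]])) + logScale
}
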