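# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (no pruning, no vectorized counting) so agreement is
# meaningful.

# Weighted pseudocounted mutual information between two residue columns by
# direct double loop over all 400 residue pairs.
bruteMI <- function(colA, colB, w, lambda) {
  alpha <- EvoMotif:::AA_ALPHABET
  ok <- colA %in% alpha & colB %in% alpha
  colA <- colA[ok]; colB <- colB[ok]; w <- w[ok]
  total <- sum(w) + 400 * lambda
  mi <- 0
  for (a in alpha) for (b in alpha) {
    jab <- sum(w[colA == a & colB == b]) + lambda
    pa <- sum(w[colA == a]) + 20 * lambda
    pb <- sum(w[colB == b]) + 20 * lambda
    if (jab > 0)
      mi <- mi + (jab / total) * log2(jab * total / (pa * pb))
  }
  mi
}

# Brute-force likelihood of one site on a rooted binary tree by summing
# over every assignment of states to internal nodes.
bruteSiteLik <- function(tree, tipStates, Pfun, pi) {
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  nstate <- length(pi)
  root <- nTip + 1L
  combos <- as.matrix(expand.grid(rep(list(seq_len(nstate)), nInt)))
  tot <- pi[combos[, root - nTip]]
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
    P <- Pfun(tree$edge.length[k])
    sp <- combos[, par - nTip]
    if (chi <= nTip) {
      s <- tipStates[chi]
      if (is.na(s)) next
      tot <- tot * P[sp, s]
    } else {
      tot <- tot * P[cbind(sp, combos[, chi - nTip])]
    }
  }
  sum(tot)
}

# Brute-force marginal posterior at one internal node (single rate class).
brutePosterior <- function(tree, tipStates, Pfun, pi, node) {
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  nstate <- length(pi)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nstate)), nInt)))
  w <- pi[combos[, 1L]]      # root is node nTip+1 = first internal column
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
    P <- Pfun(tree$edge.length[k])
    sp <- combos[, par - nTip]
    if (chi <= nTip) {
      s <- tipStates[chi]
      if (is.na(s)) next
      w <- w * P[sp, s]
    } else {
      w <- w * P[cbind(sp, combos[, chi - nTip])]
    }
  }
  post <- vapply(seq_len(nstate), function(s)
    sum(w[combos[, node - nTip] == s]), numeric(1))
  post / sum(post)
}

# Simplified Nei-Gojobori-style count of synonymous vs nonsynonymous
# differences over all sequence pairs (codons differing at one position
# only; multi-step differences are skipped, which suffices for constructed
# single-sweep columns).
ngProportions <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  syn <- 0L; nonsyn <- 0L
  n <- length(codons)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- codons[i]; b <- codons[j]
    if (a == b) next
    diffs <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (diffs != 1L) next
    if (gc[[a]] == gc[[b]]) syn <- syn + 1L else nonsyn <- nonsyn + 1L
  }
  c(syn = syn, nonsyn = nonsyn)
}

# Rank-based AUC for separating planted pairs from background by a score.
rankAUC <- function(score, isPlanted) {
  r <- rank(score)
  (mean(r[isPlanted]) - (sum(isPlanted) + 1) / 2) / sum(!isPlanted)
}
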