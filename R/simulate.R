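# Synthetic-data generators: trees, protein alignments with planted
# coevolving column pairs, codon alignments with planted omega classes, and
# assay tables with known ground truth. All generators are deterministic
# given their seed and return the truth alongside the data.

# Exact continuous-time Markov simulation of one lineage segment, so
# ancestral states at internal nodes are available as truth.
gillespieEvolve <- function(state, t, exitRate, jumpProb, onJump = NULL) {
  repeat {
    r <- exitRate[state]
    if (r <= 0) return(state)
    dt <- rexp(1L, r)
    if (dt > t) return(state)
    t <- t - dt
    newState <- sample.int(ncol(jumpProb), 1L, prob = jumpProb[state, ])
    if (!is.null(onJump)) onJump(state, newState)
    state <- newState
  }
}

jumpTable <- function(Q) {
  exit <- -diag(Q)
  P <- Q
  diag(P) <- 0
  pos <- exit > 0
  P[pos, ] <- P[pos, , drop = FALSE] / exit[pos]
  list(exit = exit, prob = P)
}

#' Simulate a phylogenetic tree
#'
#' Yule (pure-birth) trees rescaled to a given root-to-tip height, or
#' perfectly balanced trees with equal edge lengths. Deterministic per
#' seed.
#'
#' @param nTaxa number of tips (power of 2 for "balanced").
#' @param model "yule" or "balanced".
#' @param height root-to-tip height (expected substitutions per site).
#' @param seed integer RNG seed.
#' @return an \code{ape::phylo} with tip labels t1..tn.
#' @export
simulateTree <- function(nTaxa, model = c("yule", "balanced"), height = 1,
                         seed = 1L) {
  model <- match.arg(model)
  stopifnot(nTaxa >= 2L)
  if (model == "yule") {
    set.seed(as.integer(seed))
    tr <- ape::rphylo(nTaxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * height / depth
  } else {
    lev <- log2(nTaxa)
    if (abs(lev - round(lev)) > 1e-9)
      stop("balanced trees need a power-of-2 tip count")
    tr <- ape::stree(nTaxa, "balanced")
    tr$edge.length <- rep(height / lev, nrow(tr$edge))
  }
  tr$tip.label <- paste0("t", seq_len(nTaxa))
  tr
}

# Ancestor-first edge ordering (parents before children).
preorderEdges <- function(tree) {
  phy <- ape::reorder.phylo(tree, "postorder")
  list(phy = phy, order = rev(seq_len(nrow(phy$edge))),
       root = phy$edge[nrow(phy$edge), 1L])
}

#' Simulate a protein alignment with planted coevolving pairs
#'
#' Independent sites evolve under the amino-acid model with discrete-gamma
#' site rates, simulated exactly (Gillespie) along each edge so ancestral
#' states are recorded. Each planted pair evolves as a joint 400-state
#' chain: a random residue-compatibility bijection is drawn per pair, and
#' substitution rates toward compatible residue combinations are multiplied
#' by the coupling strength kappa while rates toward incompatible ones are
#' divided by it. kappa = 1 recovers independent evolution.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param nSites number of alignment columns.
#' @param model \linkS4class{AAModel}.
#' @param coevolvingPairs data.frame (i, j, kappa) of disjoint column pairs.
#' @param seed integer RNG seed.
#' @return list(alignment = \linkS4class{RefAlignment}, truth = list(...))
#'   where truth records per-site rates and categories, pair definitions
#'   with their compatibility tables, and ancestral sequences at every
#'   node.
#' @export
simulateProteinAlignment <- function(tree, nSites, model = jttModel(),
                                     coevolvingPairs = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  if (!is.null(coevolvingPairs)) {
    idx <- c(coevolvingPairs$i, coevolvingPairs$j)
    if (anyDuplicated(idx)) stop("configuration error: overlapping pairs")
    stopifnot(all(coevolvingPairs$kappa >= 1), all(idx >= 1),
              all(idx <= nSites))
  }
  Q0 <- aaRateMatrix(model)
  rates <- gammaCategoryRates(model@gammaShape, model@nCategories)
  cat <- sample.int(model@nCategories, nSites, replace = TRUE)
  siteRate <- rates[cat]
  pairCols <- integer()
  if (!is.null(coevolvingPairs))
    pairCols <- c(coevolvingPairs$i, coevolvingPairs$j)
  indepCols <- setdiff(seq_len(nSites), pairCols)
  siteRate[pairCols] <- 1       # planted pairs evolve at the mean rate
  cat[pairCols] <- NA_integer_
  ord <- preorderEdges(tree)
  phy <- ord$phy
  nTip <- length(phy$tip.label)
  nNode <- phy$Nnode
  states <- matrix(NA_integer_, nTip + nNode, nSites)
  jt <- jumpTable(Q0)
  # independent sites
  states[ord$root, indepCols] <- sample.int(20L, length(indepCols),
                                            replace = TRUE,
                                            prob = model@freqs)
  for (k in ord$order) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    len <- phy$edge.length[k]
    for (j in indepCols)
      states[chi, j] <- gillespieEvolve(states[par, j], len * siteRate[j],
                                        jt$exit, jt$prob)
  }
  # planted pairs: joint 400-state chains
  compat <- list()
  if (!is.null(coevolvingPairs)) {
    for (p in seq_len(nrow(coevolvingPairs))) {
      i <- coevolvingPairs$i[p]; j <- coevolvingPairs$j[p]
      kap <- coevolvingPairs$kappa[p]
      sigma <- sample.int(20L)   # compatibility bijection a -> sigma[a]
      compat[[p]] <- sigma
      Qj <- matrix(0, 400L, 400L)
      for (a in 1:20) for (b in 1:20) {
        s <- (a - 1L) * 20L + b
        for (a2 in seq_len(20L)[-a]) {
          mult <- if (sigma[a2] == b) kap else 1 / kap
          Qj[s, (a2 - 1L) * 20L + b] <- Q0[a, a2] * mult
        }
        for (b2 in seq_len(20L)[-b]) {
          mult <- if (sigma[a] == b2) kap else 1 / kap
          Qj[s, (a - 1L) * 20L + b2] <- Q0[b, b2] * mult
        }
      }
      diag(Qj) <- -rowSums(Qj)
      # Rescale so the joint chain substitutes at the pace of two
      # independent sites (mean rate 2 at stationarity); without this the
      # coupling mostly freezes the pair instead of correlating it.
      A <- rbind(t(Qj), rep(1, 400L))
      statD <- qr.solve(A, c(rep(0, 400L), 1))
      statD <- pmax(statD, 0); statD <- statD / sum(statD)
      meanRate <- -sum(statD * diag(Qj))
      Qj <- Qj * (2 / meanRate)
      jtj <- jumpTable(Qj)
      rootState <- sample.int(400L, 1L, prob = statD)
      joint <- integer(nTip + nNode)
      joint[ord$root] <- rootState
      for (k in ord$order) {
        par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
        joint[chi] <- gillespieEvolve(joint[par], phy$edge.length[k],
                                      jtj$exit, jtj$prob)
      }
      states[, i] <- (joint - 1L) %/% 20L + 1L
      states[, j] <- (joint - 1L) %% 20L + 1L
    }
  }
  chars <- matrix(AA_ALPHABET[states], nrow(states), nSites)
  aln <- newRefAlignment(phy$tip.label,
                         chars[seq_len(nTip), , drop = FALSE], "protein")
  anc <- chars[nTip + seq_len(nNode), , drop = FALSE]
  rownames(anc) <- as.character(nTip + seq_len(nNode))
  list(alignment = aln,
       truth = list(rateCategory = cat, siteRate = siteRate,
                    pairs = coevolvingPairs, compat = compat,
                    ancestralStates = anc, tree = phy, seed = seed))
}

#' Default codon model parameters for simulation
#'
#' @param kappa transition/transversion ratio.
#' @param freqModel frequency model ("equal" gives uniform codon
#'   frequencies).
#' @param treeScale branch-length multiplier.
#' @return a \linkS4class{CodonModelParams}.
#' @export
codonModelParams <- function(kappa = 2, freqModel = "equal",
                             treeScale = 1) {
  nucFreqs <- setNames(rep(0.25, 4), NUCS)
  new("CodonModelParams", kappa = kappa, codonFreqs = rep(1 / 61, 61),
      freqModel = freqModel, nucFreqs = nucFreqs, treeScale = treeScale)
}

#' Simulate a codon alignment with planted selection classes
#'
#' Each codon site is assigned an omega class (synonymous rate 1,
#' nonsynonymous rate omega) and evolved under MG94xHKY along the tree by
#' exact simulation. Substitution events are tallied by
#' transition/transversion and synonymous/nonsynonymous type.
#'
#' @param tree \code{ape::phylo}.
#' @param nCodons number of codon sites.
#' @param params \linkS4class{CodonModelParams}.
#' @param omegaClasses data.frame (fraction, omega), fractions summing
#'   to 1.
#' @param seed integer RNG seed.
#' @return list(alignment = codon \linkS4class{RefAlignment},
#'   truth = list(...)).
#' @export
simulateCodonAlignment <- function(tree, nCodons,
                                   params = codonModelParams(),
                                   omegaClasses = data.frame(fraction = 1,
                                                             omega = 1),
                                   seed = 1L) {
  stopifnot(abs(sum(omegaClasses$fraction) - 1) < 1e-9,
            all(omegaClasses$omega >= 0))
  set.seed(as.integer(seed))
  counts <- round(omegaClasses$fraction * nCodons)
  counts[1L] <- counts[1L] + (nCodons - sum(counts))
  classIdx <- sample(rep(seq_len(nrow(omegaClasses)), times = counts))
  norm <- codonNormalizer(params@kappa, params@nucFreqs, params@codonFreqs)
  env <- .codonSetup()
  nbr <- env$nbr
  tsMat <- matrix(FALSE, 61, 61)
  tsMat[cbind(nbr$from, nbr$to)] <- nbr$ts
  synMat <- matrix(FALSE, 61, 61)
  synMat[cbind(nbr$from, nbr$to)] <- nbr$syn
  counts <- new.env()
  counts$ts <- 0L; counts$tv <- 0L; counts$syn <- 0L; counts$nonsyn <- 0L
  onJump <- function(from, to) {
    if (tsMat[from, to]) counts$ts <- counts$ts + 1L
    else counts$tv <- counts$tv + 1L
    if (synMat[from, to]) counts$syn <- counts$syn + 1L
    else counts$nonsyn <- counts$nonsyn + 1L
  }
  jts <- lapply(omegaClasses$omega, function(om)
    jumpTable(buildCodonQ(params@kappa, 1, om, params@nucFreqs) / norm))
  ord <- preorderEdges(tree)
  phy <- ord$phy
  nTip <- length(phy$tip.label)
  nNode <- phy$Nnode
  states <- matrix(NA_integer_, nTip + nNode, nCodons)
  states[ord$root, ] <- sample.int(61L, nCodons, replace = TRUE,
                                   prob = params@codonFreqs)
  for (k in ord$order) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    len <- phy$edge.length[k] * params@treeScale
    for (j in seq_len(nCodons)) {
      jt <- jts[[classIdx[j]]]
      states[chi, j] <- gillespieEvolve(states[par, j], len, jt$exit,
                                        jt$prob, onJump)
    }
  }
  codons <- senseCodons()
  cells <- matrix(codons[states], nrow(states), nCodons)
  aln <- newRefAlignment(phy$tip.label,
                         cells[seq_len(nTip), , drop = FALSE], "codon")
  list(alignment = aln,
       truth = list(classIndex = classIdx,
                    omega = omegaClasses$omega[classIdx],
                    omegaClasses = omegaClasses,
                    events = list(ts = counts$ts, tv = counts$tv,
                                  syn = counts$syn, nonsyn = counts$nonsyn),
                    ancestralStates = cells[nTip + seq_len(nNode), ,
                                            drop = FALSE],
                    tree = phy, seed = seed))
}

#' Simulate assay tables with known ground truth
#'
#' Builds (i) 10-fraction gMFI profiles per channel as a bimodal design —
#' a detergent-resistant-membrane (DRM) peak at fractions 3-4 holding a
#' designed mass fraction and a detergent-soluble (DSM) peak at fractions
#' 8-9 holding the rest, fraction 1 at zero — with multiplicative
#' log-normal noise; (ii) an IL-2 dose-response table from a 4-parameter
#' logistic evaluated on the 1:3 titration from 30 uM with additive noise;
#' (iii) a paired null/agonist intensity histogram in which a designed
#' fraction of agonist-stimulated cells responds with log-normally shifted
#' intensity.
#'
#' @param design named list overriding any of the defaults documented in
#'   the implementation (DRM masses per channel, channel scales, noise
#'   sigma, replicate count, dose-curve parameters, responder fraction and
#'   histogram shape).
#' @param seed integer RNG seed.
#' @return list(fractions, doses, histograms, truth).
#' @export
simulateAssayTables <- function(design = list(), seed = 1L) {
  d <- modifyList(list(
    drmMass = c(CD4 = 0.45, Lck = 0.30, CTxB = 0.60),
    scale = c(CD4 = 2000, Lck = 800, CTxB = 1200),
    noiseSigma = 0.1, nReplicates = 3L,
    dose = list(top = 2000, bottom = 0, ec50_nM = 1000, hill = 1,
                noiseSD = 25, maxDose_nM = 30000, nDoses = 7L,
                dilution = 3),
    responder = list(fraction = 0.3, nCells = 10000L,
                     nullMeanLog = log(120), sdLog = 0.35,
                     shiftLog = log(12), nBins = 128L)), design)
  stopifnot(all(d$drmMass >= 0), all(d$drmMass <= 1),
            d$responder$fraction >= 0, d$responder$fraction <= 1)
  set.seed(as.integer(seed))
  drmShape <- c(0, 0.15, 0.35, 0.35, 0.15, 0, 0, 0, 0, 0)
  dsmShape <- c(0, 0, 0, 0, 0, 0.05, 0.20, 0.35, 0.30, 0.10)
  channels <- names(d$drmMass)
  profiles <- sapply(channels, function(ch)
    d$drmMass[ch] * drmShape + (1 - d$drmMass[ch]) * dsmShape)
  fr <- expand.grid(replicate = seq_len(d$nReplicates), fraction = 1:10,
                    channel = channels, stringsAsFactors = FALSE)
  fr$gmfi <- mapply(function(rep, fx, ch)
    d$scale[ch] * profiles[fx, ch] *
      if (d$noiseSigma > 0) rlnorm(1, 0, d$noiseSigma) else 1,
    fr$replicate, fr$fraction, fr$channel)
  doses <- d$dose$maxDose_nM / d$dose$dilution^(0:(d$dose$nDoses - 1L))
  dtab <- expand.grid(dose_nM = doses, replicate = seq_len(d$nReplicates))
  mu <- with(d$dose, bottom + (top - bottom) /
               (1 + (ec50_nM / dtab$dose_nM)^hill))
  dtab$response <- pmax(mu + rnorm(nrow(dtab), 0, d$dose$noiseSD), 0)
  r <- d$responder
  nullInt <- rlnorm(r$nCells, r$nullMeanLog, r$sdLog)
  nResp <- round(r$fraction * r$nCells)
  agoInt <- c(rlnorm(r$nCells - nResp, r$nullMeanLog, r$sdLog),
              rlnorm(nResp, r$nullMeanLog + r$shiftLog, r$sdLog))
  top <- max(nullInt, agoInt) * 1.001
  edges <- seq(0, top, length.out = r$nBins + 1L)
  mkHist <- function(x) {
    h <- hist(x, breaks = edges, plot = FALSE)
    data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1L],
               count = h$counts)
  }
  list(fractions = fr,
       doses = dtab,
       histograms = list(null = mkHist(nullInt), agonist = mkHist(agoInt)),
       truth = list(design = d, profiles = profiles,
                    drmMassPct = 100 * d$drmMass,
                    responderFraction = r$fraction,
                    doseMeans = with(d$dose, bottom + (top - bottom) /
                                      (1 + (ec50_nM / doses)^hill)),
                    doses_nM = doses, seed = seed))
}
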