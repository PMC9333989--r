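# Site-wise dN/dS estimation and testing in the fixed-effects-likelihood
# (FEL) style: per-codon synonymous (alpha) and nonsynonymous (beta) rates
# fitted by ML on a fixed tree under MG94xHKY, with a chi-square(1)
# likelihood-ratio test of beta = alpha, optionally restricted to a
# foreground branch set.

FEL_RATE_MIN <- 1e-6
FEL_RATE_MAX <- 50

# Integer codon states (1..61) per tip x site, rows ordered by tip labels.
codonStates <- function(caln, tipOrder) {
  mat <- alnMatrix(caln)[match(tipOrder, alnIds(caln)), , drop = FALSE]
  matrix(match(mat, senseCodons()), nrow = nrow(mat))
}

#' Edges of the clade spanned by a set of tips
#'
#' Returns the indices (rows of \code{tree$edge}) of every edge whose child
#' node lies inside the monophyletic group spanned by \code{tips}, including
#' the stem edge of their most recent common ancestor. Used to declare
#' foreground branch sets for selection tests.
#'
#' @param tree an \code{ape::phylo}.
#' @param tips tip labels spanning the clade.
#' @return integer vector of edge indices.
#' @export
foregroundEdges <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
    return(which(tree$edge[, 2L] == node))
  }
  mrca <- ape::getMRCA(tree, tips)
  nodes <- mrca
  frontier <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1L] %in% frontier, 2L]
    if (!length(kids)) break
    nodes <- c(nodes, kids)
    frontier <- kids
  }
  which(tree$edge[, 2L] %in% nodes)
}

#' Fit global codon-model nuisance parameters
#'
#' Fits the transition/transversion ratio kappa and a global branch-length
#' multiplier (treeScale) by maximum likelihood under the neutral
#' (alpha = beta = 1) MG94xHKY model, with codon frequencies from the chosen
#' empirical estimator. Site patterns are compressed before fitting. These
#' parameters are then held fixed by the per-site tests.
#'
#' @param caln in-frame codon \linkS4class{RefAlignment}.
#' @param tree \code{ape::phylo} with branch lengths; tips match alignment
#'   ids.
#' @param freqModel codon frequency estimator.
#' @return a \linkS4class{CodonModelParams}.
#' @export
estimateGlobalParams <- function(caln, tree,
                                 freqModel = c("F1x4", "F3x4", "equal")) {
  freqModel <- match.arg(freqModel)
  checkTreeAlignment(tree, caln)
  fr <- codonFrequencies(alnMatrix(caln), freqModel)
  phy <- prepTree(tree, 61L)
  states <- codonStates(caln, phy$tip.label)
  pat <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(pat)
  patW <- as.numeric(table(pat)[pat[upat]])
  stateMat <- states[, upat, drop = FALSE]
  lk <- function(par) {
    kappa <- min(max(exp(par[1]), 0.1), 100)
    scale <- min(max(exp(par[2]), 1e-3), 100)
    Q <- buildCodonQ(kappa, 1, 1, fr$nucFreqs) /
      codonNormalizer(kappa, fr$nucFreqs, fr$codonFreqs)
    eig <- reversibleEigen(Q, fr$codonFreqs)
    ll <- pruneSitesLogLik(phy, stateMat, eig, phy$edge.length * scale)
    if (!all(is.finite(ll))) stop("optimization error: non-finite likelihood")
    -sum(patW * ll)
  }
  fit <- optim(c(log(2), log(3)), lk, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 400))
  kappa <- min(max(exp(fit$par[1]), 0.1), 100)
  scale <- min(max(exp(fit$par[2]), 1e-3), 100)
  new("CodonModelParams", kappa = kappa, codonFreqs = fr$codonFreqs,
      freqModel = freqModel, nucFreqs = fr$nucFreqs, treeScale = scale)
}

# Shared per-scan context so per-site fits do not re-derive tree order,
# states or the normalizer.
felContext <- function(caln, tree, params, foreground = NULL) {
  checkTreeAlignment(tree, caln)
  phy <- prepTree(tree, 61L)
  states <- codonStates(caln, phy$tip.label)
  fgMask <- rep(TRUE, nrow(phy$edge))
  partitioned <- FALSE
  if (!is.null(foreground)) {
    fgIdx <- if (is.character(foreground)) foregroundEdges(phy, foreground)
             else as.integer(foreground)
    fgMask <- seq_len(nrow(phy$edge)) %in% fgIdx
    partitioned <- any(!fgMask)
  }
  norm <- codonNormalizer(params@kappa, params@nucFreqs, params@codonFreqs)
  list(phy = phy, states = states, fgMask = fgMask,
       partitioned = partitioned, norm = norm,
       edgeLen = phy$edge.length * params@treeScale, params = params)
}

felSiteEig <- function(ctx, alpha, beta) {
  p <- ctx$params
  Q <- buildCodonQ(p@kappa, alpha, beta, p@nucFreqs) / ctx$norm
  reversibleEigen(Q, p@codonFreqs)
}

felSiteLL <- function(ctx, site, alpha, beta, betaBg = NULL) {
  states <- ctx$states[, site]
  if (ctx$partitioned && !is.null(betaBg)) {
    eigs <- list(felSiteEig(ctx, alpha, beta), felSiteEig(ctx, alpha, betaBg))
    edgeEig <- ifelse(ctx$fgMask, 1L, 2L)
  } else {
    eigs <- list(felSiteEig(ctx, alpha, beta))
    edgeEig <- rep(1L, nrow(ctx$phy$edge))
  }
  pruneSiteLogLik(ctx$phy, states, eigs, edgeEig, ctx$edgeLen)
}

#' Site log-likelihood under the MG94xHKY model
#'
#' Felsenstein pruning over the 61 sense-codon states for one alignment
#' column, with synonymous changes scaled by \code{alpha} and nonsynonymous
#' changes by \code{beta} on foreground edges (\code{betaBg} on background
#' edges when a foreground set is declared). Gaps and ambiguous codons are
#' missing data. The rate matrix is normalized by the neutral mean rate so
#' branch lengths keep their units.
#'
#' @param caln codon \linkS4class{RefAlignment}.
#' @param tree \code{ape::phylo}.
#' @param site codon column index (1-based within the alignment).
#' @param params \linkS4class{CodonModelParams}.
#' @param alpha,beta site synonymous / nonsynonymous rates (>= 0).
#' @param betaBg background nonsynonymous rate (with \code{foreground}).
#' @param foreground tip labels or edge indices of the test branch set
#'   (NULL = all branches).
#' @return log-likelihood (floored at -1e8 when the likelihood underflows).
#' @export
siteLogLikelihood <- function(caln, tree, site, params, alpha, beta,
                              betaBg = NULL, foreground = NULL) {
  stopifnot(alpha >= 0, beta >= 0)
  ctx <- felContext(caln, tree, params, foreground)
  felSiteLL(ctx, site, max(alpha, FEL_RATE_MIN), max(beta, FEL_RATE_MIN),
            if (!is.null(betaBg)) max(betaBg, FEL_RATE_MIN))
}

# Bounded Nelder-Mead over log-rates with the documented restarts.
felOptim <- function(fn, starts) {
  lmin <- log(FEL_RATE_MIN); lmax <- log(FEL_RATE_MAX)
  clamp <- function(p) pmin(pmax(p, lmin), lmax)
  best <- NULL
  for (s in starts) {
    obj <- function(p) fn(exp(clamp(p)))
    fit <- optim(log(s), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = exp(clamp(best$par)), value = best$value,
       converged = best$convergence == 0L)
}

felTestOne <- function(ctx, site, level) {
  states <- ctx$states[, site]
  obsStates <- unique(states[!is.na(states)])
  if (length(obsStates) <= 1L) {
    # no variation: alpha and beta pinned to the lower bound, no test signal
    ll <- if (length(obsStates) == 1L)
      felSiteLL(ctx, site, FEL_RATE_MIN, FEL_RATE_MIN) else NA_real_
    return(data.frame(site = site, alpha = FEL_RATE_MIN, beta = FEL_RATE_MIN,
                      beta_bg = NA_real_, lnl_alt = ll, lnl_null = ll,
                      lrt = 0, p = 1, class = "ns", converged = TRUE))
  }
  if (!ctx$partitioned) {
    alt <- felOptim(function(r) -felSiteLL(ctx, site, r[1], r[2]),
                    list(c(1, 1), c(0.1, 1), c(1, 0.1)))
    # null: beta = alpha is a pure rate scaling of the neutral matrix
    eig0 <- felSiteEig(ctx, 1, 1)
    edgeEig <- rep(1L, nrow(ctx$phy$edge))
    nullFn <- function(lr) -pruneSiteLogLik(ctx$phy, states, list(eig0),
                                            edgeEig,
                                            ctx$edgeLen * exp(lr))
    nf <- optimize(nullFn, c(log(FEL_RATE_MIN), log(FEL_RATE_MAX)),
                   tol = 1e-8)
    lnlNull <- -nf$objective
    lnlAlt <- -alt$value
    if (lnlAlt < lnlNull) {
      r0 <- exp(nf$minimum)
      alt2 <- felOptim(function(r) -felSiteLL(ctx, site, r[1], r[2]),
                       list(c(r0, r0)))
      if (-alt2$value > lnlAlt) { alt <- alt2; lnlAlt <- -alt2$value }
    }
    alpha <- alt$par[1]; beta <- alt$par[2]; betaBg <- NA_real_
  } else {
    alt <- felOptim(function(r) -felSiteLL(ctx, site, r[1], r[2], r[3]),
                    list(c(1, 1, 1), c(0.1, 1, 1), c(1, 0.1, 1)))
    nul <- felOptim(function(r) -felSiteLL(ctx, site, r[1], r[1], r[2]),
                    list(c(1, 1), c(0.1, 1)))
    lnlAlt <- -alt$value; lnlNull <- -nul$value
    if (lnlAlt < lnlNull) {
      alt2 <- felOptim(function(r) -felSiteLL(ctx, site, r[1], r[2], r[3]),
                       list(c(nul$par[1], nul$par[1], nul$par[2])))
      if (-alt2$value > lnlAlt) { alt <- alt2; lnlAlt <- -alt2$value }
    }
    alpha <- alt$par[1]; beta <- alt$par[2]; betaBg <- alt$par[3]
  }
  lrt <- max(2 * (lnlAlt - lnlNull), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  cls <- if (p < level && beta < alpha) "purifying"
         else if (p < level && beta > alpha) "diversifying" else "ns"
  data.frame(site = site, alpha = alpha, beta = beta, beta_bg = betaBg,
             lnl_alt = lnlAlt, lnl_null = lnlNull, lrt = lrt, p = p,
             class = cls, converged = alt$converged)
}

#' FEL test at one codon site
#'
#' Alternative model: site-specific alpha and beta (plus a background beta
#' when a foreground set is declared) fitted by bounded Nelder-Mead with
#' three restarts; null model constrains beta = alpha on the test set.
#' p-value from the chi-square(1) tail of the likelihood-ratio statistic.
#'
#' @inheritParams siteLogLikelihood
#' @param level per-site significance level (default 0.1).
#' @return one-row data.frame (site, alpha, beta, beta_bg, lnl_alt,
#'   lnl_null, lrt, p, class, converged).
#' @export
felSiteTest <- function(caln, tree, site, params, level = 0.1,
                        foreground = NULL) {
  ctx <- felContext(caln, tree, params, foreground)
  felTestOne(ctx, site, level)
}

#' Site-wise selection scan
#'
#' Runs \code{\link{felSiteTest}} at every codon column and tabulates
#' classes. Sites are reported in reference numbering when available; the
#' displayed dN:dS ratio floors alpha at 1e-6.
#'
#' @inheritParams felSiteTest
#' @return a \linkS4class{SelectionProfile}.
#' @export
felScan <- function(caln, tree, params, level = 0.1, foreground = NULL) {
  ctx <- felContext(caln, tree, params, foreground)
  rows <- lapply(seq_len(nCol(caln)), function(s) felTestOne(ctx, s, level))
  sites <- do.call(rbind, rows)
  refs <- colToRef(caln)
  sites$ref_codon <- ifelse(is.na(refs), sites$site, refs)
  sites$ratio <- sites$beta / pmax(sites$alpha, 1e-6)
  sites$significant <- sites$p < level & sites$class != "ns"
  counts <- table(factor(sites$class,
                         levels = c("purifying", "diversifying", "ns")))
  new("SelectionProfile", sites = sites, level = level,
      counts = setNames(as.integer(counts), names(counts)))
}

#' Export a selection profile as TSV
#'
#' Columns: ref_codon, dS (alpha), dN (beta), ratio, lrt, p, class,
#' significant.
#' @param profile a \linkS4class{SelectionProfile}.
#' @param path output path.
#' @export
writeSelectionTSV <- function(profile, path) {
  s <- profile@sites
  df <- data.frame(ref_codon = s$ref_codon, dS = s$alpha, dN = s$beta,
                   ratio = s$ratio, lrt = s$lrt, p = s$p, class = s$class,
                   significant = s$significant)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
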