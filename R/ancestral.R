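# Marginal ancestral sequence reconstruction under an empirical amino-acid
# model with discrete-gamma rates, via an inside-outside formulation of the
# pruning algorithm. For a reversible model the inside pass alone gives the
# tree likelihood (root-invariant); the outside pass supplies the
# complementary likelihood above each node so that per-node posteriors come
# from a single traversal pair per rate category.

# Inside pass for one rate category. Returns per-node scaled conditionals,
# cumulative per-site log-scales, and per-edge contributions (needed by the
# outside pass).
insidePass <- function(phy, stateMat, eig, edgeLen) {
  nTip <- length(phy$tip.label)
  nstate <- length(eig$pi)
  nSites <- ncol(stateMat)
  nNode <- phy$Nnode
  ins <- vector("list", nTip + nNode)
  insScale <- vector("list", nTip + nNode)
  for (v in seq_len(nTip + nNode)) insScale[[v]] <- numeric(nSites)
  for (v in nTip + seq_len(nNode)) ins[[v]] <- matrix(1, nstate, nSites)
  contrib <- vector("list", nrow(phy$edge))
  for (k in phy$poOrder) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    P <- probMatrix(eig, edgeLen[k])
    if (chi <= nTip) {
      s <- stateMat[chi, ]
      cb <- matrix(1, nstate, nSites)
      ok <- !is.na(s)
      if (any(ok)) cb[, ok] <- P[, s[ok], drop = FALSE]
    } else {
      cb <- P %*% ins[[chi]]
    }
    contrib[[k]] <- cb
    slab <- ins[[par]] * cb
    m <- apply(slab, 2L, max)
    m[m <= 0] <- .Machine$double.xmin
    ins[[par]] <- sweep(slab, 2L, m, "/")
    insScale[[par]] <- insScale[[par]] + insScale[[chi]] + log(m)
  }
  list(ins = ins, insScale = insScale, contrib = contrib)
}

# Outside pass: out[v](s) = P(data outside v's subtree | state s at v),
# computed in preorder using the reversibility identity
# out[child] = P(t) %*% (out[parent] * prod of sibling contributions).
outsidePass <- function(phy, inside, eig, edgeLen) {
  nTip <- length(phy$tip.label)
  nstate <- length(eig$pi)
  nSites <- ncol(inside$ins[[phy$rootNode]])
  out <- vector("list", nTip + phy$Nnode)
  outScale <- vector("list", nTip + phy$Nnode)
  out[[phy$rootNode]] <- matrix(1, nstate, nSites)
  outScale[[phy$rootNode]] <- numeric(nSites)
  childEdges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  for (k in rev(phy$poOrder)) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    sibs <- setdiff(childEdges[[as.character(par)]], k)
    acc <- out[[par]]
    accScale <- outScale[[par]]
    for (j in sibs) {
      acc <- acc * inside$contrib[[j]]
      accScale <- accScale + inside$insScale[[phy$edge[j, 2L]]]
      m <- apply(acc, 2L, max)
      m[m <= 0] <- .Machine$double.xmin
      acc <- sweep(acc, 2L, m, "/")
      accScale <- accScale + log(m)
    }
    P <- probMatrix(eig, edgeLen[k])
    o <- P %*% acc
    m <- apply(o, 2L, max)
    m[m <= 0] <- .Machine$double.xmin
    out[[chi]] <- sweep(o, 2L, m, "/")
    outScale[[chi]] <- accScale + log(m)
  }
  list(out = out, outScale = outScale)
}

# Tips descended from each node (ape numbering).
descendantTips <- function(phy) {
  nTip <- length(phy$tip.label)
  res <- vector("list", nTip + phy$Nnode)
  for (v in seq_len(nTip)) res[[v]] <- v
  for (k in phy$poOrder) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    res[[par]] <- c(res[[par]], res[[chi]])
  }
  res
}

#' Marginal ancestral sequence reconstruction
#'
#' Per-site marginal posteriors over the 20 amino acids at internal nodes
#' under an \linkS4class{AAModel} with discrete-gamma rates, integrating
#' over rate categories. The MAP residue is reported per site (ties broken
#' alphabetically); sites where every descendant leaf of the node is gapped
#' are reported as "-".
#'
#' Requires a rooted tree: node identity ("the ancestor of clade X") is a
#' rooted notion even though the likelihood itself is root-invariant. An
#' unrooted input is rooted at the given outgroup, or by midpoint rooting
#' when no outgroup is supplied.
#'
#' @param aln protein \linkS4class{RefAlignment}.
#' @param tree \code{ape::phylo}; tips must match alignment ids.
#' @param model an \linkS4class{AAModel} (default JTT + gamma(1), 20
#'   categories).
#' @param nodes internal node ids (ape numbering) to reconstruct; default
#'   all internal nodes. See \code{\link{mrcaNode}}.
#' @param outgroup optional tip labels used to root an unrooted tree.
#' @return named list of \linkS4class{AncestralReconstruction}, keyed by
#'   node id.
#' @export
marginalASR <- function(aln, tree, model = jttModel(), nodes = NULL,
                        outgroup = NULL) {
  checkTreeAlignment(tree, aln)
  if (!ape::is.rooted(tree)) {
    if (!is.null(outgroup)) {
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    } else if (requireNamespace("phangorn", quietly = TRUE)) {
      tree <- phangorn::midpoint(tree)
    } else {
      stop("configuration error: unrooted tree needs an outgroup ",
           "(or phangorn for midpoint rooting)")
    }
  }
  phy <- prepTree(tree, 20L)
  nTip <- length(phy$tip.label)
  if (is.null(nodes)) nodes <- nTip + seq_len(phy$Nnode)
  stopifnot(all(nodes > nTip), all(nodes <= nTip + phy$Nnode))
  stateMat <- aaStates(aln, phy$tip.label)
  nSites <- ncol(stateMat)
  eig <- aaEigen(model)
  rates <- gammaCategoryRates(model@gammaShape, model@nCategories)
  K <- length(rates)
  passes <- lapply(rates, function(r) {
    el <- phy$edge.length * r
    inside <- insidePass(phy, stateMat, eig, el)
    outside <- outsidePass(phy, inside, eig, el)
    list(inside = inside, outside = outside)
  })
  desc <- descendantTips(phy)
  missingAtTip <- is.na(stateMat)
  gapChar <- alnMatrix(aln)[match(phy$tip.label, alnIds(aln)), ,
                            drop = FALSE] == "-"
  out <- list()
  for (v in nodes) {
    # per-category joint log-likelihood of (node state, data) per site
    logJ <- array(NA_real_, dim = c(20L, nSites, K))
    for (k in seq_len(K)) {
      p <- passes[[k]]
      J <- eig$pi * p$inside$ins[[v]] * p$outside$out[[v]]
      ls <- p$inside$insScale[[v]] + p$outside$outScale[[v]]
      logJ[, , k] <- log(pmax(J, .Machine$double.xmin)) +
        rep(ls, each = 20L)
    }
    siteMax <- apply(logJ, 2L, max)
    joint <- matrix(0, 20L, nSites)
    for (k in seq_len(K))
      joint <- joint + exp(sweep(matrix(logJ[, , k], 20L, nSites), 2L,
                                 siteMax))
    post <- sweep(joint, 2L, colSums(joint), "/")
    tipsBelow <- desc[[v]]
    noInfo <- colSums(!missingAtTip[tipsBelow, , drop = FALSE]) == 0L
    allGap <- noInfo & colSums(!gapChar[tipsBelow, , drop = FALSE]) == 0L
    mapRes <- vapply(seq_len(nSites), function(j) {
      p <- post[, j]
      cands <- which(p >= max(p) - 1e-12)
      sort(AA_ALPHABET[cands])[1L]
    }, character(1))
    maxPost <- apply(post, 2L, max)
    mapRes[noInfo & !allGap] <- "X"   # only ambiguous residues below
    mapRes[allGap] <- "-"
    post[, allGap] <- NA_real_
    maxPost[allGap] <- NA_real_
    rownames(post) <- AA_ALPHABET
    out[[as.character(v)]] <- new("AncestralReconstruction",
      node = as.integer(v), mapSequence = mapRes, posterior = post,
      maxPosterior = maxPost)
  }
  out
}

#' Most recent common ancestor node of a set of tips
#'
#' @param tree rooted \code{ape::phylo}.
#' @param tips tip labels.
#' @return internal node id usable as \code{nodes} in
#'   \code{\link{marginalASR}}.
#' @export
mrcaNode <- function(tree, tips) {
  if (length(tips) == 1L) stop("need at least two tips")
  ape::getMRCA(tree, tips)
}

#' Neighbor-joining helper tree
#'
#' Standard neighbor joining (via \code{ape::nj}) with negative branch
#' lengths clamped to zero; a convenience so simulation-based tests need no
#' external tree-inference tool.
#'
#' @param dist symmetric nonnegative distance matrix (or \code{dist}).
#' @return an \code{ape::phylo}.
#' @export
njTree <- function(dist) {
  d <- as.matrix(dist)
  stopifnot(isSymmetric(unname(d)), all(d >= 0))
  if (nrow(d) == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
               tip.label = rownames(d), edge.length = rep(d[1, 2] / 2, 2),
               Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write per-site ancestral posteriors as TSV
#'
#' Long format: node, site, residue, posterior (zero posteriors omitted).
#' @param asr list returned by \code{\link{marginalASR}}.
#' @param path output path.
#' @export
writeAncestralPosteriorsTSV <- function(asr, path) {
  rows <- do.call(rbind, lapply(asr, function(a) {
    nSites <- ncol(a@posterior)
    df <- data.frame(node = a@node,
                     site = rep(seq_len(nSites), each = 20L),
                     residue = rep(rownames(a@posterior), nSites),
                     posterior = as.vector(a@posterior))
    df[!is.na(df$posterior) & df$posterior > 1e-6, ]
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write MAP ancestral sequences to FASTA
#'
#' @param asr list returned by \code{\link{marginalASR}}.
#' @param path output path.
#' @export
writeAncestralFASTA <- function(asr, path) {
  lines <- unlist(lapply(asr, function(a)
    c(paste0(">node_", a@node), paste0(a@mapSequence, collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}
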