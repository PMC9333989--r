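# Jones-Taylor-Thornton (1992) amino-acid exchangeabilities (lower triangle,
# column-major, residue order ARNDCQEGHILKMFPSTWYV) and stationary
# frequencies.
JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- setNames(
  c(0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
    0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
    0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005),
  AA_ALPHABET)

#' Discrete-gamma rate-category means
#'
#' Equal-probability discretization of a mean-1 gamma distribution: the
#' category rate is the conditional mean within each probability bin
#' (Yang's mean-category convention). Rates are renormalized so their mean
#' is exactly 1.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories.
#' @return numeric vector of k relative rates, mean 1.
#' @export
gammaCategoryRates <- function(shape, k) {
  if (k == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  r <- k * (pgamma(q[-1L], shape = shape + 1, rate = shape) -
            pgamma(q[-(k + 1L)], shape = shape + 1, rate = shape))
  r / mean(r)
}

#' JTT amino-acid model with discrete-gamma rate heterogeneity
#'
#' @param gammaShape gamma shape parameter.
#' @param nCategories number of equal-probability rate categories.
#' @return an \linkS4class{AAModel}.
#' @export
jttModel <- function(gammaShape = 1, nCategories = 20L) {
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[lower.tri(S)] <- JTT_EXCH
  S <- S + t(S)
  freqs <- JTT_FREQS / sum(JTT_FREQS)
  new("AAModel", rates = S, freqs = freqs, gammaShape = gammaShape,
      nCategories = as.integer(nCategories), name = "JTT")
}

# Normalized rate matrix (mean rate 1 at stationarity) of an AAModel.
aaRateMatrix <- function(model) {
  Q <- model@rates * rep(model@freqs, each = 20L)
  diag(Q) <- -rowSums(Q)
  Q / -sum(model@freqs * diag(Q))
}

aaEigen <- function(model) reversibleEigen(aaRateMatrix(model), model@freqs)

# Integer amino-acid states per tip x site (NA = gap/ambiguous).
aaStates <- function(aln, tipOrder) {
  mat <- alnMatrix(aln)[match(tipOrder, alnIds(aln)), , drop = FALSE]
  matrix(match(mat, AA_ALPHABET), nrow = nrow(mat))
}

# Total log-likelihood of a protein alignment under model + gamma mixture.
aaLogLikelihood <- function(aln, tree, model) {
  checkTreeAlignment(tree, aln)
  phy <- prepTree(tree, 20L)
  stateMat <- aaStates(aln, phy$tip.label)
  eig <- aaEigen(model)
  rates <- gammaCategoryRates(model@gammaShape, model@nCategories)
  llk <- vapply(rates, function(r)
    pruneSitesLogLik(phy, stateMat, eig, phy$edge.length * r),
    numeric(ncol(stateMat)))
  llk <- matrix(llk, ncol = length(rates))
  shift <- apply(llk, 1L, max)
  sum(shift + log(rowMeans(exp(llk - shift))))
}

#' Estimate the gamma shape parameter by maximum likelihood
#'
#' Profiles the total tree likelihood over a log-spaced shape grid on
#' [0.1, 10] and refines the best grid point by golden-section search.
#' A flat likelihood surface (e.g. an invariant alignment) returns the
#' default shape 1 with a warning.
#'
#' @param aln protein \linkS4class{RefAlignment}.
#' @param tree \code{ape::phylo} with branch lengths.
#' @param model \linkS4class{AAModel} (its shape slot is ignored).
#' @return ML shape estimate.
#' @export
estimateGammaShape <- function(aln, tree, model = jttModel()) {
  nStates <- apply(alnMatrix(aln), 2L,
                   function(col) length(unique(col[col %in% AA_ALPHABET])))
  if (!any(nStates >= 2L)) {
    warning("no variable columns: flat rate signal, returning default 1.0")
    return(1.0)
  }
  ll <- function(shape) {
    m <- model; m@gammaShape <- shape
    aaLogLikelihood(aln, tree, m)
  }
  grid <- exp(seq(log(0.1), log(10), length.out = 13L))
  vals <- vapply(grid, ll, numeric(1))
  if (max(vals) - min(vals) < 1e-6) {
    warning("flat likelihood over gamma shape; returning default 1.0")
    return(1.0)
  }
  i <- which.max(vals)
  lo <- log(grid[max(i - 1L, 1L)]); hi <- log(grid[min(i + 1L, 13L)])
  opt <- optimize(function(ls) -ll(exp(ls)), c(lo, hi), tol = 1e-4)
  exp(opt$minimum)
}
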