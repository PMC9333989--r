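#' @import methods
#' @importFrom stats optim optimize qgamma pgamma pchisq sd setNames rexp runif
#'   rgamma rlnorm rnorm weighted.mean quantile ks.test ecdf
#' @importFrom utils write.table read.csv head modifyList packageVersion
#' @importFrom graphics hist
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Reference-numbered multiple sequence alignment
#'
#' An alignment of protein or in-frame codon sequences stored as a character
#' matrix (one row per sequence; cells are single residues or codon triplets),
#' optionally carrying a reference sequence id and a map from alignment
#' columns to 1-based reference residue numbers. All reported coordinates in
#' downstream profiles use this reference numbering.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot mat character matrix, rows = sequences, columns = alignment columns;
#'   protein cells are single letters, codon cells are nucleotide triplets,
#'   gap is \code{"-"} (protein) or \code{"---"} (codon).
#' @slot alphabet \code{"protein"} or \code{"codon"}.
#' @slot refId identifier of the reference row (length 0 if unset).
#' @slot colToRef integer vector, one entry per column, giving the reference
#'   residue/codon number of that column (NA if unmapped); strictly
#'   increasing over mapped columns.
#' @export
setClass("RefAlignment",
  representation(ids = "character", mat = "matrix", alphabet = "character",
                 refId = "character", colToRef = "integer"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@ids)) msg <- c(msg, "sequence ids must be unique")
    if (nrow(object@mat) != length(object@ids))
      msg <- c(msg, "mat rows must match ids")
    if (!object@alphabet %in% c("protein", "codon"))
      msg <- c(msg, "alphabet must be 'protein' or 'codon'")
    if (length(object@colToRef) != ncol(object@mat))
      msg <- c(msg, "colToRef length must equal number of columns")
    mapped <- object@colToRef[!is.na(object@colToRef)]
    if (length(mapped) > 1L && any(diff(mapped) <= 0L))
      msg <- c(msg, "colToRef must be strictly increasing over mapped columns")
    if (length(object@refId) == 1L && !object@refId %in% object@ids)
      msg <- c(msg, "refId not among sequence ids")
    if (object@alphabet == "codon" && ncol(object@mat) > 0L) {
      cells <- object@mat
      if (any(nchar(cells) != 3L)) msg <- c(msg, "codon cells must be triplets")
      if (any(cells %in% STOP_CODONS))
        msg <- c(msg, "internal stop codons are not allowed")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn RefAlignment number of sequences
#' @param x,object a \code{RefAlignment}
#' @export
nSeq <- function(x) nrow(x@mat)

#' @describeIn RefAlignment number of alignment columns
#' @export
nCol <- function(x) ncol(x@mat)

#' @describeIn RefAlignment sequence identifiers
#' @export
alnIds <- function(x) x@ids

#' @describeIn RefAlignment character matrix of residues/codons
#' @export
alnMatrix <- function(x) x@mat

#' @describeIn RefAlignment alignment alphabet
#' @export
alnAlphabet <- function(x) x@alphabet

#' @describeIn RefAlignment column -> reference-number map
#' @export
colToRef <- function(x) x@colToRef

setMethod("show", "RefAlignment", function(object) {
  cat(sprintf("RefAlignment: %d %s sequences x %d columns\n",
              nSeq(object), object@alphabet, nCol(object)))
  if (length(object@refId))
    cat(sprintf("  reference: %s (positions %s..%s)\n", object@refId,
                min(object@colToRef, na.rm = TRUE),
                max(object@colToRef, na.rm = TRUE)))
})

newRefAlignment <- function(ids, mat, alphabet, refId = character(),
                            colToRef = NULL) {
  if (is.null(colToRef)) colToRef <- rep(NA_integer_, ncol(mat))
  rownames(mat) <- ids
  new("RefAlignment", ids = as.character(ids), mat = mat,
      alphabet = alphabet, refId = as.character(refId),
      colToRef = as.integer(colToRef))
}

#' Per-sequence weights shared by conservation and covariation scoring
#'
#' @slot weights named positive numeric vector (one per sequence id),
#'   normalized to mean 1.
#' @slot scheme weighting scheme tag.
#' @export
setClass("SequenceWeights",
  representation(weights = "numeric", scheme = "character"),
  validity = function(object) {
    if (any(object@weights <= 0)) return("weights must be positive")
    if (is.null(names(object@weights))) return("weights must be named")
    TRUE
  })

setMethod("show", "SequenceWeights", function(object) {
  cat(sprintf("SequenceWeights (%s): %d sequences, effective N %.2f\n",
              object@scheme, length(object@weights),
              sum(object@weights) / max(object@weights)))
})

#' Column conservation profile on the ConSurf scale convention
#'
#' Raw information-theoretic scores z-normalized across scored columns to
#' mean 0 and SD 1, signed so that lower = more conserved.
#'
#' @slot position integer reference positions (or column index if unmapped).
#' @slot rawScore numeric raw score per column (NA where not scored).
#' @slot zScore numeric normalized score per column (mean 0, SD 1 over
#'   scored columns; lower = more conserved).
#' @slot nEffective weighted non-gap count per column.
#' @slot scored logical; FALSE where occupancy was below the threshold.
#' @slot method scoring method tag.
#' @export
setClass("ConservationProfile",
  representation(position = "integer", rawScore = "numeric",
                 zScore = "numeric", nEffective = "numeric",
                 scored = "logical", method = "character"),
  validity = function(object) {
    z <- object@zScore[object@scored]
    if (length(z) >= 2L) {
      if (abs(mean(z)) > 1e-9) return("z-scores must have mean 0")
      if (abs(popSD(z) - 1) > 1e-9) return("z-scores must have SD 1")
    }
    TRUE
  })

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf("ConservationProfile (%s): %d columns (%d scored)\n",
              object@method, length(object@position), sum(object@scored)))
})

#' Residue covariation matrices and pair table
#'
#' @slot position integer reference positions of the scored columns.
#' @slot mi symmetric matrix of raw mutual information (bits; NaN diagonal).
#' @slot miApc mi after average-product correction.
#' @slot z permutation z-scores of miApc.
#' @slot pairs data.frame (pos_i, pos_j, mi, mi_apc, z).
#' @slot nPerm number of permutations behind z.
#' @slot seed RNG seed used for the permutation null.
#' @export
setClass("CovariationResult",
  representation(position = "integer", mi = "matrix", miApc = "matrix",
                 z = "matrix", pairs = "data.frame", nPerm = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@mi, t(object@mi), tolerance = 1e-8,
                          check.attributes = FALSE)))
      return("mi matrix must be symmetric")
    off <- object@mi[upper.tri(object@mi)]
    if (any(off < -1e-12, na.rm = TRUE)) return("raw MI must be >= 0")
    TRUE
  })

setMethod("show", "CovariationResult", function(object) {
  cat(sprintf("CovariationResult: %d columns, %d pairs (%d permutations)\n",
              length(object@position), nrow(object@pairs), object@nPerm))
})

#' Called covarying pairs under the two-tier conservation-gated rule
#'
#' @slot calls data.frame (pos_i, pos_j, tier, z, cons_i, cons_j).
#' @slot selectionFraction fraction of scored pairs retained.
#' @slot cap configured maximum fraction of scored pairs (the retained count
#'   never exceeds \code{floor(cap * nScoredPairs)}, floored at one pair).
#' @slot nScoredPairs number of pairs with a finite covariation score.
#' @export
setClass("CovariationCalls",
  representation(calls = "data.frame", selectionFraction = "numeric",
                 cap = "numeric", nScoredPairs = "integer"),
  validity = function(object) {
    capN <- max(1L, floor(object@cap * object@nScoredPairs))
    if (nrow(object@calls) > capN)
      return("called pairs exceed the configured cap")
    TRUE
  })

setMethod("show", "CovariationCalls", function(object) {
  cat(sprintf("CovariationCalls: %d pairs (%.3f%% of %d scored pairs, cap %.3f%%)\n",
              nrow(object@calls), 100 * object@selectionFraction,
              object@nScoredPairs, 100 * object@cap))
})

#' Codon substitution model nuisance parameters (MG94xHKY)
#'
#' @slot kappa transition/transversion rate ratio.
#' @slot codonFreqs stationary frequencies over the 61 sense codons (sum 1).
#' @slot freqModel frequency estimator tag ("equal", "F1x4", "F3x4").
#' @slot nucFreqs nucleotide frequencies backing the MG94 target-nucleotide
#'   parameterization (4 for F1x4/equal, 4x3 matrix for F3x4).
#' @slot treeScale global branch-length multiplier (nucleotide units ->
#'   neutral codon substitution units).
#' @export
setClass("CodonModelParams",
  representation(kappa = "numeric", codonFreqs = "numeric",
                 freqModel = "character", nucFreqs = "ANY",
                 treeScale = "numeric"),
  validity = function(object) {
    if (object@kappa <= 0) return("kappa must be > 0")
    if (length(object@codonFreqs) != 61L) return("need 61 codon frequencies")
    if (abs(sum(object@codonFreqs) - 1) > 1e-9)
      return("codon frequencies must sum to 1")
    TRUE
  })

setMethod("show", "CodonModelParams", function(object) {
  cat(sprintf("CodonModelParams: kappa=%.3f, freqs=%s, treeScale=%.3f\n",
              object@kappa, object@freqModel, object@treeScale))
})

#' Site-wise selection scan results (FEL style)
#'
#' One row per codon site: synonymous rate alpha (dS), nonsynonymous rate
#' beta (dN) on the test branch set, likelihood-ratio test of beta = alpha
#' against a chi-square(1) reference, and the resulting class at the chosen
#' significance level.
#'
#' @slot sites data.frame with columns site, alpha, beta, beta_bg, lnl_alt,
#'   lnl_null, lrt, p, class, converged.
#' @slot level per-site significance level.
#' @slot counts named integer vector of class counts.
#' @export
setClass("SelectionProfile",
  representation(sites = "data.frame", level = "numeric", counts = "integer"),
  validity = function(object) {
    s <- object@sites
    if (any(s$lrt < -1e-6, na.rm = TRUE)) return("lrt must be >= 0")
    if (any(s$p < 0 | s$p > 1, na.rm = TRUE)) return("p must lie in [0,1]")
    TRUE
  })

setMethod("show", "SelectionProfile", function(object) {
  cat(sprintf("SelectionProfile: %d sites at level %.2f\n",
              nrow(object@sites), object@level))
  print(object@counts)
})

#' Empirical amino-acid substitution model with discrete-gamma rates
#'
#' @slot rates symmetric exchangeability matrix (20 x 20, zero diagonal).
#' @slot freqs stationary amino-acid frequencies (sum 1).
#' @slot gammaShape shape of the gamma rate distribution.
#' @slot nCategories number of equal-probability discrete rate categories.
#' @slot name model tag.
#' @export
setClass("AAModel",
  representation(rates = "matrix", freqs = "numeric", gammaShape = "numeric",
                 nCategories = "integer", name = "character"),
  validity = function(object) {
    if (abs(sum(object@freqs) - 1) > 1e-9) return("freqs must sum to 1")
    if (object@gammaShape <= 0) return("gammaShape must be > 0")
    r <- gammaCategoryRates(object@gammaShape, object@nCategories)
    if (abs(mean(r) - 1) > 1e-9) return("mean category rate must be 1")
    TRUE
  })

setMethod("show", "AAModel", function(object) {
  cat(sprintf("AAModel %s + gamma(shape=%.3f, %d categories)\n",
              object@name, object@gammaShape, object@nCategories))
})

#' Marginal ancestral reconstruction at one internal node
#'
#' @slot node internal node id (ape numbering) or label.
#' @slot mapSequence character vector over alignment columns; the
#'   maximum-a-posteriori residue, or "-" where every descendant leaf is
#'   gapped.
#' @slot posterior 20 x nCol matrix of per-site posteriors (columns sum to 1
#'   at non-gap sites).
#' @slot maxPosterior numeric vector of per-site MAP probabilities.
#' @export
setClass("AncestralReconstruction",
  representation(node = "integer", mapSequence = "character",
                 posterior = "matrix", maxPosterior = "numeric"),
  validity = function(object) {
    cs <- colSums(object@posterior)
    ok <- object@mapSequence != "-"
    if (any(abs(cs[ok] - 1) > 1e-9)) return("posteriors must sum to 1")
    TRUE
  })

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction at node %d: %d sites, mean MAP %.3f\n",
              object@node, length(object@mapSequence),
              mean(object@maxPosterior[object@mapSequence != "-"])))
})
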