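#' Read a multiple sequence alignment from FASTA
#'
#' Sequences are uppercased, '.' gap characters are converted to '-', and
#' unrecognized residues are recorded as 'X' (protein) or 'NNN' (codon;
#' applied per triplet). Codon alignments must be in frame (length divisible
#' by 3) and free of stop codons.
#'
#' @param path path to a FASTA file.
#' @param alphabet "protein" or "codon".
#' @return a \linkS4class{RefAlignment}.
#' @export
readAlignment <- function(path, alphabet = c("protein", "codon")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("alignment-error: empty FASTA")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("id-collision: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- toupper(as.character(ss))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  len <- unique(nchar(rows))
  if (length(len) != 1L)
    stop("alignment-error: sequences have unequal lengths")
  makeAlignment(ids, rows, alphabet)
}

# Build a RefAlignment from gapped row strings, normalizing unknown symbols.
makeAlignment <- function(ids, rows, alphabet, refId = character(),
                          colToRef = NULL) {
  len <- unique(nchar(rows))
  stopifnot(length(len) == 1L)
  if (alphabet == "protein") {
    mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
    bad <- !(mat %in% c(AA_ALPHABET, "-", "X"))
    if (any(bad)) mat[bad] <- "X"
  } else {
    if (len %% 3L != 0L)
      stop("frame-error: codon alignment length ", len,
           " is not divisible by 3")
    chars <- matrix(unlist(strsplit(rows, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(rows), byrow = TRUE)
    ncod <- len %/% 3L
    mat <- matrix("", nrow = length(rows), ncol = ncod)
    for (k in seq_len(ncod)) {
      trip <- chars[, 3L * k - 2L, drop = TRUE]
      mat[, k] <- paste0(chars[, 3L * k - 2L], chars[, 3L * k - 1L],
                         chars[, 3L * k])
    }
    isGap <- mat == "---"
    valid <- grepl("^[ACGT]{3}$", mat)
    mat[!isGap & !valid] <- "NNN"
    if (any(mat %in% STOP_CODONS))
      stop("alignment-error: stop codon present in codon alignment")
  }
  newRefAlignment(ids, mat, alphabet, refId = refId, colToRef = colToRef)
}

#' Write an alignment to FASTA
#'
#' @param aln a \linkS4class{RefAlignment}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(aln, path) {
  rows <- apply(alnMatrix(aln), 1L, paste0, collapse = "")
  writeLines(paste0(">", alnIds(aln), "\n", rows), path)
  invisible(path)
}

#' Mask an alignment to a reference sequence
#'
#' Removes every column in which the reference row is gapped, so that the
#' surviving columns are in one-to-one correspondence with reference
#' residues, numbered \code{refStart, refStart + 1, ...} (protein residues or
#' codons). An optional \code{refEnd} truncates the alignment after that
#' reference position, covering datasets trimmed to different 3' end points.
#' Other rows keep their gaps. The operation is idempotent.
#'
#' @param aln a \linkS4class{RefAlignment}.
#' @param refId id of the reference row.
#' @param refStart reference number of the first reference residue
#'   (e.g. 48 when the alignment starts at residue K48).
#' @param refEnd optional last reference number to keep.
#' @return masked \linkS4class{RefAlignment} with \code{colToRef} set.
#' @export
maskToReference <- function(aln, refId, refStart = 1L, refEnd = NULL) {
  if (!refId %in% alnIds(aln))
    stop("missing-reference: id '", refId, "' not in alignment")
  mat <- alnMatrix(aln)
  gap <- if (alnAlphabet(aln) == "codon") "---" else "-"
  refRow <- mat[match(refId, alnIds(aln)), ]
  keep <- which(refRow != gap)
  if (length(keep) == 0L) {
    warning("reference row is entirely gapped; returning empty alignment")
    return(newRefAlignment(alnIds(aln), mat[, 0, drop = FALSE],
                           alnAlphabet(aln), refId = refId,
                           colToRef = integer()))
  }
  numbering <- refStart + seq_along(keep) - 1L
  if (!is.null(refEnd)) {
    inWin <- numbering <= refEnd
    keep <- keep[inWin]
    numbering <- numbering[inWin]
  }
  newRefAlignment(alnIds(aln), mat[, keep, drop = FALSE], alnAlphabet(aln),
                  refId = refId, colToRef = numbering)
}

#' Per-column residue frequencies (logo data)
#'
#' Relative frequency of each amino acid at each column over a taxon subset,
#' with gaps and ambiguous residues excluded from the denominator. Columns
#' where the subset carries no residue are flagged empty.
#'
#' @param aln protein \linkS4class{RefAlignment}.
#' @param subset sequence ids to include (default: all).
#' @return a 20 x nCol matrix of frequencies (rows = amino acids, columns
#'   named by reference position where mapped), with attributes
#'   \code{empty} (logical per column) and \code{position}.
#' @export
columnFrequencies <- function(aln, subset = alnIds(aln)) {
  stopifnot(alnAlphabet(aln) == "protein")
  if (length(subset) == 0L) stop("subset must be non-empty")
  missing <- setdiff(subset, alnIds(aln))
  if (length(missing))
    stop("lookup error: unknown ids: ", paste(missing, collapse = ", "))
  mat <- alnMatrix(aln)[match(subset, alnIds(aln)), , drop = FALSE]
  freqs <- matrix(0, nrow = 20L, ncol = ncol(mat),
                  dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(ncol(mat))) {
    res <- mat[, j]
    res <- res[res %in% AA_ALPHABET]
    if (length(res))
      freqs[, j] <- tabulate(match(res, AA_ALPHABET), 20L) / length(res)
  }
  empty <- colSums(freqs) == 0
  pos <- colToRef(aln)
  colnames(freqs) <- ifelse(is.na(pos), as.character(seq_along(pos)), pos)
  structure(freqs, empty = empty, position = pos)
}

#' Export logo frequencies as TSV
#'
#' Long-format table with columns ref_position, residue, frequency.
#' @param freqs result of \code{\link{columnFrequencies}}.
#' @param path output path.
#' @export
writeLogoTSV <- function(freqs, path) {
  df <- data.frame(
    ref_position = rep(colnames(freqs), each = nrow(freqs)),
    residue = rep(rownames(freqs), ncol(freqs)),
    frequency = as.vector(freqs))
  df <- df[df$frequency > 0, ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phylogenetic trees (newick)
#'
#' Thin wrappers around \code{ape} that default missing branch lengths to 0
#' with a warning, so downstream likelihood code can assume edge lengths
#' exist.
#'
#' @param path newick file path.
#' @return an \code{ape::phylo} tree.
#' @export
readTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("parse error: invalid newick in ", path)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths not allowed")
  tr
}

#' @rdname readTree
#' @param tree an \code{ape::phylo}.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Check that tree tips and alignment ids agree.
checkTreeAlignment <- function(tree, aln) {
  if (!setequal(tree$tip.label, alnIds(aln)))
    stop("tree tip labels do not match alignment ids")
  invisible(TRUE)
}
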