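# Small fixture builders used across the test files.

protAln <- function(rows) {
  ids <- names(rows)
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  EvoMotif:::makeAlignment(ids, rows, "protein")
}

codonAln <- function(rows) {
  ids <- names(rows)
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  EvoMotif:::makeAlignment(ids, rows, "codon")
}

unitWeights <- function(aln) {
  ids <- alnIds(aln)
  new("SequenceWeights", weights = stats::setNames(rep(1, length(ids)), ids),
      scheme = "unit")
}

tmpFasta <- function(rows, ids = names(rows)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", rows), path)
  path
}

quartetTree <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.05);")
}
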