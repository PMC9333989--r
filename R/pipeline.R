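# End-to-end orchestration: mask -> conserve -> covary -> fel -> asr ->
# report, and the assay-table pipeline. One config list drives a run; every
# stage writes a TSV artifact and the run manifest records the config, the
# seeds, and the package version, so identical config + inputs reproduce
# identical outputs.

#' Default run configuration
#'
#' Defaults encode the analysis constants the pipeline is built around: covariation tiers
#' (score > 4 with both conservation z < -0.5; score > 8 with both < -0.3),
#' a 0.5 percent selection cap, FEL significance level 0.1, 20 gamma
#' categories.
#'
#' @param ... overrides.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  modifyList(list(
    proteinFasta = NULL, codonFasta = NULL, treeFile = NULL,
    refId = NULL, refStart = 1L, refEnd = NULL,
    weighting = "identity_cluster", weightThreshold = 0.62,
    conservationMethod = "jsd",
    covariation = list(nPerm = 100L, pseudocount = 0.05,
                       t1z = 4, t1cons = -0.5, t2z = 8, t2cons = -0.3,
                       cap = 0.005),
    fel = list(level = 0.1, foreground = NULL, freqModel = "F1x4"),
    asr = list(nodes = NULL, gammaShape = NULL, nCategories = 20L,
               outgroup = NULL),
    motifs = list(),
    seed = 1L, outDir = "evomotif_run"), list(...))
}

#' Run the evolutionary analysis pipeline
#'
#' Reads a protein alignment (and optionally an in-frame codon alignment)
#' plus a tree, masks to the reference sequence, then runs conservation
#' scoring, covariation calling, the site-wise selection scan, and
#' ancestral reconstruction, writing per-stage TSVs and a JSON manifest
#' into \code{cfg$outDir}. Returns the combined per-position motif report.
#'
#' @param cfg configuration list; see \code{\link{defaultRunConfig}}.
#' @return invisibly, a list with the report data.frame, per-stage objects,
#'   and motif rollups.
#' @export
runEvolutionPipeline <- function(cfg = defaultRunConfig()) {
  for (f in c("proteinFasta", "treeFile"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("stage config: missing input file for ", f)
  if (!is.null(cfg$codonFasta) && !file.exists(cfg$codonFasta))
    stop("stage config: codonFasta not found")
  if (is.null(cfg$refId)) stop("stage config: refId is required")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$outDir, name)

  aln <- readAlignment(cfg$proteinFasta, "protein")
  tree <- readTree(cfg$treeFile)
  aln <- maskToReference(aln, cfg$refId, cfg$refStart, cfg$refEnd)
  writeAlignment(aln, outfile("masked_protein.fasta"))

  w <- sequenceWeights(aln, cfg$weighting, cfg$weightThreshold)
  cons <- columnConservation(aln, w, cfg$conservationMethod)
  writeConservationTSV(cons, outfile("conservation.tsv"))
  writeLogoTSV(columnFrequencies(aln), outfile("logo.tsv"))

  cc <- cfg$covariation
  cov <- permutationZ(aln, w, nPerm = cc$nPerm, seed = cfg$seed,
                      pseudocount = cc$pseudocount)
  calls <- callCovaryingPairs(cov, cons, cc$t1z, cc$t1cons, cc$t2z,
                              cc$t2cons, cc$cap)
  writeCovariationTSV(cov, outfile("covariation_pairs.tsv"), calls,
                      outfile("covariation_calls.tsv"))

  sel <- NULL
  if (!is.null(cfg$codonFasta)) {
    caln <- readAlignment(cfg$codonFasta, "codon")
    caln <- maskToReference(caln, cfg$refId, cfg$refStart, cfg$refEnd)
    params <- estimateGlobalParams(caln, tree, cfg$fel$freqModel)
    sel <- felScan(caln, tree, params, cfg$fel$level, cfg$fel$foreground)
    writeSelectionTSV(sel, outfile("selection.tsv"))
  }

  shape <- cfg$asr$gammaShape
  model0 <- jttModel(1, cfg$asr$nCategories)
  if (is.null(shape)) shape <- estimateGammaShape(aln, tree, model0)
  model <- jttModel(shape, cfg$asr$nCategories)
  asr <- marginalASR(aln, tree, model, nodes = cfg$asr$nodes,
                     outgroup = cfg$asr$outgroup)
  writeAncestralFASTA(asr, outfile("ancestral_map.fasta"))
  writeAncestralPosteriorsTSV(asr, outfile("ancestral_posteriors.tsv"))

  report <- buildMotifReport(aln, cons, calls, sel, asr, cfg$motifs)
  write.table(report$positions, outfile("motif_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "outDir")],
                   package = as.character(utils::packageVersion("EvoMotif")),
                   gammaShape = shape)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null")
  writeLines(json, outfile("manifest.json"))
  manifest$hash <- unname(tools::md5sum(outfile("manifest.json")))
  invisible(list(report = report, alignment = aln, conservation = cons,
                 covariation = cov, calls = calls, selection = sel,
                 asr = asr, manifest = manifest))
}

# Combined per-position table plus per-motif rollups.
buildMotifReport <- function(aln, cons, calls, sel, asr, motifs) {
  pos <- cons@position
  df <- data.frame(ref_position = pos, conservation_z = cons@zScore)
  partners <- vapply(pos, function(p) {
    hit <- calls@calls$pos_i == p | calls@calls$pos_j == p
    other <- c(calls@calls$pos_j[calls@calls$pos_i == p],
               calls@calls$pos_i[calls@calls$pos_j == p])
    paste(sort(other), collapse = ",")
  }, character(1))
  df$covariation_partners <- partners
  if (!is.null(sel)) {
    s <- sel@sites
    m <- match(df$ref_position, s$ref_codon)
    df$selection_class <- s$class[m]
    df$selection_p <- s$p[m]
  }
  for (nm in names(asr)) {
    a <- asr[[nm]]
    df[[paste0("node", nm, "_residue")]] <- a@mapSequence
  }
  rollups <- lapply(motifs, function(positions) {
    sub <- df[df$ref_position %in% positions, , drop = FALSE]
    if (!nrow(sub)) stop("motif rollup references unknown positions")
    list(positions = positions,
         mean_conservation_z = mean(sub$conservation_z, na.rm = TRUE),
         n_covarying = sum(sub$covariation_partners != ""),
         classes = if ("selection_class" %in% names(sub))
           table(sub$selection_class) else NULL)
  })
  list(positions = df, motifs = rollups)
}

#' Run the assay quantification pipeline
#'
#' Reads CSV tables (fractions, doses, histograms), applies background
#' subtraction, percent-of-total and channel normalization with DRM/DSM
#' AUCs, dose-response summaries, and responder analysis, writing TSV
#' outputs into \code{outDir}.
#'
#' @param fractionsCsv CSV with replicate, fraction, channel, gmfi.
#' @param doseCsv CSV with dose_nM, replicate, response.
#' @param histNullCsv,histAgonistCsv CSVs with bin_left, bin_right, count.
#' @param outDir output directory.
#' @param drmRange,dsmRange AUC fraction windows.
#' @param smoothK responder smoothing window.
#' @return invisibly, a list of all computed tables and statistics.
#' @export
runAssayPipeline <- function(fractionsCsv = NULL, doseCsv = NULL,
                             histNullCsv = NULL, histAgonistCsv = NULL,
                             outDir = "assay_run", drmRange = 1:5,
                             dsmRange = 6:10, smoothK = 500L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  readCsv <- function(path, need) {
    df <- read.csv(path)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("schema error in ", basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "))
    if (!nrow(df)) stop("schema error in ", basename(path), ": empty table")
    df
  }
  if (!is.null(fractionsCsv)) {
    tab <- readCsv(fractionsCsv, c("replicate", "fraction", "channel",
                                   "gmfi"))
    tab <- backgroundSubtractFractions(tab)
    pct <- percentOfTotal(tab, "CD4")
    out$cd4_pct <- pct
    aucRows <- lapply(split(pct, pct$replicate), function(d)
      data.frame(replicate = d$replicate[1], channel = "CD4",
                 t(fractionAuc(d$pct[order(d$fraction)], drmRange,
                               dsmRange))))
    norms <- list()
    for (ch in setdiff(unique(tab$channel), "CD4")) {
      nm <- normalizeChannel(tab, ch)
      norms[[ch]] <- nm
      aucRows <- c(aucRows, lapply(split(nm, nm$replicate), function(d)
        data.frame(replicate = d$replicate[1], channel = ch,
                   t(fractionAuc(d$norm[order(d$fraction)], drmRange,
                                 dsmRange)))))
    }
    out$channel_norm <- norms
    out$auc <- do.call(rbind, aucRows)
    rownames(out$auc) <- NULL
    write.table(pct, file.path(outDir, "cd4_percent.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$auc, file.path(outDir, "fraction_auc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(doseCsv)) {
    dtab <- readCsv(doseCsv, c("dose_nM", "replicate", "response"))
    out$dose <- doseResponseSummary(dtab)
    write.table(out$dose$perDose, file.path(outDir, "dose_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(auc = out$dose$auc,
                           sensitivity = out$dose$sensitivity,
                           sensitivity_dose_nM =
                             out$dose$sensitivity_dose_nM),
                file.path(outDir, "dose_auc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(histNullCsv) && !is.null(histAgonistCsv)) {
    h0 <- readCsv(histNullCsv, c("bin_left", "bin_right", "count"))
    h1 <- readCsv(histAgonistCsv, c("bin_left", "bin_right", "count"))
    rs <- responderAnalysis(h0, h1, smoothK)
    out$responders <- rs
    write.table(data.frame(n_responders = rs$n_responders,
                           pct_responders = rs$pct_responders,
                           responder_mean_intensity =
                             rs$responder_mean_intensity,
                           responder_sem = rs$responder_sem),
                file.path(outDir, "responders.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
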