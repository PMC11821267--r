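#' Read a counts table and sample metadata into a MediationExperiment
#'
#' Counts and metadata are delimited tables (TSV or CSV by extension) with
#' sample identifiers: the first column of the metadata table and either the
#' row names (samples-by-taxa) or column names (taxa-by-samples) of the
#' counts table. Samples are aligned by identifier; mismatches are an
#' error listing the offenders. Rows with missing treatment, outcome or
#' covariate values are dropped with a message. Taxa observed in fewer than
#' `prevalence` of the retained samples are removed.
#'
#' @param countsFile path to the counts table.
#' @param metadataFile path to the per-sample metadata table.
#' @param treatmentCol,outcomeCol metadata column names.
#' @param covariateCols optional character vector of covariate columns.
#' @param logDepthCol optional metadata column holding the per-sample log
#'   sequencing depth, stored as the count-model offset.
#' @param orientation `"samples_by_taxa"` (default) or `"taxa_by_samples"`.
#' @param prevalence minimum fraction of samples in which a taxon must be
#'   nonzero (default 0.10); set 0 to keep all taxa.
#' @return a [MediationExperiment-class].
#' @export
readDataset <- function(countsFile, metadataFile, treatmentCol, outcomeCol,
                        covariateCols = character(0), logDepthCol = NULL,
                        orientation = c("samples_by_taxa",
                                        "taxa_by_samples"),
                        prevalence = 0.10) {
  orientation <- match.arg(orientation)
  cnt <- as.matrix(readTable(countsFile))
  if (orientation == "samples_by_taxa") cnt <- t(cnt)  # internal: taxa rows
  if (any(is.na(cnt)) || any(abs(cnt - round(cnt)) > 1e-8) || any(cnt < 0))
    stop("counts table must contain non-negative integers")
  meta <- readTable(metadataFile)
  missingCols <- setdiff(c(treatmentCol, outcomeCol, covariateCols,
                           logDepthCol), colnames(meta))
  if (length(missingCols))
    stop("metadata is missing columns: ", paste(missingCols, collapse = ", "))
  onlyCounts <- setdiff(colnames(cnt), rownames(meta))
  onlyMeta <- setdiff(rownames(meta), colnames(cnt))
  if (length(onlyCounts) || length(onlyMeta))
    stop("sample identifiers do not align; only in counts: [",
         paste(onlyCounts, collapse = ", "), "]; only in metadata: [",
         paste(onlyMeta, collapse = ", "), "]")
  meta <- meta[colnames(cnt), , drop = FALSE]
  keep <- stats::complete.cases(meta[, c(treatmentCol, outcomeCol,
                                         covariateCols), drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " samples dropped due to missing metadata")
  cnt <- cnt[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  prev <- rowMeans(cnt > 0)
  if (prevalence > 0 && any(prev < prevalence)) {
    message(sum(prev < prevalence), " taxa removed at prevalence < ",
            prevalence)
    cnt <- cnt[prev >= prevalence, , drop = FALSE]
  }
  MediationExperiment(
    cnt, treatment = meta[[treatmentCol]], outcome = meta[[outcomeCol]],
    covariates = if (length(covariateCols))
      meta[, covariateCols, drop = FALSE] else NULL,
    logDepth = if (is.null(logDepthCol)) NULL else meta[[logDepthCol]],
    metadata = list(countsFile = countsFile, metadataFile = metadataFile))
}

#' Read a BIOM count table (optional format support)
#'
#' Convenience reader for the sparse BIOM format used by several microbiome
#' pipelines; requires the `biomformat` package. The returned matrix is
#' taxa by samples and can be passed to [MediationExperiment()]. The
#' delimited-text path ([readDataset()]) remains the primary interface.
#'
#' @param path path to a BIOM file.
#' @return integer matrix, taxa in rows.
#' @export
readBiomCounts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  as(biomformat::biom_data(biomformat::read_biom(path)), "matrix")
}

readTable <- function(path, rowNames = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.table(path, header = TRUE, sep = sep, row.names = rowNames,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write per-taxon mediation results to disk
#'
#' One row per tested taxon with p-values, adjusted p-values, selection
#' flag, effect estimates, CI bounds and flags, written as a TSV with
#' full-precision floats, plus a JSON sidecar (`<path>.json`) carrying the
#' run configuration and screening record.
#'
#' @param res a [MediationResults-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(res, path) {
  stopifnot(is(res, "MediationResults"))
  tab <- res@results
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "index"
  for (nm in names(tab)[num]) tab[[nm]] <- trimws(formatC(tab[[nm]],
                                                          digits = 17,
                                                          format = "g"))
  tryCatch(
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e)))
  sidecar <- list(config = res@config, method = res@method,
                  screen = list(D = res@screen$D,
                                lambdaChosen = res@screen$lambdaChosen,
                                nFolds = res@screen$nFolds))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a results TSV written by [writeResults()]
#'
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
readResults <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in intersect(c("p1", "p2", "pmax", "pAdj", "nie", "niep", "niea",
                         "nieLower", "nieUpper", "niepLower", "niepUpper",
                         "nieaLower", "nieaUpper"), colnames(tab)))
    tab[[nm]] <- as.numeric(tab[[nm]])
  if ("selected" %in% colnames(tab)) tab$selected <- as.logical(tab$selected)
  tab
}

#' Write a simulated dataset as plain-text files
#'
#' Writes `<prefix>_counts.tsv` (samples by taxa), `<prefix>_metadata.tsv`
#' (sample, treatment, outcome, logDepth and any confounder columns) and
#' `<prefix>_truth.json` (generator tag, seed, causal labels and the
#' coefficient scheme).
#'
#' @param sim a simulated [MediationExperiment-class].
#' @param prefix output path prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeDataset <- function(sim, prefix) {
  cnt <- t(assay(sim, "counts"))
  countsPath <- paste0(prefix, "_counts.tsv")
  write.table(data.frame(sample = rownames(cnt), cnt, check.names = FALSE),
              countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(sim))
  metaPath <- paste0(prefix, "_metadata.tsv")
  write.table(data.frame(sample = rownames(cd), cd, check.names = FALSE),
              metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  truthPath <- paste0(prefix, "_truth.json")
  md <- metadata(sim)
  scheme <- md$scheme
  jsonlite::write_json(
    list(generator = md$generator, seed = md$seed,
         taxa = rownames(sim),
         causal = if (is.null(causalTaxa(sim))) NULL else causalTaxa(sim),
         scheme = if (is.null(scheme)) NULL else
           c(list(taxa = scheme@taxa),
             list(alpha0 = scheme@alpha0, beta0 = scheme@beta0,
                  beta1 = scheme@beta1, sigma2 = scheme@sigma2))),
    truthPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(counts = countsPath, metadata = metaPath, truth = truthPath))
}

# run manifest: everything needed to reproduce a run from its inputs
writeManifest <- function(path, config, inputs = character(0),
                          flags = NULL, elapsed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else NULL
  jsonlite::write_json(
    list(package = "zinbMediate",
         version = as.character(packageVersion("zinbMediate")),
         config = config, inputDigests = digests,
         taxonFlags = flags, elapsedSeconds = elapsed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
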