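#' Confusion counts for a selected mediator set
#'
#' @param selected logical vector: taxa declared mediators.
#' @param truth logical vector of the same length: causal labels.
#' @return named integer vector `c(tp, fp, tn, fn)`; the four counts sum to
#'   the number of taxa.
#' @export
confusionCounts <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("selected and truth must have the same length")
  selected <- as.logical(selected)
  truth <- as.logical(truth)
  c(tp = sum(selected & truth), fp = sum(selected & !truth),
    tn = sum(!selected & !truth), fn = sum(!selected & truth))
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2*recall*precision/(recall+precision)`. A metric whose denominator
#' is zero is undefined and returned as `NA` (and later excluded from
#' benchmark means with a reported count) rather than coerced to 0 or 1;
#' when recall and precision are both defined and both zero, F1 is 0.
#'
#' @param tp,fp,tn,fn non-negative integer counts (`tn` unused by the
#'   three metrics but kept for the full confusion record).
#' @return named numeric `c(recall, precision, f1)`.
#' @export
selectionMetrics <- function(tp, fp, tn, fn) {
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(recall) || is.na(precision)) NA_real_
  else if (recall + precision == 0) 0
  else 2 * recall * precision / (recall + precision)
  c(recall = recall, precision = precision, f1 = f1)
}

#' Benchmark a mediation pipeline on simulated data
#'
#' Repeatedly simulates a dataset, runs the chosen pipeline, selects taxa
#' at the BH-adjusted FDR threshold, and scores the selection against the
#' simulator's ground-truth labels. Fully seeded: replicate `r` uses a
#' sub-seed derived from `(seed, r)`, so reports are bit-reproducible.
#'
#' @param n,m sample and taxon counts for the simulator.
#' @param generator `"zinb"`, `"hurdle_nb"`, `"hurdle_poisson"` or
#'   `"confounded"`.
#' @param method `"zinb"` (zero-inflated CRT pipeline) or `"naive"`
#'   (Gaussian baseline).
#' @param nReplicates number of simulated datasets.
#' @param B CRT resamples per taxon.
#' @param fdr FDR threshold.
#' @param seed master seed.
#' @param h confounding strength (confounded generator only).
#' @param screen apply LASSO screening.
#' @param permuteTreatment permute the treatment labels after simulation
#'   (breaks every causal path; used for null-FDR checks, where all
#'   discoveries are false).
#' @return a [BenchmarkReport-class].
#' @export
runBenchmark <- function(n, m, generator = c("zinb", "hurdle_nb",
                                             "hurdle_poisson", "confounded"),
                         method = c("zinb", "naive"), nReplicates = 20L,
                         B = 50L, fdr = 0.05, seed = 1L, h = 1,
                         screen = TRUE, permuteTreatment = FALSE) {
  generator <- match.arg(generator)
  method <- match.arg(method)
  rows <- vector("list", nReplicates)
  failures <- 0L
  for (r in seq_len(nReplicates)) {
    simSeed <- deriveSeed(seed, 1000L + r)
    sim <- switch(generator,
      zinb = simulateZinbData(n, m, seed = simSeed),
      hurdle_nb = simulateHurdleData(n, m, family = "nb", seed = simSeed),
      hurdle_poisson = simulateHurdleData(n, m, family = "poisson",
                                          seed = simSeed),
      confounded = simulateConfoundedData(n, m, h = h, seed = simSeed))
    truth <- causalTaxa(sim)
    if (permuteTreatment) {
      set.seed(deriveSeed(simSeed, 7L))
      colData(sim)$treatment <- sample(treatment(sim))
      truth <- rep(FALSE, nrow(sim))
    }
    res <- tryCatch({
      runner <- if (method == "zinb") runMediation else runNaiveMediation
      runner(sim, B = B, fdr = fdr, seed = deriveSeed(simSeed, 11L),
             screen = screen)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    sel <- selectionVector(res, m)
    cc <- confusionCounts(sel, truth)
    met <- selectionMetrics(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]])
    nSel <- sum(sel)
    rows[[r]] <- data.frame(replicate = r, t(cc), t(met),
                            nSelected = nSel,
                            fdp = if (nSel > 0) cc[["fp"]] / nSel else 0)
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per)) per <- data.frame()
  summaryList <- list(
    recall = mean(per$recall, na.rm = TRUE),
    precision = mean(per$precision, na.rm = TRUE),
    f1 = mean(per$f1, na.rm = TRUE),
    fdp = mean(per$fdp),
    nUndefinedPrecision = sum(is.na(per$precision)),
    nUndefinedRecall = sum(is.na(per$recall)),
    nFailures = failures)
  new("BenchmarkReport", perReplicate = per, summary = summaryList,
      fdr = fdr, method = method, generator = generator,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

setMethod("show", "BenchmarkReport", function(object) {
  s <- object@summary
  cat(sprintf("BenchmarkReport: %s pipeline on %s data, %d replicates (fdr %.2g)\n",
              object@method, object@generator, object@nReplicates,
              object@fdr))
  cat(sprintf("  recall %.3f, precision %.3f (undefined in %d), F1 %.3f, mean FDP %.3f\n",
              s$recall, s$precision, s$nUndefinedPrecision, s$f1, s$fdp))
  if (s$nFailures) cat("  failed replicates:", s$nFailures, "\n")
})
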