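## End-to-end CAD-detection workflow: stratified half split, feature
## selection on the acquisition half, repeated-CV evaluation on the held-out
## half. Plus the command-line dispatcher used by the exec script.

#' Full CAD-detection workflow on labeled HRV beats
#'
#' Splits the beats into two stratified halves with a seeded RNG. The
#' acquisition half is used to extract the 25-feature vectors, rank them by
#' Student's t-test and select RdisEn + the top `kTop` wavelet-packet
#' statistics. Features are then extracted from the evaluation half only for
#' the selected names, and the classifier is scored with repeated stratified
#' k-fold cross-validation. The evaluation half never influences selection.
#'
#' @param beats list of numeric beats (or `beatSegment`s).
#' @param labels two-level factor, one per beat ("cad" positive when present).
#' @param B,m,q RdisEn parameters (defaults 512, 2, 0.4).
#' @param basis wavelet basis (default "db1").
#' @param kTop wavelet-packet features to keep (default 4).
#' @param classifier "knn" or "svm".
#' @param folds,repeats CV protocol (defaults 10, 10).
#' @param k,cost classifier settings (defaults 10, 1).
#' @param seed master seed; fans out to split and fold child seeds.
#' @return list of class `cadPipelineResult` with `ranking`, `selected`,
#'   `report`, and the split indices (`acquisitionIdx`, `evaluationIdx`).
#' @export
cadPipeline <- function(beats, labels, B = 512, m = 2, q = 0.4, basis = "db1",
                        kTop = 4, classifier = "knn", folds = 10, repeats = 10,
                        k = 10, cost = 1, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must be binary", call. = FALSE)
  if (min(table(labels)) < 2 * folds)
    stop(sprintf("need at least %d beats per class for a half-split with %d-fold CV",
                 2 * folds, folds), call. = FALSE)
  set.seed(deriveSeed(seed, "split"))
  acq <- unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, floor(length(idx) / 2))
  }))
  evl <- setdiff(seq_along(beats), acq)
  acqTab <- extractFeatureTable(beats[acq], labels[acq],
                                B = B, m = m, q = q, basis = basis)
  ranking <- ttestRank(acqTab)
  selected <- selectFeatures(ranking, kTop = kTop)
  evlTab <- extractFeatureTable(beats[evl], labels[evl],
                                B = B, m = m, q = q, basis = basis)
  report <- repeatedKFold(evlTab[selected], evlTab$label,
                          classifier = classifier, folds = folds,
                          repeats = repeats, k = k, cost = cost,
                          seed = deriveSeed(seed, "eval"))
  structure(list(ranking = ranking, selected = selected, report = report,
                 acquisitionIdx = sort(acq), evaluationIdx = evl,
                 basis = basis, seed = seed),
            class = "cadPipelineResult")
}

#' @export
print.cadPipelineResult <- function(x, ...) {
  cat(sprintf("CAD-detection pipeline (basis %s, seed %d)\n", x$basis, x$seed))
  cat("selected features:", paste(x$selected, collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}

#' JSON summary of a pipeline result
#'
#' @param result a `cadPipelineResult`.
#' @param path optional file to write the JSON to.
#' @return the summary list (invisibly when written to file).
#' @export
pipelineSummary <- function(result, path = NULL) {
  s <- result$report$summary
  out <- list(classifier = result$report$classifier, basis = result$basis,
              n_features = result$report$nFeatures,
              features = result$selected, seed = result$seed,
              acc_mean = s$mean[s$metric == "acc"], acc_sd = s$sd[s$metric == "acc"],
              sen_mean = s$mean[s$metric == "sen"], sen_sd = s$sd[s$metric == "sen"],
              spe_mean = s$mean[s$metric == "spe"], spe_sd = s$sd[s$metric == "spe"])
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

## ---- command-line surface --------------------------------------------------

cliArgValue <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1]
}

#' Command-line dispatcher
#'
#' Thin shell interface over the package functions, used by the `exec/rdisen`
#' script. Commands: `simulate` (logistic | ecg | rr), `entropy`,
#' `preprocess`, `features`, `rank`, `classify`, `sweep`, `optimize-q`,
#' `assess`. Run `rdisenCli(c(cmd, "--help"))` for per-command flags. Every
#' command is deterministic given its flags and `--seed`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
rdisenCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: rdisen <command> [flags]; commands: ",
                                "simulate entropy preprocess features rank ",
                                "classify sweep optimize-q assess", call. = FALSE)
    cmd <- args[1]; rest <- args[-1]
    seed <- as.integer(cliArgValue(rest, "--seed", "1"))
    num <- function(flag, default) as.numeric(cliArgValue(rest, flag, default))
    switch(cmd,
      simulate = {
        what <- cliArgValue(rest, "--kind", "rr")
        out <- cliArgValue(rest, "--out")
        if (is.null(out)) stop("--out required", call. = FALSE)
        if (what == "logistic") {
          sigs <- logisticMap(num("--w", 3.8), n = num("--n", 1000),
                              realizations = num("--realizations", 20), seed = seed)
          writeSignalCsv(sigs, out, seed = seed)
        } else if (what == "ecg") {
          e <- syntheticEcg(fs = num("--fs", 257), duration = num("--duration", 60),
                            meanHr = num("--hr", 60), noiseSd = num("--noise-sd", 0),
                            seed = seed)
          writeSignalCsv(e$record$samples, out, seed = seed)
          writeSignalCsv(e$peaks, paste0(out, ".peaks.csv"), seed = seed)
        } else if (what == "rr") {
          g <- twoClassRR(n = num("--n", 1000),
                          recordsPerClass = num("--records", 40), seed = seed)
          writeSignalCsv(g$signals, out, seed = seed)
          writeLines(as.character(g$labels), paste0(out, ".labels.txt"))
        } else stop("unknown --kind ", what, call. = FALSE)
        0L
      },
      entropy = {
        sigs <- readSignalCsv(cliArgValue(rest, "--in"))
        est <- cliArgValue(rest, "--estimator", "rdisen")
        vals <- vapply(sigs, function(x) {
          v <- .entropyAt(x, est, m = num("--m", 2), B = num("--B", 512),
                          r = num("--r", 0.2), q = num("--q", 0.4))
          if (isUndefined(v)) NA_real_ else as.numeric(v)
        }, numeric(1))
        cat(paste(ifelse(is.na(vals), "undefined", format(vals)), collapse = "\n"), "\n")
        0L
      },
      preprocess = {
        sigs <- readSignalCsv(cliArgValue(rest, "--in"))
        fs <- num("--fs", 257)
        out <- cliArgValue(rest, "--out")
        rrs <- lapply(seq_along(sigs), function(i) {
          rec <- ecgRecord(sigs[[i]], fs, id = paste0("sig", i))
          rec <- resampleRecord(rec, num("--target-rate", fs))
          rec <- denoiseRecord(rec)
          computeRR(detectRPeaks(rec), rec$fs)
        })
        for (i in seq_along(rrs))
          writeSignalCsv(rrs[[i]], sub("\\.csv$", sprintf("_rr%d.csv", i), out),
                         seed = seed)
        0L
      },
      features = {
        sigs <- readSignalCsv(cliArgValue(rest, "--in"))
        labPath <- cliArgValue(rest, "--labels")
        labels <- if (is.null(labPath)) rep(NA, length(sigs)) else readLines(labPath)
        beats <- unlist(lapply(seq_along(sigs), function(i)
          segmentBeats(sigs[[i]], beatLength = num("--beat-length", 500),
                       label = labels[i], recordId = paste0("sig", i))),
          recursive = FALSE)
        tab <- extractFeatureTable(beats, B = num("--B", 512), m = num("--m", 2),
                                   q = num("--q", 0.4),
                                   basis = cliArgValue(rest, "--basis", "db1"))
        writeFeatureCsv(tab, cliArgValue(rest, "--out"), seed = seed)
        0L
      },
      rank = {
        tab <- readFeatureCsv(cliArgValue(rest, "--in"))
        rk <- ttestRank(tab)
        utils::write.csv(rk, cliArgValue(rest, "--out"), row.names = FALSE)
        cat("selected:", paste(selectFeatures(rk, kTop = num("--k-top", 4)),
                               collapse = ", "), "\n")
        0L
      },
      classify = {
        tab <- readFeatureCsv(cliArgValue(rest, "--in"))
        sel <- selectFeatures(ttestRank(tab), kTop = num("--k-top", 4))
        rep_ <- repeatedKFold(tab[sel], tab$label,
                              classifier = cliArgValue(rest, "--classifier", "knn"),
                              folds = num("--folds", 10), repeats = num("--repeats", 10),
                              k = num("--k", 10), seed = seed)
        print(rep_)
        outPath <- cliArgValue(rest, "--out")
        if (!is.null(outPath))
          jsonlite::write_json(rep_$summary, outPath, auto_unbox = TRUE, digits = NA)
        0L
      },
      `sweep` = {
        sigs <- readSignalCsv(cliArgValue(rest, "--in"))
        res <- sweepEntropy(list(all = sigs),
                            estimator = cliArgValue(rest, "--estimator", "rdisen"))
        utils::write.csv(res, cliArgValue(rest, "--out"), row.names = FALSE)
        0L
      },
      `optimize-q` = {
        a <- readSignalCsv(cliArgValue(rest, "--beats-a"))
        b <- readSignalCsv(cliArgValue(rest, "--beats-b"))
        opt <- optimizeQ(a, b, B = num("--B", 512), m = num("--m", 2))
        cat("q* =", opt$qStar, "\n")
        outPath <- cliArgValue(rest, "--out")
        if (!is.null(outPath))
          utils::write.csv(opt$curve, outPath, row.names = FALSE)
        0L
      },
      assess = {
        tab <- readFeatureCsv(cliArgValue(rest, "--in"))
        sel <- selectFeatures(ttestRank(tab), kTop = num("--k-top", 4))
        a <- assessFeatures(tab[sel], tab$label)
        print(a$univariate); print(a$multivariate)
        0L
      },
      stop("unknown command '", cmd, "'", call. = FALSE)
    )
  }, error = function(e) {
    message("rdisen: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
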