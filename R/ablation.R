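# Loss-composition ablation harness: trains the four compositions on the
# identical seeded dataset, synthesizes held-out cases, and assembles the
# per-case + mean (+/- sd) report shape used by the evaluation tables.

#' Evaluate a synthetic CT against its ground truth
#'
#' Image similarity (MAE in HU, SSIM, PSNR) plus FMR, and dosimetric
#' comparison through the deterministic pseudo-dose operator
#' ([doseFromAnatomy()]) applied identically to dCT and sCT.
#'
#' @param sct,dct [ImageSlice-class] prediction and ground truth.
#' @param caseSeed seed for the case's dose lobe geometry.
#' @param ssCfg scale-space configuration for FMR.
#' @param gammaCrit list of [GammaCriteria-class] (named).
#' @return one-row data.frame of metric values.
#' @export
evaluateCase <- function(sct, dct, caseSeed = 1L,
                         ssCfg = ScaleSpaceConfig(),
                         gammaCrit = list(g11 = GammaCriteria(1, 1),
                                          g22 = GammaCriteria(2, 2))) {
  refDose <- doseFromAnatomy(dct, seed = caseSeed, role = "reference")
  evalDose <- doseFromAnatomy(sct, seed = caseSeed, role = "evaluated")
  row <- data.frame(
    mae_hu = maeHU(sct, dct),
    ssim = ssimMetric(sct, dct),
    psnr_db = psnrDB(sct, dct),
    fmr = fmr(sct, dct, ssCfg)$fmr,
    dose_diff = doseDifference(refDose, evalDose))
  for (nm in names(gammaCrit))
    row[[paste0("gamma_", nm)]] <-
      gammaPassRate(gammaMap(refDose, evalDose, gammaCrit[[nm]]))
  row
}

#' Assemble a MetricReport from per-case rows
#'
#' @param perCase data.frame with a `caseId` column and metric columns.
#' @param configTag loss composition label.
#' @return a [MetricReport-class]; the aggregate uses the sample (n-1)
#'   standard deviation across cases.
#' @export
buildMetricReport <- function(perCase, configTag = "L1") {
  metrics <- setdiff(names(perCase), "caseId")
  agg <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m) mean(perCase[[m]]),
                                  numeric(1)),
                    sd = vapply(metrics, function(m)
                      if (nrow(perCase) > 1) sd(perCase[[m]]) else 0,
                      numeric(1)),
                    row.names = NULL)
  new("MetricReport", perCase = perCase, aggregate = agg,
      configTag = configTag)
}

#' Run the loss-composition ablation
#'
#' Trains one network per loss configuration on the identical seeded
#' dataset (same split, same initialisation seed), synthesizes every test
#' case, and computes the full metric panel per configuration.
#'
#' @param dataset result of [generatePhantomDataset()] (or [readDataset()]).
#' @param configs named list of [TrainConfig-class], e.g. one per
#'   composition tag.
#' @param netCfg a [NetworkConfig-class] shared by all runs.
#' @param ssCfg scale-space configuration for FMR.
#' @param verbose print progress.
#' @return list with `reports` (one [MetricReport-class] per config) and
#'   `comparison` (wide data.frame: metric rows, per-case columns,
#'   mean/sd columns).
#' @export
runAblation <- function(dataset,
                        configs = ablationConfigs(),
                        netCfg = tinyNetworkConfig(),
                        ssCfg = ScaleSpaceConfig(),
                        verbose = FALSE) {
  if (length(configs) < 1) stop("need at least one configuration")
  man <- dataset$manifest
  byId <- setNames(dataset$samples, man$caseId)
  tr <- byId[man$caseId[man$split == "train"]]
  va <- byId[man$caseId[man$split == "valid"]]
  te <- byId[man$caseId[man$split == "test"]]
  if (length(te) == 0) stop("manifest has no test cases")
  reports <- list()
  for (tag in names(configs)) {
    cfg <- configs[[tag]]
    if (verbose) message("training configuration ", tag)
    net <- buildNetwork(netCfg, seed = cfg@seed)
    fit <- trainNetwork(tr, va, net, cfg, verbose = verbose)
    rows <- lapply(seq_along(te), function(i) {
      sm <- te[[i]]
      sct <- synthesizeCT(fit$net, sm@cbct)
      cbind(data.frame(caseId = sm@caseId),
            evaluateCase(sct, sm@dct,
                         caseSeed = .subSeed(man$seed[1],
                                             match(sm@caseId, man$caseId),
                                             3L),
                         ssCfg = ssCfg))
    })
    reports[[tag]] <- buildMetricReport(do.call(rbind, rows),
                                        configTag = tag)
  }
  list(reports = reports, comparison = comparisonTable(reports))
}

#' Default ablation configurations: the four loss compositions
#'
#' Identical hyper-parameters across compositions; only the loss definition
#' varies.
#'
#' @param epochs,learningRate,batchSize,seed shared protocol settings.
#' @return named list of [TrainConfig-class] (`L1`, `LP`, `LS`, `LPS`).
#' @export
ablationConfigs <- function(epochs = 30L, learningRate = 1e-3,
                            batchSize = 8L, seed = 1L) {
  tags <- c("L1", "LP", "LS", "LPS")
  setNames(lapply(tags, function(tg)
    TrainConfig(epochs = epochs, learningRate = learningRate,
                batchSize = batchSize, seed = seed,
                loss = LossConfig(tg))), tags)
}

#' Wide comparison table across configurations
#'
#' One row per (metric, configuration) with per-case columns `P1..Pn` and
#' `mean`/`sd` columns — the shape of the published evaluation tables.
#'
#' @param reports named list of [MetricReport-class].
#' @return data.frame.
#' @export
comparisonTable <- function(reports) {
  rows <- list()
  for (tag in names(reports)) {
    rep <- reports[[tag]]
    metrics <- setdiff(names(rep@perCase), "caseId")
    for (m in metrics) {
      vals <- rep@perCase[[m]]
      row <- data.frame(metric = m, config = tag)
      for (i in seq_along(vals)) row[[paste0("P", i)]] <- vals[i]
      row$mean <- mean(vals)
      row$sd <- if (length(vals) > 1) sd(vals) else 0
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$metric, out$config), , drop = FALSE]
}
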