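#' @include AllClasses.R
NULL

## End-to-end orchestration over synthetic data, a YAML config with the
## study defaults, and the group-comparison helper.

#' Default pipeline configuration
#'
#' All stage parameters with the study defaults: MVAR order 5, band
#' 0.009-0.08 Hz, 1000 surrogate realizations at the 99th percentile,
#' lesion threshold t > 3 with clusters > 10 voxels, abnormality at z < -1,
#' SVR gamma 0.25 with the fixed 75 % accuracy bar.
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    stages = list(hrv = TRUE, pica = TRUE, lesions = TRUE, tpdc = TRUE,
                  surrogates = TRUE, compare = TRUE, svr = TRUE),
    synthetic = list(
      nSubjects = 42L, nControls = 30L,
      gridShape = c(12L, 12L, 12L), voxelSize = c(2, 2, 2),
      loadingCorr = 0.9, noiseSd = 0.5,
      rr = list(meanRR = 800, lfAmp = 40, hfAmp = 20, noiseSd = 10,
                durationS = 300),
      tpdcSamples = 400L, coupling = 0.5, couplingNetwork = 6L
    ),
    hrv = list(resampleHz = 4, relTol = 0.30, zCut = -1),
    pica = list(k = NA_integer_, nPerm = 1000L),
    lesions = list(tThresh = 3, minVoxels = 10L, connectivity = 26L),
    tpdc = list(order = 5L, band = c(0.009, 0.08), threshold = 0.1,
                nFreq = 64L, timeStride = 1L, qParam = 1e-4),
    surrogates = list(nReal = 1000L, percentile = 99, windowLen = NA_integer_),
    compare = list(method = "permutation", nPerm = 10000L, bonferroni = TRUE),
    svr = list(gamma = 0.25, gridMax = 10L, trainFrac = 0.75, nFolds = 10L,
               accuracyThreshold = 0.75)
  )
}

mergeConfig <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && is.list(user[[key]]))
      base[[key]] <- mergeConfig(base[[key]], user[[key]], full)
    else base[[key]] <- user[[key]]
  }
  base
}

#' Read / write a pipeline configuration (YAML)
#'
#' `readPipelineConfig` merges the file over [defaultPipelineConfig()] and
#' rejects unknown keys; `writePipelineConfig` serializes a config so the
#' pair round-trips.
#'
#' @param path YAML file path.
#' @param config a config list.
#' @return `readPipelineConfig` returns the merged config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  mergeConfig(defaultPipelineConfig(), user)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Two-group comparison of connectivity values
#'
#' Permutation test on the difference of group means (default, 10 000
#' permutations) or a Welch t test.
#'
#' @param valuesA,valuesB numeric vectors (each >= 3 values).
#' @param method `"permutation"` or `"welch"`.
#' @param nPerm permutation count (default 10000).
#' @param seed RNG seed (permutation method).
#' @return list with `statistic` (mean difference) and `p`.
#' @export
compareGroups <- function(valuesA, valuesB,
                          method = c("permutation", "welch"),
                          nPerm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(valuesA) < 3L || length(valuesB) < 3L)
    stop("each group needs at least 3 values")
  if (sd(c(valuesA, valuesB)) == 0) stop("degenerate (constant) groups")
  dObs <- mean(valuesA) - mean(valuesB)
  if (method == "welch") {
    tt <- stats::t.test(valuesA, valuesB)
    return(list(statistic = dObs, p = tt$p.value))
  }
  pooled <- c(valuesA, valuesB)
  nA <- length(valuesA)
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample.int(length(pooled), nA)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(dObs) - 1e-12)
      cnt <- cnt + 1L
  }
  list(statistic = dObs, p = (cnt + 1L) / (nPerm + 1L))
}

#' Compare connectivity profiles between groups across networks
#'
#' Applies [compareGroups()] per network and direction (14 tests) with
#' optional Bonferroni correction. A nuisance covariate (e.g. medication
#' class) can be supplied for both groups jointly; it is regressed out of
#' the band-averaged connectivity values (linear residualization around the
#' grand mean) before the comparison.
#'
#' @param profilesA,profilesB lists of [ConnectivityProfile-class].
#' @param method,nPerm,seed passed to [compareGroups()].
#' @param bonferroni correct across the 14 tests (default TRUE).
#' @param covariate optional per-subject nuisance covariate, ordered as
#'   `c(profilesA, profilesB)`; a factor (medication class) or numeric.
#' @return data.frame with columns `network`, `direction`, `meanA`, `meanB`,
#'   `statistic`, `p`, `p_adj`.
#' @export
compareGroupProfiles <- function(profilesA, profilesB,
                                 method = "permutation", nPerm = 10000L,
                                 bonferroni = TRUE, seed = 1L,
                                 covariate = NULL) {
  nets <- names(forwardValues(profilesA[[1]]))
  nA <- length(profilesA)
  if (!is.null(covariate) &&
      length(covariate) != nA + length(profilesB))
    stop("covariate must have one value per subject across both groups")
  rows <- list()
  for (dir in c("forward", "backward")) {
    get <- if (dir == "forward") forwardValues else backwardValues
    mA <- t(vapply(profilesA, function(p) get(p), numeric(length(nets))))
    mB <- t(vapply(profilesB, function(p) get(p), numeric(length(nets))))
    for (j in seq_along(nets)) {
      vA <- mA[, j]; vB <- mB[, j]
      if (!is.null(covariate)) {
        v <- c(vA, vB)
        res <- stats::residuals(lm(v ~ covariate)) + mean(v)
        vA <- res[seq_len(nA)]; vB <- res[-seq_len(nA)]
      }
      cmp <- compareGroups(vA, vB, method = method, nPerm = nPerm,
                           seed = seed + j)
      rows[[length(rows) + 1L]] <- data.frame(
        network = nets[j], direction = dir,
        meanA = mean(vA), meanB = mean(vB),
        statistic = cmp$statistic, p = cmp$p)
    }
  }
  df <- do.call(rbind, rows)
  df$p_adj <- if (bonferroni) pmin(1, df$p * nrow(df)) else df$p
  df
}

#' Run the full synthetic-data pipeline
#'
#' Executes, on generated data with known ground truth: HRV metric
#' computation and z-score dichotomization, parallel ICA of lesion maps
#' against the z-scored LF covariate, lesion-pattern thresholding and atlas
#' overlay, per-subject TPDC connectivity profiles (seed coupling into one
#' network for the "abnormal" group), window-shuffle surrogate thresholds,
#' group comparison across networks, and SVR validation. All outputs are
#' written under `outDir` together with a JSON manifest.
#'
#' @param config from [defaultPipelineConfig()] / [readPipelineConfig()].
#' @param outDir output directory (created; default a tempdir subfolder).
#' @return invisibly, a list with all stage results and `outDir`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outDir = file.path(tempfile("bhrun"))) {
  config <- mergeConfig(defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  # dependency closure: downstream consumers of TPDC profiles switch off
  if (!stages$tpdc) stages$surrogates <- stages$compare <- stages$svr <- FALSE
  if (!stages$pica) stages$lesions <- FALSE
  seed <- as.integer(config$seed)
  syn <- config$synthetic
  res <- list(config = config, outDir = outDir)

  ## ---- synthetic cohort -----------------------------------------------
  cohort <- genLesionCohort(
    nSubjects = syn$nSubjects, gridShape = syn$gridShape,
    voxelSize = syn$voxelSize, loadingCorr = syn$loadingCorr,
    noiseSd = syn$noiseSd, seed = seed)

  ## ---- HRV stage ------------------------------------------------------
  if (stages$hrv) {
    rrp <- syn$rr
    # controls: nominal LF/HF amplitudes; patients: LF amplitude shifted by
    # the covariate so reduced covariate values mean reduced LF power
    mkMetrics <- function(lfAmp, sd) {
      rr <- cleanRR(genRRSeries(meanRR = rrp$meanRR, lfAmp = lfAmp,
                                hfAmp = rrp$hfAmp, noiseSd = rrp$noiseSd,
                                durationS = rrp$durationS, seed = sd),
                    relTol = config$hrv$relTol)
      hrvMetrics(rr, resampleHz = config$hrv$resampleHz)
    }
    ctrl <- t(vapply(seq_len(syn$nControls),
                     function(i) mkMetrics(rrp$lfAmp, seed + 1000L + i),
                     numeric(6)))
    lfPat <- pmax(rrp$lfAmp * (1 + 0.35 * cohort$covariate), 1)
    pat <- t(vapply(seq_len(syn$nSubjects),
                    function(i) mkMetrics(lfPat[i], seed + 2000L + i),
                    numeric(6)))
    norms <- controlNorms(ctrl[, c("vc", "rmssd", "lf", "hf")])
    panel <- zscorePanel(pat[, c("vc", "rmssd", "lf", "hf")], norms)
    zlf <- panel$z[panel$metric == "lf"]
    abnormal <- zlf < config$hrv$zCut
    utils::write.csv(cbind(subject = seq_len(syn$nSubjects),
                           as.data.frame(pat)),
                     file.path(outDir, "hrv_metrics.csv"), row.names = FALSE)
    utils::write.csv(panel, file.path(outDir, "hrv_zscores.csv"),
                     row.names = FALSE)
    res$hrv <- list(metrics = pat, controls = ctrl, norms = norms,
                    panel = panel, zlf = zlf, abnormal = abnormal)
  } else {
    zlf <- cohort$covariate
    abnormal <- zlf < stats::median(zlf)
  }

  ## ---- parallel ICA ---------------------------------------------------
  if (stages$pica) {
    covariate <- if (stages$hrv) as.numeric(scale(zlf)) else cohort$covariate
    k <- config$pica$k
    lesionMat <- t(vapply(cohort$maps,
                          function(m) as.numeric(mapValues(m)),
                          numeric(prod(syn$gridShape))))
    if (is.na(k)) k <- min(estimateComponentCount(lesionMat, seed = seed), 5L)
    cs <- fitParallelICA(cohort$maps, covariate, k = k,
                         nPerm = config$pica$nPerm, seed = seed)
    utils::write.csv(crossCorr(cs), file.path(outDir, "pica_correlations.csv"),
                     row.names = FALSE)
    res$pica <- cs
  }

  ## ---- lesion pattern -------------------------------------------------
  if (stages$lesions) {
    pattern <- componentMap(res$pica, tThresh = config$lesions$tThresh,
                            voxelSize = syn$voxelSize)
    pattern <- thresholdCluster(pattern, tThresh = 0,
                                minVoxels = config$lesions$minVoxels,
                                connectivity = config$lesions$connectivity)
    atlas <- genAtlas(syn$gridShape, 7L, syn$voxelSize)
    overlay <- atlasOverlay(pattern, atlas,
                            minVoxels = config$lesions$minVoxels)
    writeLesionMap(pattern, file.path(outDir, "lesion_pattern.nii.gz"))
    utils::write.csv(overlay, file.path(outDir, "lesion_overlay.csv"),
                     row.names = FALSE)
    res$lesionPattern <- pattern
    res$overlay <- overlay
  }

  ## ---- per-subject TPDC ----------------------------------------------
  if (stages$tpdc) {
    tp <- config$tpdc
    p <- tp$order
    nets <- sevenNetworks()
    profs <- vector("list", syn$nSubjects)
    for (s in seq_len(syn$nSubjects)) {
      A <- array(0, c(8, 8, p))
      diag(A[, , 1]) <- 0.3
      cpl <- if (abnormal[s]) syn$coupling else syn$coupling * 0.2
      A[1 + syn$couplingNetwork, 1, 1] <- cpl   # seed drives one network
      sim <- genMVARNetwork(A, nSamples = syn$tpdcSamples,
                            seed = seed + 3000L + s,
                            channelNames = c("Seed", nets))
      profs[[s]] <- connectivityProfile(
        sim$ts, order = p, band = tp$band, threshold = tp$threshold,
        subjectId = paste0("S", s), nFreq = tp$nFreq,
        timeStride = tp$timeStride, qParam = tp$qParam)
    }
    fwd <- t(vapply(profs, forwardValues, numeric(7)))
    bwd <- t(vapply(profs, backwardValues, numeric(7)))
    conn <- data.frame(subject = seq_len(syn$nSubjects), abnormal = abnormal,
                       fwd, bwd, check.names = FALSE)
    names(conn) <- c("subject", "abnormal", paste0("fwd_", nets),
                     paste0("bwd_", nets))
    utils::write.csv(conn, file.path(outDir, "connectivity_profiles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(conn, file.path(outDir, "connectivity_profiles.json"),
                         dataframe = "rows", digits = NA)
    res$profiles <- profs
    res$connectivity <- conn
  }

  ## ---- surrogate thresholds (first subject of each group) -------------
  if (stages$surrogates) {
    sg <- config$surrogates
    tp <- config$tpdc
    pick <- c(which(abnormal)[1], which(!abnormal)[1])
    pick <- pick[!is.na(pick)]
    fn <- makeTPDCPipeline(order = tp$order, band = tp$band,
                           sampleRateHz = 1, nFreq = tp$nFreq,
                           timeStride = tp$timeStride, qParam = tp$qParam)
    nulls <- lapply(pick, function(s) {
      A <- array(0, c(8, 8, tp$order)); diag(A[, , 1]) <- 0.3
      cpl <- if (abnormal[s]) syn$coupling else syn$coupling * 0.2
      A[1 + syn$couplingNetwork, 1, 1] <- cpl
      sim <- genMVARNetwork(A, nSamples = syn$tpdcSamples,
                            seed = seed + 3000L + s,
                            channelNames = c("Seed", sevenNetworks()))
      wl <- sg$windowLen
      windowShuffleNull(sim$ts, fn,
                        windowLen = if (is.na(wl)) NULL else wl,
                        nReal = sg$nReal, percentile = sg$percentile,
                        order = tp$order, seed = seed + 4000L + s)
    })
    names(nulls) <- paste0("S", pick)
    thr <- lapply(nulls, function(nl)
      list(threshold = as.list(nullThreshold(nl)),
           significant = as.list(nl@significant)))
    jsonlite::write_json(thr, file.path(outDir, "surrogate_thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    res$surrogates <- nulls
  }

  ## ---- group comparison ----------------------------------------------
  if (stages$compare && sum(abnormal) >= 3 && sum(!abnormal) >= 3) {
    cmp <- compareGroupProfiles(res$profiles[abnormal],
                                res$profiles[!abnormal],
                                method = config$compare$method,
                                nPerm = config$compare$nPerm,
                                bonferroni = config$compare$bonferroni,
                                seed = seed)
    utils::write.csv(cmp, file.path(outDir, "group_comparison.csv"),
                     row.names = FALSE)
    res$comparison <- cmp
  }

  ## ---- SVR validation -------------------------------------------------
  if (stages$svr) {
    sv <- config$svr
    feat <- as.matrix(res$connectivity[, -(1:2)])
    report <- svrValidate(feat, as.numeric(abnormal), gamma = sv$gamma,
                          gridMax = sv$gridMax, trainFrac = sv$trainFrac,
                          nFolds = sv$nFolds,
                          accuracyThreshold = sv$accuracyThreshold,
                          seed = seed)
    hdi <- credibleThreshold(as.numeric(feat))
    jsonlite::write_json(
      list(accuracy = report$accuracy, pass = report$pass,
           foldAccuracy = report$foldAccuracy,
           bestDegree = report$bestDegree, bestCost = report$bestCost,
           hdi = hdi$interval),
      file.path(outDir, "svr_report.json"), auto_unbox = TRUE, digits = NA)
    res$svr <- report
    res$hdi <- hdi
  }

  manifest <- list(
    package = "BrainHeart",
    packageVersion = as.character(utils::packageVersion("BrainHeart")),
    rVersion = R.version.string,
    seed = seed,
    stagesRun = names(Filter(isTRUE, stages)),
    parameters = config[setdiff(names(config), "stages")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
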