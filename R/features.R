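# Per-modality feature extraction: Fourier ECG features, image grid
# descriptor, patient-record statistics, nutrition feature engineering.
# Every operator returns a `modalityFeatures` object: a named numeric vector
# plus the modality tag, with degeneracies recorded as flags.

modalityFeatures <- function(modality, values, names) {
  stopifnot(length(values) == length(names))
  v <- as.numeric(values)
  names(v) <- names
  structure(list(modality = modality, values = v), class = "modalityFeatures")
}

#' @export
print.modalityFeatures <- function(x, ...) {
  cat(sprintf("modalityFeatures [%s]: %d features\n", x$modality, length(x$values)))
  print(utils::head(x$values, 10L))
  invisible(x)
}

#' Frequency-domain ECG features
#'
#' Computes the magnitude spectrum on the positive frequencies and emits the
#' top `nPeaks` spectral peak frequencies (Hz) with magnitudes normalized to
#' the strongest peak, plus band-power fractions over \[0,5), \[5,15),
#' \[15,40) and \[40, fs/2\] Hz (fractions of total positive-frequency power,
#' summing to 1 for non-degenerate signals).
#'
#' @param signal numeric ECG trace (length >= 16).
#' @param fs sampling frequency in Hz.
#' @param nPeaks number of dominant spectral peaks to report.
#' @return a `modalityFeatures` (modality `"ecg"`); an all-zero signal yields
#'   a zero vector flagged `"zero_signal"` (see [getFlags()]).
#' @export
ecgFourierFeatures <- function(signal, fs, nPeaks = 5L) {
  fs <- checkNumber(fs, "fs", min = 0, strict = TRUE)
  nPeaks <- checkCount(nPeaks, "nPeaks")
  n <- length(signal)
  if (n < 16L) stopParam("signal", "must have length >= 16")
  nms <- c(sprintf("peak_freq_%d", seq_len(nPeaks)),
           sprintf("peak_mag_%d", seq_len(nPeaks)),
           "band_0_5", "band_5_15", "band_15_40", "band_40_nyq")
  spectrum <- Mod(fft(signal))
  nPos <- floor(n / 2) + 1L
  freqs <- (seq_len(nPos) - 1L) / n * fs
  mag <- spectrum[seq_len(nPos)]
  if (all(mag == 0)) {
    out <- modalityFeatures("ecg", numeric(length(nms)), nms)
    return(setFlags(out, "zero_signal"))
  }
  power <- mag^2
  bandEdges <- c(0, 5, 15, 40, fs / 2)
  totalPower <- sum(power)
  bands <- vapply(seq_len(4L), function(b) {
    lo <- bandEdges[b]; hi <- bandEdges[b + 1L]
    inBand <- if (b < 4L) freqs >= lo & freqs < hi else freqs >= lo & freqs <= hi
    sum(power[inBand]) / totalPower
  }, numeric(1))
  # local maxima of the magnitude spectrum (interior bins), top nPeaks
  isPeak <- c(FALSE, mag[2:(nPos - 1L)] > mag[1:(nPos - 2L)] &
                mag[2:(nPos - 1L)] >= mag[3:nPos], FALSE)
  cand <- which(isPeak)
  if (length(cand) == 0L) cand <- which.max(mag)
  ord <- cand[order(mag[cand], decreasing = TRUE)]
  top <- utils::head(ord, nPeaks)
  pf <- pm <- numeric(nPeaks)
  pf[seq_along(top)] <- freqs[top]
  pm[seq_along(top)] <- mag[top] / mag[top[1L]]
  modalityFeatures("ecg", c(pf, pm, bands), nms)
}

#' Statistical summary of patient-record features
#'
#' Mean, population variance (`sum((x - mu)^2) / n`) and its square root, per
#' column for a matrix or for a single vector. The population form (divisor
#' `n`) is used deliberately, so `n = 1` gives variance 0.
#'
#' @param x numeric vector or samples x features matrix.
#' @return a `modalityFeatures` (modality `"record"`) with `mean_*`, `var_*`,
#'   `sd_*` entries.
#' @export
recordStatistics <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 1L) stopParam("x", "needs at least one row")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
    nm <- colnames(x)
    if (is.null(nm)) nm <- sprintf("f%02d", seq_len(ncol(x)))
  } else {
    if (length(x) < 1L) stopParam("x", "needs at least one value")
    mu <- mean(x)
    v <- mean((x - mu)^2)
    nm <- "x"
  }
  modalityFeatures("record",
                   c(mu, v, sqrt(v)),
                   c(paste0("mean_", nm), paste0("var_", nm), paste0("sd_", nm)))
}

#' Engineered nutrition features
#'
#' Aggregates the per-day intake table first, then forms ratios: total calorie
#' intake, saturated-to-total-fat ratio and protein-to-carbohydrate ratio.
#' Zero total fat yields ratio 0 with a flag; zero carbohydrate caps the
#' protein ratio at `ratioCap` with a flag. If a [kmeansDiet()] model is
#' supplied, the patient's diet-cluster membership is appended one-hot.
#'
#' @param nutrition per-day data.frame with columns `calories`, `total_fat`,
#'   `saturated_fat`, `protein`, `carbohydrate`.
#' @param clusterModel optional `clusterModel`; cluster is assigned by nearest
#'   centroid on the three engineered features.
#' @param ratioCap cap for the protein/carbohydrate ratio when carbohydrate
#'   intake is 0.
#' @return a `modalityFeatures` (modality `"nutrition"`).
#' @export
nutritionFeatures <- function(nutrition, clusterModel = NULL, ratioCap = 10) {
  need <- c("calories", "total_fat", "saturated_fat", "protein", "carbohydrate")
  if (!all(need %in% colnames(nutrition)))
    stopParam("nutrition", paste("needs columns", paste(need, collapse = ", ")))
  if (nrow(nutrition) == 0L) stopParam("nutrition", "table is empty")
  if (any(nutrition$total_fat < 0) || any(nutrition$protein < 0) ||
      any(nutrition$carbohydrate < 0) || any(nutrition$saturated_fat < 0))
    stopParam("nutrition", "intake values must be >= 0")
  flags <- character(0)
  totalCal <- sum(nutrition$calories)
  totFat <- sum(nutrition$total_fat)
  satFat <- sum(nutrition$saturated_fat)
  protein <- sum(nutrition$protein)
  carbs <- sum(nutrition$carbohydrate)
  fatRatio <- if (totFat == 0) { flags <- c(flags, "zero_total_fat"); 0 } else satFat / totFat
  pcr <- if (carbs == 0) { flags <- c(flags, "zero_carbohydrate"); ratioCap } else
    min(protein / carbs, ratioCap)
  vals <- c(total_calories = totalCal, fat_ratio = fatRatio,
            protein_carb_ratio = pcr)
  if (!is.null(clusterModel)) {
    if (!inherits(clusterModel, "clusterModel"))
      stopParam("clusterModel", "must come from kmeansDiet()")
    d2 <- colSums((t(clusterModel$centroids) - as.numeric(vals))^2)
    oneHotCl <- numeric(clusterModel$k)
    oneHotCl[which.min(d2)] <- 1
    names(oneHotCl) <- sprintf("diet_cluster_%d", seq_len(clusterModel$k))
    vals <- c(vals, oneHotCl)
  }
  out <- modalityFeatures("nutrition", vals, names(vals))
  setFlags(out, flags)
}

#' Grid descriptor of an image
#'
#' Tiles the image into a `grid[1]` x `grid[2]` lattice and records each
#' cell's mean intensity and mean gradient magnitude (forward differences),
#' giving `2 * prod(grid)` deterministic features. An externally computed
#' embedding (e.g. from a pretrained CNN) can be passed through the
#' `embedding` adapter instead, in which case it is returned verbatim.
#'
#' @param image numeric matrix, at least `grid` in both dimensions.
#' @param grid integer vector `c(gr, gc)` of tiling dimensions.
#' @param embedding optional numeric vector replacing the grid descriptor.
#' @return a `modalityFeatures` (modality `"image"`).
#' @export
imageDescriptor <- function(image, grid = c(4L, 4L), embedding = NULL) {
  if (!is.null(embedding)) {
    return(modalityFeatures("image", embedding,
                            sprintf("embed_%03d", seq_along(embedding))))
  }
  if (!is.matrix(image)) stopParam("image", "must be a numeric matrix")
  gr <- checkCount(grid[1], "grid[1]"); gc <- checkCount(grid[2], "grid[2]")
  r <- nrow(image); cc <- ncol(image)
  if (r < gr || cc < gc)
    stopParam("image", sprintf("image %dx%d smaller than grid %dx%d", r, cc, gr, gc))
  gradX <- rbind(image[-1, , drop = FALSE] - image[-r, , drop = FALSE], 0)
  gradY <- cbind(image[, -1, drop = FALSE] - image[, -cc, drop = FALSE], 0)
  gradMag <- sqrt(gradX^2 + gradY^2)
  rowBins <- ceiling(seq_len(r) / r * gr)
  colBins <- ceiling(seq_len(cc) / cc * gc)
  means <- grads <- numeric(gr * gc)
  cell <- 0L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      cell <- cell + 1L
      sel <- image[rowBins == i, colBins == j, drop = FALSE]
      selG <- gradMag[rowBins == i, colBins == j, drop = FALSE]
      means[cell] <- mean(sel)
      grads[cell] <- mean(selG)
    }
  }
  nms <- c(sprintf("mean_r%dc%d", rep(seq_len(gr), each = gc), rep(seq_len(gc), gr)),
           sprintf("grad_r%dc%d", rep(seq_len(gr), each = gc), rep(seq_len(gc), gr)))
  modalityFeatures("image", c(means, grads), nms)
}

#' Assemble per-modality feature matrices for a cohort
#'
#' Runs the preprocessing + feature-extraction pipeline over a cohort:
#' images are median-filtered and summarized by the grid descriptor; ECG
#' traces are band-pass filtered and summarized by their Fourier features;
#' records are min-max scaled (statistics fitted here, or frozen ones applied)
#' and carry their per-patient statistics; nutrition tables are engineered,
#' optionally with a diet-cluster one-hot.
#'
#' Feature scaling statistics (`minmaxStats` per modality block) are fitted on
#' the cohort when `stats = NULL` (training) and must be reused on held-out
#' cohorts, mirroring train-split-frozen normalization.
#'
#' @param cohort a `cardioCohort`.
#' @param medianWindow odd median-filter window for images.
#' @param band numeric `c(f1, f2)` band-pass edges in Hz (NULL to skip).
#' @param grid image descriptor tiling.
#' @param dietClusters number of diet clusters (0 to skip clustering).
#' @param includeRecordStats append per-patient record statistics
#'   (mean/var/sd of the scaled record vector).
#' @param stats frozen statistics from a previous call (training cohort); when
#'   NULL they are fitted on `cohort`.
#' @return a `cohortFeatures` object: `modalities` (named list of n x d_i
#'   matrices for `image`, `ecg`, `record`, `nutrition`), `labels`, `stats`
#'   (for reuse on held-out data), `featureNames`.
#' @export
cohortFeatures <- function(cohort, medianWindow = 3L, band = c(0.5, 40),
                           grid = c(4L, 4L), dietClusters = 3L,
                           includeRecordStats = TRUE, stats = NULL) {
  if (!inherits(cohort, "cardioCohort")) stopParam("cohort", "must be a cardioCohort")
  n <- nSamples(cohort)
  fs <- cohort$spec$ecgFs

  bp <- if (!is.null(band)) bandpassSpec(band[1], band[2], fs) else NULL

  ecgOne <- function(i) {
    s <- cohort$ecg[i, ]
    if (!is.null(bp)) s <- bandpass(s, bp)
    ecgFourierFeatures(s, fs)$values
  }
  ecgF <- t(vapply(seq_len(n), ecgOne, numeric(14L)))
  colnames(ecgF) <- names(ecgOne(1L))

  imgOne <- function(i)
    imageDescriptor(medianFilter(cohort$image[i, , ], medianWindow), grid)$values
  imgF <- t(vapply(seq_len(n), imgOne, numeric(2L * grid[1] * grid[2])))
  colnames(imgF) <- names(imgOne(1L))

  # records: min-max scale (train-frozen), then append per-patient statistics
  if (is.null(stats)) {
    recStats <- minmaxFit(cohort$records)
  } else recStats <- stats$record
  recScaled <- minmaxApply(cohort$records, recStats)
  recF <- recScaled
  if (includeRecordStats) {
    perPatient <- t(apply(recScaled, 1L, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2); c(mu, v, sqrt(v))
    }))
    colnames(perPatient) <- c("rec_mean", "rec_var", "rec_sd")
    recF <- cbind(recScaled, perPatient)
  }

  # nutrition: engineer per patient, cluster on the training cohort
  nutBase <- t(vapply(seq_len(n), function(i) {
    tab <- cohort$nutrition[cohort$nutrition$sample_id == i, , drop = FALSE]
    nutritionFeatures(tab)$values
  }, numeric(3L)))
  colnames(nutBase) <- c("total_calories", "fat_ratio", "protein_carb_ratio")
  clModel <- NULL
  if (dietClusters > 0L) {
    clModel <- if (is.null(stats)) {
      kmeansDiet(scale(nutBase), k = dietClusters, seed = cohort$spec$seed)
    } else stats$dietCluster
    centerAttr <- if (is.null(stats)) attr(scale(nutBase), "scaled:center") else stats$nutCenter
    scaleAttr <- if (is.null(stats)) attr(scale(nutBase), "scaled:scale") else stats$nutScale
    scaleAttr[scaleAttr == 0 | !is.finite(scaleAttr)] <- 1
    z <- sweep(sweep(nutBase, 2L, centerAttr), 2L, scaleAttr, "/")
    d2 <- outer(rowSums(z^2), rowSums(clModel$centroids^2), "+") -
      2 * z %*% t(clModel$centroids)
    memb <- max.col(-d2, ties.method = "first")
    oneHotCl <- matrix(0, n, clModel$k,
                       dimnames = list(NULL, sprintf("diet_cluster_%d", seq_len(clModel$k))))
    oneHotCl[cbind(seq_len(n), memb)] <- 1
    nutF <- cbind(nutBase, oneHotCl)
  } else nutF <- nutBase

  # per-modality min-max scaling of the assembled blocks (train-frozen)
  if (is.null(stats)) {
    blockStats <- list(ecg = minmaxFit(ecgF), image = minmaxFit(imgF),
                       recordBlock = minmaxFit(recF), nutrition = minmaxFit(nutF))
  } else blockStats <- stats$blocks
  modalities <- list(
    image = minmaxApply(imgF, blockStats$image),
    ecg = minmaxApply(ecgF, blockStats$ecg),
    record = minmaxApply(recF, blockStats$recordBlock),
    nutrition = minmaxApply(nutF, blockStats$nutrition)
  )
  sc <- scale(nutBase)
  out <- list(
    modalities = modalities,
    labels = cohort$labels,
    nClasses = cohort$spec$nClasses,
    stats = if (is.null(stats)) list(
      record = recStats, blocks = blockStats, dietCluster = clModel,
      nutCenter = attr(sc, "scaled:center"),
      nutScale = attr(sc, "scaled:scale")
    ) else stats,
    featureNames = lapply(modalities, colnames)
  )
  class(out) <- "cohortFeatures"
  out
}

#' @export
print.cohortFeatures <- function(x, ...) {
  dims <- vapply(x$modalities, ncol, integer(1))
  cat(sprintf("cohortFeatures: %d samples, %d classes | dims: %s\n",
              length(x$labels), x$nClasses,
              paste(sprintf("%s=%d", names(dims), dims), collapse = ", ")))
  invisible(x)
}

# ---- feature-statistics serialization ---------------------------------------

mmToList <- function(mm) list(hMin = as.numeric(mm$hMin), hMax = as.numeric(mm$hMax),
                              names = names(mm$hMin))
mmFromList <- function(l) {
  hMin <- as.numeric(l$hMin); hMax <- as.numeric(l$hMax)
  if (!is.null(l$names) && length(l$names)) names(hMin) <- names(hMax) <- l$names
  structure(list(hMin = hMin, hMax = hMax, constantMask = hMin == hMax),
            class = "minmaxStats")
}

#' Persist cohort feature statistics as JSON
#'
#' Saves the train-frozen scaling statistics and diet-cluster model of a
#' [cohortFeatures()] result so held-out cohorts can be featurized
#' consistently in a later session.
#'
#' @param stats the `$stats` element of a [cohortFeatures()] result.
#' @param path output JSON file.
#' @export
writeFeatureStats <- function(stats, path) {
  payload <- list(
    format = "cardiofed-feature-stats", version = 1L,
    record = mmToList(stats$record),
    blocks = lapply(stats$blocks, mmToList),
    nutCenter = as.numeric(stats$nutCenter),
    nutScale = as.numeric(stats$nutScale),
    dietCluster = if (is.null(stats$dietCluster)) NULL else list(
      k = stats$dietCluster$k,
      centroids = apply(stats$dietCluster$centroids, 1L, as.numeric,
                        simplify = FALSE))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read feature statistics written by [writeFeatureStats()]
#' @param path JSON file.
#' @export
readFeatureStats <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$format, "cardiofed-feature-stats"))
    stop("format error: not a cardiofed feature-statistics file", call. = FALSE)
  cl <- NULL
  if (!is.null(l$dietCluster)) {
    cen <- l$dietCluster$centroids
    cen <- if (is.list(cen)) do.call(rbind, lapply(cen, as.numeric)) else as.matrix(cen)
    cl <- structure(list(k = l$dietCluster$k, centroids = cen,
                         assignments = NULL, inertia = NA_real_,
                         inertiaPath = NA_real_),
                    class = "clusterModel")
  }
  list(record = mmFromList(l$record),
       blocks = lapply(l$blocks, mmFromList),
       dietCluster = cl,
       nutCenter = as.numeric(l$nutCenter),
       nutScale = as.numeric(l$nutScale))
}
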