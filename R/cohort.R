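# Synthetic multimodal cohort generation and federated partitioning.
#
# Every downstream stage (preprocessing, feature extraction, fusion, the
# classifier, the federated engine, the recommender) is exercised on cohorts
# produced here, so the generator is first-class, deterministic code with
# controllable class structure:
#   * ECG: classes are frequency-coded. Each class carries a class-specific
#     tone at f_c whose amplitude grows with the class-separation knob, on top
#     of a shared baseline-wander sinusoid, plus white noise of sd `noiseSd`.
#   * images: a smooth background plus a centred blob whose intensity shifts
#     with class (scaled by the separation knob), values clipped to [0, 1].
#   * records: unit-sd Gaussian features whose per-class means are exactly
#     `classSeparation` apart, so the single-feature Bayes error has the
#     closed form pnorm(-classSeparation / 2).
#   * nutrition: per-day (calories, total fat, saturated fat, protein,
#     carbohydrate) with class-shifted daily means; saturated fat is generated
#     as a fraction of total fat so the physical constraint sat <= total holds
#     by construction.

# Dominant class tones (Hz): one per class, spread over the clinical ECG bands
# reachable at fs = 125 Hz.
classToneHz <- function(nClasses) {
  base <- c(3, 8, 14, 20, 26, 32)
  if (nClasses <= length(base)) base[seq_len(nClasses)]
  else seq(3, 34, length.out = nClasses)
}

#' Specify a synthetic multimodal cohort
#'
#' @param nSamples number of patients.
#' @param nClasses number of disease classes (>= 2).
#' @param ecgLength ECG trace length in samples.
#' @param ecgFs ECG sampling frequency in Hz (default 125).
#' @param imageShape integer vector `c(rows, cols)` of the image grid.
#' @param nRecordFeatures number of tabular patient-record features.
#' @param nDaysNutrition days of nutrition logging per patient.
#' @param classSeparation effect size (>= 0) separating per-class means; record
#'   features have unit sd, so the two-class single-feature Bayes error is
#'   `pnorm(-classSeparation / 2)`.
#' @param noiseSd within-class noise scale (>= 0).
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return a `cohortSpec` list.
#' @export
cohortSpec <- function(nSamples, nClasses = 2L, ecgLength = 250L, ecgFs = 125,
                       imageShape = c(16L, 16L), nRecordFeatures = 13L,
                       nDaysNutrition = 7L, classSeparation = 4,
                       noiseSd = 1, seed = 1L) {
  spec <- list(
    nSamples = checkCount(nSamples, "nSamples"),
    nClasses = checkCount(nClasses, "nClasses", min = 2L),
    ecgLength = checkCount(ecgLength, "ecgLength", min = 16L),
    ecgFs = checkNumber(ecgFs, "ecgFs", min = 0, strict = TRUE),
    imageShape = c(checkCount(imageShape[1], "imageShape[1]", min = 4L),
                   checkCount(imageShape[2], "imageShape[2]", min = 4L)),
    nRecordFeatures = checkCount(nRecordFeatures, "nRecordFeatures"),
    nDaysNutrition = checkCount(nDaysNutrition, "nDaysNutrition"),
    classSeparation = checkNumber(classSeparation, "classSeparation", min = 0),
    noiseSd = checkNumber(noiseSd, "noiseSd", min = 0),
    seed = checkCount(seed, "seed", min = 0L)
  )
  class(spec) <- "cohortSpec"
  spec
}

#' Generate a labeled multimodal cohort
#'
#' Labels are balanced across classes (counts differ by at most one). All
#' class dependence is scaled by `spec$classSeparation`: at separation 0 every
#' class shares identical generating means in every modality.
#'
#' @param spec a [cohortSpec()].
#' @return a `cardioCohort`: columnar container with elements `ecg`
#'   (n x T matrix), `image` (n x rows x cols array), `records` (n x p matrix),
#'   `nutrition` (long data.frame with per-day intake), `labels` (0-based
#'   integer classes) and `spec`.
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "cohortSpec")) stopParam("spec", "must be a cohortSpec")
  n <- spec$nSamples; C <- spec$nClasses; sep <- spec$classSeparation
  withSeed(spec$seed, {
    # balanced labels, shuffled
    labels <- rep(seq_len(C) - 1L, length.out = n)
    labels <- sample(labels)

    # --- ECG ---------------------------------------------------------------
    tt <- (seq_len(spec$ecgLength) - 1L) / spec$ecgFs
    tones <- classToneHz(C)
    toneAmp <- min(1, 0.25 * sep)          # class tone vanishes at sep = 0
    ecg <- matrix(0, n, spec$ecgLength)
    for (i in seq_len(n)) {
      f <- tones[labels[i] + 1L]
      ph <- runif(2L, 0, 2 * pi)
      sig <- 0.3 * sin(2 * pi * 1 * tt + ph[1]) +
        toneAmp * sin(2 * pi * f * tt + ph[2])
      if (2 * f < spec$ecgFs / 2)
        sig <- sig + 0.4 * toneAmp * sin(2 * pi * 2 * f * tt + ph[2])
      ecg[i, ] <- sig + rnorm(spec$ecgLength, sd = spec$noiseSd)
    }

    # --- images ------------------------------------------------------------
    r <- spec$imageShape[1]; cc <- spec$imageShape[2]
    gx <- matrix(seq(0, 1, length.out = r), r, cc)
    gy <- matrix(seq(0, 1, length.out = cc), r, cc, byrow = TRUE)
    background <- 0.25 + 0.2 * gx + 0.1 * gy
    blob <- exp(-(((gx - 0.5)^2 + (gy - 0.5)^2) / (2 * 0.04)))
    img <- array(0, c(n, r, cc))
    for (i in seq_len(n)) {
      inten <- 0.3 + 0.08 * sep * labels[i]
      frame <- background + inten * blob +
        matrix(rnorm(r * cc, sd = 0.05 * spec$noiseSd), r, cc)
      img[i, , ] <- pmin(pmax(frame, 0), 1)
    }

    # --- patient records ----------------------------------------------------
    p <- spec$nRecordFeatures
    baseMeans <- seq(0, 1, length.out = p)  # fixed per-feature baseline
    rec <- matrix(rnorm(n * p, sd = spec$noiseSd), n, p)
    rec <- rec + matrix(baseMeans, n, p, byrow = TRUE) + sep * labels
    colnames(rec) <- sprintf("rec_%02d", seq_len(p))

    # --- nutrition ----------------------------------------------------------
    d <- spec$nDaysNutrition
    rows <- n * d
    lab <- rep(labels, each = d)
    nsd <- spec$noiseSd
    calories <- pmax(0, rnorm(rows, 2000 + 70 * sep * lab, 150 * nsd))
    totalFat <- pmax(0, rnorm(rows, 70 + 3 * sep * lab, 8 * nsd))
    satFrac <- pmin(pmax(rnorm(rows, 0.30 + 0.02 * sep * lab, 0.05 * nsd), 0), 0.9)
    protein <- pmax(0, rnorm(rows, 80 - 2 * sep * lab, 10 * nsd))
    carbs <- pmax(0, rnorm(rows, 250 + 8 * sep * lab, 20 * nsd))
    nutrition <- data.frame(
      sample_id = rep(seq_len(n), each = d),
      day = rep(seq_len(d), times = n),
      calories = calories,
      total_fat = totalFat,
      saturated_fat = satFrac * totalFat,
      protein = protein,
      carbohydrate = carbs
    )

    cohort <- list(ecg = ecg, image = img, records = rec,
                   nutrition = nutrition, labels = labels, spec = spec)
    class(cohort) <- "cardioCohort"
    cohort
  })
}

#' @export
print.cardioCohort <- function(x, ...) {
  cat(sprintf(
    "cardioCohort: %d samples, %d classes | ecg %d @ %g Hz | image %dx%d | %d record features | %d nutrition days\n",
    x$spec$nSamples, x$spec$nClasses, x$spec$ecgLength, x$spec$ecgFs,
    x$spec$imageShape[1], x$spec$imageShape[2], x$spec$nRecordFeatures,
    x$spec$nDaysNutrition))
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort a `cardioCohort`.
#' @export
nSamples <- function(cohort) length(cohort$labels)

#' Extract one patient as a multimodal sample
#'
#' @param cohort a `cardioCohort`.
#' @param i sample index (1-based).
#' @return list with `ecg`, `image`, `record`, `nutrition` (per-day table) and
#'   `label` (0-based class).
#' @export
getSample <- function(cohort, i) {
  i <- checkCount(i, "i")
  if (i > nSamples(cohort)) stopParam("i", "exceeds cohort size")
  list(ecg = cohort$ecg[i, ],
       image = cohort$image[i, , ],
       record = cohort$records[i, ],
       nutrition = cohort$nutrition[cohort$nutrition$sample_id == i,
                                    c("day", "calories", "total_fat",
                                      "saturated_fat", "protein", "carbohydrate")],
       label = cohort$labels[i])
}

#' Subset a cohort by sample indices
#' @param cohort a `cardioCohort`.
#' @param idx integer vector of 1-based sample indices.
#' @export
subsetCohort <- function(cohort, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > nSamples(cohort))) stopParam("idx", "out of range")
  nut <- cohort$nutrition[cohort$nutrition$sample_id %in% idx, , drop = FALSE]
  # renumber sample ids to the new positions
  nut$sample_id <- match(nut$sample_id, idx)
  nut <- nut[order(nut$sample_id, nut$day), , drop = FALSE]
  rownames(nut) <- NULL
  out <- list(ecg = cohort$ecg[idx, , drop = FALSE],
              image = cohort$image[idx, , , drop = FALSE],
              records = cohort$records[idx, , drop = FALSE],
              nutrition = nut,
              labels = cohort$labels[idx],
              spec = cohort$spec)
  out$spec$nSamples <- length(idx)
  class(out) <- "cardioCohort"
  out
}

#' Partition a cohort across federated nodes
#'
#' Balanced mode shuffles the indices and deals them out so node sizes differ
#' by at most one. Label-skew mode draws, for every class, a Dirichlet(alpha)
#' vector of node proportions and routes that class's samples accordingly
#' (smaller alpha = stronger non-IID skew).
#'
#' @param labels 0-based integer class labels (or a `cardioCohort`).
#' @param K number of nodes (1 <= K <= n).
#' @param mode `"balanced"` or `"dirichlet"`.
#' @param alpha Dirichlet concentration for skew mode.
#' @param seed RNG seed.
#' @return a `nodePartition`: list with `assignments` (list of disjoint index
#'   vectors covering 1..n), `mode`, `alpha`.
#' @export
partitionCohort <- function(labels, K, mode = c("balanced", "dirichlet"),
                            alpha = 0.5, seed = 1L) {
  if (inherits(labels, "cardioCohort")) labels <- labels$labels
  mode <- match.arg(mode)
  n <- length(labels)
  K <- checkCount(K, "K")
  if (K > n) stopParam("K", "cannot exceed the number of samples")
  withSeed(mixSeed(seed, 211L), {
    if (mode == "balanced") {
      idx <- sample.int(n)
      sizes <- rep(n %/% K, K)
      extra <- n %% K
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      assignments <- lapply(split(idx, rep(seq_len(K), times = sizes)), sort)
    } else {
      assignments <- vector("list", K)
      for (cl in sort(unique(labels))) {
        members <- sample(which(labels == cl))
        # Dirichlet(alpha) via normalized gammas
        w <- rgamma(K, shape = alpha)
        if (sum(w) == 0) w <- rep(1, K)
        p <- w / sum(w)
        node <- sample.int(K, length(members), replace = TRUE, prob = p)
        for (k in seq_len(K))
          assignments[[k]] <- c(assignments[[k]], members[node == k])
      }
      assignments <- lapply(assignments, function(v) if (is.null(v)) integer(0) else sort(v))
    }
    names(assignments) <- sprintf("node%d", seq_len(K))
    out <- list(assignments = assignments, mode = mode,
                alpha = if (mode == "dirichlet") alpha else NA_real_)
    class(out) <- "nodePartition"
    out
  })
}

#' @export
print.nodePartition <- function(x, ...) {
  sizes <- vapply(x$assignments, length, integer(1))
  cat(sprintf("nodePartition: %d nodes (%s), sizes %s\n",
              length(sizes), x$mode, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Layout: `manifest.json` (shapes, sampling frequency, label map, file list),
#' `labels.csv`, `records.csv`, `ecg.csv`, `images.csv` (row-major flattened),
#' `nutrition.csv`.
#'
#' @param cohort a `cardioCohort`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  if (!inherits(cohort, "cardioCohort")) stopParam("cohort", "must be a cardioCohort")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nSamples(cohort)
  sp <- cohort$spec
  manifest <- list(
    format = "cardiofed-cohort",
    version = 1L,
    nSamples = n, nClasses = sp$nClasses,
    ecgLength = sp$ecgLength, ecgFs = sp$ecgFs,
    imageShape = sp$imageShape,
    nRecordFeatures = sp$nRecordFeatures,
    nDaysNutrition = sp$nDaysNutrition,
    classSeparation = sp$classSeparation, noiseSd = sp$noiseSd,
    seed = sp$seed,
    labelMap = seq_len(sp$nClasses) - 1L,
    files = c("labels.csv", "records.csv", "ecg.csv", "images.csv", "nutrition.csv")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fw <- function(d, f) data.table::fwrite(d, file.path(path, f))
  fw(data.table::data.table(sample_id = seq_len(n), label = cohort$labels),
     "labels.csv")
  fw(data.table::data.table(sample_id = seq_len(n), cohort$records), "records.csv")
  ecgDT <- data.table::data.table(sample_id = seq_len(n), cohort$ecg)
  data.table::setnames(ecgDT, c("sample_id", sprintf("t%04d", seq_len(sp$ecgLength))))
  fw(ecgDT, "ecg.csv")
  flat <- t(vapply(seq_len(n),
                   function(i) as.vector(t(cohort$image[i, , ])),
                   numeric(sp$imageShape[1] * sp$imageShape[2])))
  imgDT <- data.table::data.table(sample_id = seq_len(n), flat)
  data.table::setnames(imgDT, c("sample_id", sprintf("px%04d", seq_len(ncol(flat)))))
  fw(imgDT, "images.csv")
  fw(data.table::as.data.table(cohort$nutrition), "nutrition.csv")
  invisible(path)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param path cohort directory.
#' @return a `cardioCohort`.
#' @export
readCohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("format error: missing manifest.json in ", path, call. = FALSE)
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                       error = function(e) stop("format error: unreadable manifest: ",
                                                conditionMessage(e), call. = FALSE))
  if (!identical(manifest$format, "cardiofed-cohort"))
    stop("format error: manifest is not a cardiofed cohort manifest", call. = FALSE)
  need <- c("labels.csv", "records.csv", "ecg.csv", "images.csv", "nutrition.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("format error: missing cohort file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rd <- function(f) as.data.frame(data.table::fread(file.path(path, f)))
  labels <- rd("labels.csv")
  records <- rd("records.csv")
  recMat <- as.matrix(records[, -1, drop = FALSE])
  bad <- which(!stats::complete.cases(recMat) | apply(recMat, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop(sprintf("validation error: non-finite record entry at row %d of records.csv",
                 bad[1]), call. = FALSE)
  ecg <- as.matrix(rd("ecg.csv")[, -1, drop = FALSE])
  imgFlat <- as.matrix(rd("images.csv")[, -1, drop = FALSE])
  shape <- as.integer(manifest$imageShape)
  n <- nrow(ecg)
  img <- array(0, c(n, shape[1], shape[2]))
  for (i in seq_len(n))
    img[i, , ] <- matrix(imgFlat[i, ], shape[1], shape[2], byrow = TRUE)
  spec <- cohortSpec(nSamples = manifest$nSamples, nClasses = manifest$nClasses,
                     ecgLength = manifest$ecgLength, ecgFs = manifest$ecgFs,
                     imageShape = shape,
                     nRecordFeatures = manifest$nRecordFeatures,
                     nDaysNutrition = manifest$nDaysNutrition,
                     classSeparation = manifest$classSeparation,
                     noiseSd = manifest$noiseSd, seed = manifest$seed)
  dimnames(ecg) <- NULL
  out <- list(ecg = ecg, image = img, records = recMat,
              nutrition = rd("nutrition.csv"),
              labels = as.integer(labels$label), spec = spec)
  class(out) <- "cardioCohort"
  out
}
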