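# Synthetic multi-scanner phantom study generator.
#
# Stands in for the physical acquisitions of a scanner-comparison study:
# textured single-tissue phantoms (kiwi-fruit analogs) and two-layer
# phantoms (cervix analogs, inner core + outer ring), pushed through
# monotone per-scanner intensity transforms, acquisition-parameter
# degradations and Rician noise, under a fully seeded study design.

#' Create a PhantomSpec
#'
#' @param gridShape voxel grid (3 integers, all >= 8).
#' @param voxelSpacing mm per axis.
#' @param layout "kiwi" (one tissue) or "cervix" (inner core + outer ring,
#'   delineated as two disjoint masks).
#' @param tissueMeans mean intensity per tissue (1 value for kiwi, 2 for
#'   cervix, inner first).
#' @param textureCorrLength texture correlation length in mm per tissue.
#' @param textureAmplitude texture standard deviation per tissue.
#' @param noiseSigma independent voxel noise SD.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 24L), voxelSpacing = c(1, 1, 1),
                        layout = c("kiwi", "cervix"), tissueMeans = 100,
                        textureCorrLength = 3, textureAmplitude = 15,
                        noiseSigma = 3) {
  layout <- match.arg(layout)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = rep_len(as.numeric(voxelSpacing), 3L), layout = layout,
      tissueMeans = as.numeric(tissueMeans),
      textureCorrLength = as.numeric(textureCorrLength),
      textureAmplitude = as.numeric(textureAmplitude),
      noiseSigma = as.numeric(noiseSigma))
}

#' Create a ScannerEffect
#'
#' @param gain multiplicative gain (> 0).
#' @param offset additive offset.
#' @param gamma monotone power nonlinearity (> 0).
#' @param ricianSigma Rician noise scale (>= 0).
#' @param inplaneDownsample in-plane spacing factor (>= 1), acquisition-matrix
#'   surrogate.
#' @param sliceMerge adjacent slices averaged per output slice (integer >= 1),
#'   slice-thickness / partial-volume surrogate.
#' @param blurFWHM Gaussian blur FWHM in mm (>= 0), contrast surrogate.
#' @return a \linkS4class{ScannerEffect}.
#' @export
scannerEffect <- function(gain = 1, offset = 0, gamma = 1, ricianSigma = 0,
                          inplaneDownsample = 1, sliceMerge = 1L, blurFWHM = 0) {
  new("ScannerEffect", gain = gain, offset = offset, gamma = gamma,
      ricianSigma = ricianSigma, inplaneDownsample = inplaneDownsample,
      sliceMerge = as.integer(sliceMerge), blurFWHM = blurFWHM)
}

# Cylindrical tissue masks on the phantom grid (mm geometry).
phantomMasks <- function(spec) {
  d <- spec@gridShape
  sp <- spec@voxelSpacing
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  x <- (seq_len(d[1]) - cx) * sp[1]
  y <- (seq_len(d[2]) - cy) * sp[2]
  r2 <- outer(x^2, y^2, "+")
  zIn <- seq_len(d[3]) > ceiling(d[3] * 0.12) & seq_len(d[3]) <= floor(d[3] * 0.88)
  radius <- min(d[1] * sp[1], d[2] * sp[2]) * 0.33
  inPlane <- r2 <= radius^2
  full <- array(FALSE, d)
  full[, , zIn] <- inPlane
  if (spec@layout == "kiwi") {
    list(tissue = full)
  } else {
    core <- array(FALSE, d)
    core[, , zIn] <- r2 <= (0.45 * radius)^2
    list(inner = core, outer = full & !core)
  }
}

#' Generate a textured phantom volume with its tissue mask(s)
#'
#' Each tissue is its mean intensity plus a band-limited Gaussian random
#' field (white noise smoothed to the tissue's correlation length, rescaled
#' to the stated amplitude) plus independent voxel noise. The same spec and
#' seed always reproduce the identical volume.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed.
#' @return a list with elements \code{image} (\linkS4class{VolumeImage}) and
#'   \code{masks} (named list of \linkS4class{VoxelMask}: \code{tissue} for
#'   the kiwi layout, \code{inner}/\code{outer} for the cervix layout).
#' @examples
#' ph <- generatePhantom(phantomSpec(layout = "kiwi"), seed = 1)
#' dim(voxelData(ph$image))
#' @export
generatePhantom <- function(spec, seed) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  masks <- phantomMasks(spec)
  d <- spec@gridShape
  set.seed(as.integer(seed))
  vol <- array(0.3 * spec@tissueMeans[1], d)  # dim background
  for (t in seq_along(masks)) {
    m <- masks[[t]]
    field <- array(0, d)
    if (spec@textureAmplitude[t] > 0) {
      white <- array(stats::rnorm(prod(d)), d)
      sigmaVox <- spec@textureCorrLength[t] / spec@voxelSpacing
      field <- gaussianSmooth3D(white, sigmaVox)
      s <- stats::sd(field)
      if (s > 0) field <- field / s * spec@textureAmplitude[t]
    } else {
      stats::rnorm(prod(d))  # keep the RNG stream aligned across amplitudes
    }
    vol[m] <- spec@tissueMeans[t] + field[m]
  }
  if (spec@noiseSigma > 0) vol <- vol + stats::rnorm(prod(d), sd = spec@noiseSigma)
  vol <- pmax(vol, 0)  # magnitude images are non-negative
  list(image = VolumeImage(vol, spec@voxelSpacing),
       masks = lapply(masks, VoxelMask, spacing = spec@voxelSpacing))
}

#' Apply a scanner/acquisition effect to a volume
#'
#' Applies, in order: the monotone intensity map gain * x^gamma + offset,
#' Gaussian blur, in-plane downsampling, adjacent-slice averaging, and
#' Rician noise (magnitude of two independent Gaussian channels). The
#' identity effect returns the input voxel-for-voxel.
#'
#' @param image a \linkS4class{VolumeImage} (non-negative intensities when
#'   gamma != 1).
#' @param effect a \linkS4class{ScannerEffect}.
#' @param seed integer seed for the noise channels.
#' @param mask optional \linkS4class{VoxelMask} carried through the same
#'   geometric degradations (nearest/majority, no noise).
#' @return a \linkS4class{VolumeImage}; when \code{mask} is given, a list
#'   with elements \code{image} and \code{mask}.
#' @export
applyScannerEffect <- function(image, effect, seed, mask = NULL) {
  stopifnot(is(image, "VolumeImage"), is(effect, "ScannerEffect"))
  validObject(effect)
  vol <- voxelData(image)
  sp <- voxelSpacing(image)
  if (effect@gamma != 1 && min(vol) < 0)
    stop("gamma != 1 requires non-negative intensities")
  vol <- effect@gain * (vol ^ effect@gamma) + effect@offset
  if (effect@blurFWHM > 0) {
    sigmaMM <- effect@blurFWHM / (2 * sqrt(2 * log(2)))
    vol <- gaussianSmooth3D(vol, sigmaMM / sp)
  }
  mvol <- if (!is.null(mask)) voxelData(mask) * 1 else NULL
  if (effect@inplaneDownsample > 1) {
    newSp <- c(sp[1:2] * effect@inplaneDownsample, sp[3])
    vol <- resampleArray(vol, sp, newSp, method = "cubic")
    if (!is.null(mvol)) mvol <- resampleArray(mvol, sp, newSp, method = "nearest")
    sp <- newSp
  }
  if (effect@sliceMerge > 1L) {
    f <- effect@sliceMerge
    nz <- dim(vol)[3] %/% f
    if (nz < 1L) stop("sliceMerge larger than the number of slices")
    merged <- array(0, c(dim(vol)[1:2], nz))
    mmerged <- if (!is.null(mvol)) array(0, c(dim(vol)[1:2], nz)) else NULL
    for (k in seq_len(nz)) {
      idx <- ((k - 1L) * f + 1L):(k * f)
      merged[, , k] <- apply(vol[, , idx, drop = FALSE], c(1, 2), mean)
      if (!is.null(mvol))
        mmerged[, , k] <- apply(mvol[, , idx, drop = FALSE], c(1, 2), mean)
    }
    vol <- merged
    mvol <- mmerged
    sp <- c(sp[1:2], sp[3] * f)
  }
  if (effect@ricianSigma > 0) {
    set.seed(as.integer(seed))
    n <- prod(dim(vol))
    g1 <- array(stats::rnorm(n, sd = effect@ricianSigma), dim(vol))
    g2 <- array(stats::rnorm(n, sd = effect@ricianSigma), dim(vol))
    vol <- sqrt((vol + g1)^2 + g2^2)
  }
  out <- VolumeImage(vol, sp, imageMeta(image))
  if (is.null(mask)) return(out)
  list(image = out, mask = VoxelMask(mvol >= 0.5, sp))
}

#' Default three-scanner panel
#'
#' Three scanners sharing a nominal protocol but differing in gain, offset
#' and gamma (the monotone inter-vendor intensity differences the decile
#' normalization is meant to remove), each with mild Rician noise.
#'
#' @param ricianSigma per-scan noise scale.
#' @return named list of \linkS4class{ScannerEffect}.
#' @export
defaultScannerPanel <- function(ricianSigma = 2) {
  list(
    PH = scannerEffect(gain = 1.00, offset = 0,  gamma = 1.00, ricianSigma = ricianSigma),
    GE = scannerEffect(gain = 1.60, offset = 25, gamma = 1.08, ricianSigma = ricianSigma),
    SI = scannerEffect(gain = 0.65, offset = 8,  gamma = 0.93, ricianSigma = ricianSigma))
}

#' Default acquisition-parameter sweeps
#'
#' Four single-parameter sweeps on the first scanner, everything else held
#' fixed: a 3-level repetition-time-like sweep (signal gain), a 4-level
#' echo-time-like sweep (contrast gamma), a 4-level slice-thickness sweep
#' (adjacent-slice averaging, labels in mm) and a 4-level acquisition-matrix
#' sweep (in-plane downsampling).
#'
#' @param ricianSigma per-scan noise scale.
#' @return list with elements \code{sweeps} (ScannerEffect lists) and
#'   \code{labels} (the nominal parameter values).
#' @export
defaultParameterSweeps <- function(ricianSigma = 2) {
  mk <- function(...) scannerEffect(..., ricianSigma = ricianSigma)
  sweeps <- list(
    TR = list(mk(gain = 1.00), mk(gain = 1.05), mk(gain = 1.10)),
    TE = list(mk(gamma = 1.00), mk(gamma = 1.05), mk(gamma = 1.10),
              mk(gamma = 1.15)),
    ST = list(mk(sliceMerge = 3L), mk(sliceMerge = 4L), mk(sliceMerge = 5L),
              mk(sliceMerge = 6L)),
    AM = list(mk(inplaneDownsample = 1.00), mk(inplaneDownsample = 1.15),
              mk(inplaneDownsample = 1.30), mk(inplaneDownsample = 1.45)))
  labels <- list(TR = c(3000, 4000, 5000), TE = c(80, 90, 100, 110),
                 ST = c(3, 4, 5, 6), AM = c("256x256", "320x256", "320x360",
                                            "380x280"))
  list(sweeps = sweeps, labels = labels)
}

#' Create a StudyDesign
#'
#' @param nKiwi number of single-tissue phantom subjects (group G.0).
#' @param nVolunteer number of two-layer subjects, assigned to groups
#'   G.1, G.2, G.3 in blocks of three (shorter lists stay in G.1, ...).
#' @param scanners named list of ScannerEffect (inter-scanner panel).
#' @param sweeps,sweepLabels parameter sweeps and their level labels; by
#'   default \code{\link{defaultParameterSweeps}}.
#' @param phantomSpecs named list of PhantomSpec per layout ("kiwi",
#'   "cervix").
#' @param masterSeed integer master seed; every session seed is derived
#'   from it deterministically.
#' @return a \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(nKiwi = 3L, nVolunteer = 9L,
                        scanners = defaultScannerPanel(),
                        sweeps = NULL, sweepLabels = NULL,
                        phantomSpecs = NULL, masterSeed = 20260101L) {
  if (is.null(sweeps)) {
    dflt <- defaultParameterSweeps()
    sweeps <- dflt$sweeps
    sweepLabels <- dflt$labels
  }
  if (is.null(sweepLabels))
    sweepLabels <- lapply(sweeps, seq_along)
  if (is.null(phantomSpecs)) {
    phantomSpecs <- list(
      kiwi = phantomSpec(layout = "kiwi", tissueMeans = 100,
                         textureCorrLength = 3, textureAmplitude = 15,
                         noiseSigma = 3),
      cervix = phantomSpec(layout = "cervix", tissueMeans = c(120, 80),
                           textureCorrLength = c(2.5, 4),
                           textureAmplitude = c(15, 12), noiseSigma = 3))
  }
  subjects <- data.frame(
    subject = c(if (nKiwi) paste0("K", seq_len(nKiwi)),
                if (nVolunteer) paste0("V", seq_len(nVolunteer))),
    group = c(rep("G.0", nKiwi),
              if (nVolunteer) paste0("G.", pmin(3L, (seq_len(nVolunteer) - 1L) %/% 3L + 1L))),
    layout = c(rep("kiwi", nKiwi), rep("cervix", nVolunteer)),
    stringsAsFactors = FALSE)
  new("StudyDesign", subjects = subjects, scanners = scanners,
      sweeps = sweeps, sweepLabels = sweepLabels, phantomSpecs = phantomSpecs,
      masterSeed = as.integer(masterSeed))
}

# Metadata labels for one session row of the manifest.
sessionLabels <- function(arm, sweep, levelIdx, labels) {
  nominal <- list(TR = 3000, TE = 80, ST = 5, AM = "256x256")
  if (arm == "inter") return(nominal)
  nominal[[sweep]] <- labels[[sweep]][levelIdx]
  nominal
}

#' Generate all sessions of a study design
#'
#' Inter-scanner arm: each subject once per scanner under the shared nominal
#' protocol. Intra-scanner arm: each subject once per level of every sweep,
#' on the first scanner, one parameter varied at a time. Each subject's
#' underlying phantom is fixed across all of its sessions (the same object
#' rescanned); only the scanner effect and noise vary. Seeds are derived
#' deterministically from the master seed, so two runs with the same design
#' produce identical session tables.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return list with \code{sessions} (named list; each element has
#'   \code{image}, \code{masks}, \code{info}) and \code{manifest}
#'   (data.frame: session_id, subject, group, layout, arm, scanner, sweep,
#'   level, TR, TE, ST, AM, seed).
#' @export
generateStudy <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  ms <- design@masterSeed
  subjects <- design@subjects
  phantoms <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects$subject[i]
    phantoms[[s]] <- generatePhantom(design@phantomSpecs[[subjects$layout[i]]],
                                     seed = deriveSeed(ms, "phantom", s))
  }
  sessions <- list()
  rows <- list()
  addSession <- function(subjRow, arm, scanner, sweep, levelIdx, effect) {
    s <- subjRow$subject
    cond <- if (arm == "inter") scanner else paste0(sweep, levelIdx)
    id <- paste(s, arm, cond, sep = "_")
    seed <- deriveSeed(ms, "session", s, arm, cond)
    ph <- phantoms[[s]]
    out <- applyScannerEffect(ph$image, effect, seed = seed,
                              mask = unionMask(ph$masks))
    masks <- list(voi = out$mask)
    if (subjRow$layout == "cervix") {
      for (nm in c("inner", "outer")) {
        mo <- applyScannerEffect(ph$image, stripNoise(effect), seed = seed,
                                 mask = ph$masks[[nm]])
        masks[[nm]] <- mo$mask
      }
    }
    lab <- sessionLabels(arm, sweep, levelIdx, design@sweepLabels)
    info <- list(session_id = id, subject = s, group = subjRow$group,
                 layout = subjRow$layout, arm = arm, scanner = scanner,
                 sweep = sweep, level = levelIdx, TR = lab$TR, TE = lab$TE,
                 ST = lab$ST, AM = lab$AM, seed = seed)
    out$image@meta <- info
    sessions[[id]] <<- list(image = out$image, masks = masks, info = info)
    rows[[id]] <<- as.data.frame(info, stringsAsFactors = FALSE)
  }
  scannerNames <- names(design@scanners)
  if (is.null(scannerNames)) scannerNames <- paste0("S", seq_along(design@scanners))
  for (i in seq_len(nrow(subjects))) {
    for (j in seq_along(design@scanners)) {
      addSession(subjects[i, ], "inter", scannerNames[j], NA_character_, NA_integer_,
                 design@scanners[[j]])
    }
  }
  for (i in seq_len(nrow(subjects))) {
    for (sw in names(design@sweeps)) {
      for (li in seq_along(design@sweeps[[sw]])) {
        addSession(subjects[i, ], "intra", scannerNames[1], sw, li,
                   design@sweeps[[sw]][[li]])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(sessions = sessions, manifest = manifest)
}

# Union of a list of VoxelMask sharing a grid.
unionMask <- function(masks) {
  v <- Reduce(`|`, lapply(masks, voxelData))
  VoxelMask(v, voxelSpacing(masks[[1]]))
}

# Same geometric degradation, no stochastic noise (used to carry the layer
# masks of two-layer subjects through a session's geometry).
stripNoise <- function(effect) {
  scannerEffect(gain = effect@gain, offset = effect@offset, gamma = effect@gamma,
                ricianSigma = 0, inplaneDownsample = effect@inplaneDownsample,
                sliceMerge = effect@sliceMerge, blurFWHM = effect@blurFWHM)
}
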