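#' @import methods
#' @importFrom stats rnorm runif rpois sd quantile median mad setNames ks.test
#' @importFrom utils read.csv write.csv
NULL

CHANNELS <- c("DAPI", "DNA", "RNA")
ROUNDS <- c("single", "rna_round", "dna_round")

#' Parse a 384-well plate well label
#'
#' Well labels follow the 384-well convention: a row letter A--P followed by
#' a column number 1--24 (zero-padded or not, e.g. \code{"B07"} or \code{"B7"}).
#'
#' @param well Character vector of well labels.
#' @return A data.frame with columns \code{row} (1--16) and \code{col} (1--24).
#' @examples
#' parseWell(c("A01", "P24"))
#' @export
parseWell <- function(well) {
  ok <- grepl("^[A-P]([1-9]|0[1-9]|1[0-9]|2[0-4])$", well)
  if (!all(ok))
    stop("invalid 384-well label(s): ", paste(well[!ok], collapse = ", "),
         " (rows A-P, columns 1-24)")
  data.frame(row = match(substr(well, 1, 1), LETTERS),
             col = as.integer(substring(well, 2)))
}

validChannelImage <- function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.matrix(px) || length(dim(px)) != 2L)
    msg <- c(msg, "pixels must be a 2D matrix")
  maxval <- 2^object@bitDepth - 1
  if (is.matrix(px) && length(px) &&
      (min(px) < 0 || max(px) > maxval))
    msg <- c(msg, sprintf("intensities must lie in [0, %d]", maxval))
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (!object@channel %in% CHANNELS)
    msg <- c(msg, "channel must be one of DAPI, DNA, RNA")
  if (!object@round %in% ROUNDS)
    msg <- c(msg, "round must be one of single, rna_round, dna_round")
  tw <- tryCatch(parseWell(object@well), error = function(e) conditionMessage(e))
  if (is.character(tw)) msg <- c(msg, tw)
  if (length(msg)) msg else TRUE
}

#' ChannelImage: one 2D fluorescence acquisition
#'
#' A single-channel 2D 16-bit grayscale field image tagged with its plate,
#' well, field, channel (DAPI / DNA probe / RNA probe), acquisition round and
#' physical pixel size.  Pixels are stored as a numeric matrix indexed
#' \code{[y + 1, x + 1]} for the 0-based pixel coordinate \code{(x, y)}
#' (x = column, y = row).
#'
#' @slot pixels Numeric matrix of intensities in \code{[0, 2^bitDepth - 1]}.
#' @slot plate Plate identifier.
#' @slot well 384-well label (rows A--P, columns 1--24).
#' @slot field Field-of-view index within the well.
#' @slot channel One of \code{"DAPI"}, \code{"DNA"}, \code{"RNA"}.
#' @slot round Acquisition round: \code{"single"} (simultaneous mode) or
#'   \code{"rna_round"} / \code{"dna_round"} (sequential mode).
#' @slot pixelSizeUm Physical pixel size in microns (default 0.108).
#' @slot bitDepth Camera bit depth (16).
#' @export
setClass("ChannelImage",
  representation(pixels = "matrix", plate = "character", well = "character",
                 field = "integer", channel = "character", round = "character",
                 pixelSizeUm = "numeric", bitDepth = "integer",
                 registeredShift = "integer"),
  prototype(plate = "plate01", well = "A01", field = 1L, channel = "DAPI",
            round = "single", pixelSizeUm = 0.108, bitDepth = 16L,
            registeredShift = integer(0)),
  validity = validChannelImage)

#' Construct a ChannelImage
#'
#' @param pixels Numeric matrix of intensities (indexed \code{[y+1, x+1]}).
#' @param plate,well,field,channel,round Image provenance metadata.
#' @param pixelSizeUm Pixel size in microns.
#' @param bitDepth Bit depth (default 16).
#' @return A \linkS4class{ChannelImage}.
#' @examples
#' img <- ChannelImage(matrix(0, 32, 32), well = "B07", channel = "DNA")
#' dim(pixels(img))
#' @export
ChannelImage <- function(pixels, plate = "plate01", well = "A01", field = 1L,
                         channel = "DAPI", round = "single",
                         pixelSizeUm = 0.108, bitDepth = 16L) {
  new("ChannelImage", pixels = pixels, plate = plate, well = well,
      field = as.integer(field), channel = channel, round = round,
      pixelSizeUm = pixelSizeUm, bitDepth = as.integer(bitDepth))
}

validLabeledMask <- function(object) {
  msg <- character()
  lab <- object@labels
  if (!is.matrix(lab)) msg <- c(msg, "labels must be a matrix")
  if (is.matrix(lab) && length(lab) && min(lab) < 0)
    msg <- c(msg, "labels must be non-negative")
  if (is.matrix(lab) && length(lab)) {
    u <- sort(unique(as.integer(lab[lab > 0])))
    if (length(u) && !identical(u, seq_along(u)))
      msg <- c(msg, "labels must be consecutive 1..K")
  }
  if (length(msg)) msg else TRUE
}

#' LabeledMask: segmented nuclei as a label image
#'
#' Integer label image with background 0 and nuclei labelled consecutively
#' 1..K, carrying the provenance of the DAPI image it was derived from.
#'
#' @slot labels Integer matrix, same shape as the source image.
#' @slot plate,well,field,round Provenance.
#' @slot pixelSizeUm Pixel size in microns, inherited from the source image.
#' @export
setClass("LabeledMask",
  representation(labels = "matrix", plate = "character", well = "character",
                 field = "integer", round = "character",
                 pixelSizeUm = "numeric"),
  prototype(plate = "plate01", well = "A01", field = 1L, round = "single",
            pixelSizeUm = 0.108),
  validity = validLabeledMask)

#' @rdname LabeledMask-class
#' @param labels Integer label matrix (0 = background).
#' @param plate,well,field,round Provenance metadata.
#' @param pixelSizeUm Pixel size in microns.
#' @return A \linkS4class{LabeledMask}.
#' @export
LabeledMask <- function(labels, plate = "plate01", well = "A01", field = 1L,
                        round = "single", pixelSizeUm = 0.108) {
  storage.mode(labels) <- "integer"
  new("LabeledMask", labels = labels, plate = plate, well = well,
      field = as.integer(field), round = round, pixelSizeUm = pixelSizeUm)
}

#' TranslationVector: an estimated rigid in-plane shift
#'
#' The integer translation aligning a moving image to a reference image, as
#' found at the peak of the cross-correlation surface, together with the peak
#' value and the margin separating it from the best non-neighbouring peak.
#'
#' @slot dxPx,dyPx Integer shift components (x = column, y = row).
#' @slot peakValue Cross-correlation value at the peak.
#' @slot correlationMargin Peak value minus the largest value at a
#'   displacement not 8-adjacent to the peak (a confidence measure).
#' @slot maxShift Half-width of the searched displacement window.
#' @export
setClass("TranslationVector",
  representation(dxPx = "integer", dyPx = "integer", peakValue = "numeric",
                 correlationMargin = "numeric", maxShift = "integer"))

#' @rdname TranslationVector-class
#' @param dxPx,dyPx Integer shift components.
#' @param peakValue,correlationMargin Peak statistics (NA if constructed
#'   manually).
#' @param maxShift Search half-width.
#' @return A \linkS4class{TranslationVector}.
#' @export
TranslationVector <- function(dxPx, dyPx, peakValue = NA_real_,
                              correlationMargin = NA_real_,
                              maxShift = NA_integer_) {
  new("TranslationVector", dxPx = as.integer(dxPx), dyPx = as.integer(dyPx),
      peakValue = as.numeric(peakValue),
      correlationMargin = as.numeric(correlationMargin),
      maxShift = as.integer(maxShift))
}

validSceneSpec <- function(object) {
  msg <- character()
  p <- object@expressionProbs
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    msg <- c(msg, "expressionProbs must be 3 non-negative values summing to 1 (within 1e-12)")
  if (any(object@imageSizePx < 16L))
    msg <- c(msg, "imageSizePx too small")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (object@nNuclei < 0) msg <- c(msg, "nNuclei must be non-negative")
  if (object@nucleusRadiusUm[1] <= 0 || object@nucleusRadiusUm[2] < 0)
    msg <- c(msg, "nucleusRadiusUm must be (mean > 0, sd >= 0)")
  if (object@nucleusEccentricity < 0 || object@nucleusEccentricity >= 1)
    msg <- c(msg, "nucleusEccentricity must be in [0, 1)")
  if (object@rnaOffsetSigmaUm < 0) msg <- c(msg, "rnaOffsetSigmaUm must be >= 0")
  if (object@minDnaSeparationUm < 0)
    msg <- c(msg, "minDnaSeparationUm must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  # generous placement bound: a 3-sigma nucleus must fit inside the frame
  rmaxpx <- (object@nucleusRadiusUm[1] + 3 * object@nucleusRadiusUm[2]) /
    object@pixelSizeUm
  if (object@nNuclei > 0 && 2 * rmaxpx >= min(object@imageSizePx))
    msg <- c(msg, "nuclei do not fit inside the image frame")
  for (cls in c("silent", "mono", "bi")) {
    rp <- object@radialPlacement[[cls]]
    if (is.null(rp) || rp$power <= 0 || rp$rhoMax <= 0 || rp$rhoMax > 1)
      msg <- c(msg, sprintf("radialPlacement$%s must have power > 0 and rhoMax in (0, 1]", cls))
  }
  if (length(msg)) msg else TRUE
}

#' SceneSpec: parameters of a synthetic FISH scene
#'
#' Full parameterization of one synthetic field: geometry and intensity of
#' nuclei, expression-state probabilities, DNA-spot radial placement law,
#' RNA-spot offsets, inter-round shift for sequential acquisition, and noise.
#' All randomness is governed by \code{seed}; an identical spec renders to
#' bit-identical images and truths.
#'
#' @slot imageSizePx Integer pair (rows, cols); default 512 x 512.
#' @slot pixelSizeUm Pixel size in microns; default 0.108.
#' @slot nNuclei Number of nuclei to place.
#' @slot nucleusRadiusUm (mean, sd) of nucleus equivalent radius in microns.
#' @slot nucleusEccentricity Ellipse eccentricity in [0, 1).
#' @slot expressionProbs Named triple (silent, mono, bi) summing to 1.
#' @slot radialPlacement Per-state list; each entry has \code{power} and
#'   \code{rhoMax}: the DNA-spot normalized radius is drawn as
#'   \code{rhoMax * U^(1/power)} (power 1 = uniform, power 2 = periphery-
#'   skewed).
#' @slot minDnaSeparationUm Minimum separation between the two DNA spots of
#'   a nucleus (microns, default 2): homologous alleles occupy distinct
#'   chromosome territories, and the separation keeps the simulated
#'   activity truth unambiguous under the 1.0 um proximity rule.
#' @slot rnaOffsetSigmaUm Isotropic Gaussian sd of the RNA-to-DNA spot offset
#'   at active alleles, microns; default 0.15 (so essentially all true
#'   offsets fall below the 1.0 micron activity rule).
#' @slot decoyRnaRate Expected number per nucleus of decoy RNA spots placed
#'   far (>= 1.5 um) from any DNA spot; default 0.
#' @slot interRoundShiftPx Integer (dx, dy) applied to the second
#'   (DNA-probe) acquisition round in sequential mode.
#' @slot spotIntensity List with entries \code{DNA} and \code{RNA}, each
#'   (mean, sd) of spot peak amplitude in camera counts.
#' @slot spotSigmaPx Rendered spot Gaussian sd in pixels (default 1.5).
#' @slot nucleusIntensity DAPI amplitude of nuclei in camera counts.
#' @slot backgroundLevel Constant background offset in counts.
#' @slot noiseSigma Gaussian read-noise sd in counts.
#' @slot bitDepth Camera bit depth (16).
#' @slot seed Integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(imageSizePx = "integer", pixelSizeUm = "numeric",
                 nNuclei = "integer", nucleusRadiusUm = "numeric",
                 nucleusEccentricity = "numeric", expressionProbs = "numeric",
                 radialPlacement = "list", minDnaSeparationUm = "numeric",
                 rnaOffsetSigmaUm = "numeric",
                 decoyRnaRate = "numeric", interRoundShiftPx = "integer",
                 spotIntensity = "list", spotSigmaPx = "numeric",
                 nucleusIntensity = "numeric", backgroundLevel = "numeric",
                 noiseSigma = "numeric", bitDepth = "integer",
                 seed = "integer"),
  validity = validSceneSpec)

#' Construct a SceneSpec
#'
#' Defaults emulate the acquisition geometry of a high-throughput spinning-
#' disk confocal (0.108 um pixels, 16-bit) at a reduced 512 x 512 frame, with
#' nuclei of ~10 um diameter, two DNA spots per nucleus, and expression-state
#' probabilities matching a predominantly silent gene.
#'
#' @param imageSizePx,pixelSizeUm,nNuclei,nucleusRadiusUm,nucleusEccentricity
#'   Scene geometry; see \linkS4class{SceneSpec}.
#' @param expressionProbs Probability triple (silent, mono, bi).
#' @param radialPlacement Either one list \code{list(power=, rhoMax=)} used
#'   for every expression state, or a named list with entries
#'   \code{silent}, \code{mono}, \code{bi}.
#' @param minDnaSeparationUm Minimum DNA-DNA spot separation (microns).
#' @param rnaOffsetSigmaUm,decoyRnaRate RNA-spot placement parameters.
#' @param interRoundShiftPx Integer (dx, dy) between sequential rounds.
#' @param spotIntensity,spotSigmaPx,nucleusIntensity,backgroundLevel,noiseSigma
#'   Rendering intensities (camera counts).
#' @param bitDepth,seed Bit depth and RNG seed.
#' @return A validated \linkS4class{SceneSpec}.
#' @examples
#' spec <- SceneSpec(nNuclei = 4, seed = 1)
#' spec
#' @export
SceneSpec <- function(imageSizePx = c(512L, 512L), pixelSizeUm = 0.108,
                      nNuclei = 8L,
                      nucleusRadiusUm = c(mean = 5, sd = 0.4),
                      nucleusEccentricity = 0.2,
                      expressionProbs = c(silent = 0.66, mono = 0.27, bi = 0.07),
                      radialPlacement = list(power = 1, rhoMax = 0.9),
                      minDnaSeparationUm = 2,
                      rnaOffsetSigmaUm = 0.15, decoyRnaRate = 0,
                      interRoundShiftPx = c(0L, 0L),
                      spotIntensity = list(DNA = c(mean = 1200, sd = 120),
                                           RNA = c(mean = 1200, sd = 120)),
                      spotSigmaPx = 1.5, nucleusIntensity = 2500,
                      backgroundLevel = 300, noiseSigma = 30,
                      bitDepth = 16L, seed = 1L) {
  if (!is.null(radialPlacement$power))  # single law for all states
    radialPlacement <- list(silent = radialPlacement, mono = radialPlacement,
                            bi = radialPlacement)
  new("SceneSpec", imageSizePx = as.integer(imageSizePx),
      pixelSizeUm = pixelSizeUm, nNuclei = as.integer(nNuclei),
      nucleusRadiusUm = unname(nucleusRadiusUm),
      nucleusEccentricity = nucleusEccentricity,
      expressionProbs = setNames(as.numeric(expressionProbs),
                                 c("silent", "mono", "bi")),
      radialPlacement = radialPlacement,
      minDnaSeparationUm = minDnaSeparationUm,
      rnaOffsetSigmaUm = rnaOffsetSigmaUm, decoyRnaRate = decoyRnaRate,
      interRoundShiftPx = as.integer(interRoundShiftPx),
      spotIntensity = spotIntensity, spotSigmaPx = spotSigmaPx,
      nucleusIntensity = nucleusIntensity, backgroundLevel = backgroundLevel,
      noiseSigma = noiseSigma, bitDepth = as.integer(bitDepth),
      seed = as.integer(seed))
}

#' SceneTruth: ground truth of a rendered scene
#'
#' Records the exact placement and state of every simulated nucleus and spot,
#' for recovery testing of the analysis pipeline.  Spot coordinates are in
#' the unshifted (RNA-round / simultaneous) frame; \code{shift} records the
#' translation applied to the second round in sequential mode.
#'
#' @slot nuclei data.frame: nucleus, cx_px, cy_px, rx_px, ry_px, theta, state.
#' @slot spots data.frame: nucleus, channel, x_px, y_px, radial_true.
#' @slot shift Integer (dx, dy) applied to the dna_round images.
#' @slot mode "simultaneous" or "sequential".
#' @export
setClass("SceneTruth",
  representation(nuclei = "data.frame", spots = "data.frame",
                 shift = "integer", mode = "character"),
  prototype(shift = c(0L, 0L), mode = "simultaneous"))

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage %s/%s f%d [%s, %s] %dx%d px @ %.3f um/px, range [%g, %g]\n",
              object@plate, object@well, object@field, object@channel,
              object@round, nrow(object@pixels), ncol(object@pixels),
              object@pixelSizeUm,
              if (length(object@pixels)) min(object@pixels) else NA,
              if (length(object@pixels)) max(object@pixels) else NA))
})

setMethod("show", "LabeledMask", function(object) {
  cat(sprintf("LabeledMask %s/%s f%d [%s] %dx%d px, %d nuclei\n",
              object@plate, object@well, object@field, object@round,
              nrow(object@labels), ncol(object@labels),
              max(object@labels, 0L)))
})

setMethod("show", "TranslationVector", function(object) {
  cat(sprintf("TranslationVector (dx = %d, dy = %d) peak = %.4g margin = %.4g\n",
              object@dxPx, object@dyPx, object@peakValue,
              object@correlationMargin))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec %dx%d px @ %.3f um/px, %d nuclei, probs (%.2f, %.2f, %.2f), seed %d\n",
              object@imageSizePx[1], object@imageSizePx[2], object@pixelSizeUm,
              object@nNuclei, object@expressionProbs[1],
              object@expressionProbs[2], object@expressionProbs[3],
              object@seed))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth (%s): %d nuclei, %d spots, shift (%d, %d)\n",
              object@mode, nrow(object@nuclei), nrow(object@spots),
              object@shift[1], object@shift[2]))
})
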