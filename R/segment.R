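# Nucleus segmentation from the DAPI channel and QC geometry.
# Classical pipeline: Gaussian smoothing -> Otsu threshold -> hole filling
# -> distance-transform watershed split -> small-object removal.

#' Segment nuclei from a DAPI image
#'
#' @param dapi A DAPI-channel \linkS4class{ChannelImage}.
#' @param minAreaPx Minimum object area in pixels; smaller components are
#'   removed as debris.
#' @param smoothingSigmaPx Gaussian smoothing sd in pixels applied before
#'   thresholding.
#' @param watershedTolerance Minimum depth separating two intensity maxima
#'   of the distance map for them to seed distinct nuclei.
#' @return A \linkS4class{LabeledMask} with consecutive labels 1..K
#'   (possibly 0 labels for an all-background image).
#' @export
segmentNuclei <- function(dapi, minAreaPx = 500L, smoothingSigmaPx = 2,
                          watershedTolerance = 1) {
  stopifnot(is(dapi, "ChannelImage"))
  maxval <- 2^dapi@bitDepth - 1
  im <- dapi@pixels / maxval
  emptyMask <- function() LabeledMask(
    matrix(0L, nrow(im), ncol(im)), plate = dapi@plate, well = dapi@well,
    field = dapi@field, round = dapi@round, pixelSizeUm = dapi@pixelSizeUm)
  if (diff(range(im)) < 1e-9) return(emptyMask())

  sm <- EBImage::gblur(im, sigma = smoothingSigmaPx)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bw <- sm > thr
  if (!any(bw)) return(emptyMask())
  bw <- EBImage::fillHull(bw)
  dist <- EBImage::distmap(bw, metric = "euclidean")
  lab <- EBImage::watershed(dist, tolerance = watershedTolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"

  # drop small components and relabel consecutively (by original label order)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= minAreaPx)
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0L
  lab[nz] <- remap[lab[nz]]
  LabeledMask(lab, plate = dapi@plate, well = dapi@well, field = dapi@field,
              round = dapi@round, pixelSizeUm = dapi@pixelSizeUm)
}

#' Crofton perimeter of a binary mask
#'
#' Cauchy--Crofton estimate from boundary intercepts along four line
#' directions (horizontal, vertical, both diagonals).  Far less biased on
#' rasterized smooth shapes than counting pixel edges, which systematically
#' deflates circularity of discs.
#'
#' @param bw Logical or 0/1 matrix.
#' @return Perimeter estimate in pixel units.
#' @export
croftonPerimeter <- function(bw) {
  m <- matrix(as.integer(bw != 0), nrow(bw), ncol(bw))
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  nh <- sum(abs(p[, 1:(nc + 1)] - p[, 2:(nc + 2)]))
  nv <- sum(abs(p[1:(nr + 1), ] - p[2:(nr + 2), ]))
  nd1 <- sum(abs(p[1:(nr + 1), 1:(nc + 1)] - p[2:(nr + 2), 2:(nc + 2)]))
  nd2 <- sum(abs(p[2:(nr + 2), 1:(nc + 1)] - p[1:(nr + 1), 2:(nc + 2)]))
  (pi / 8) * (nh + nv + (nd1 + nd2) / sqrt(2))
}

#' Measure nucleus geometry and apply the quality-control filter
#'
#' Computes per-nucleus area, equivalent diameter, Crofton perimeter,
#' circularity (4 * pi * area / perimeter^2, clipped at 1.05 to tolerate
#' rasterization) and centroid, all in physical units, and evaluates the
#' segmentation-error filter: nuclei smaller than \code{minDiameterUm} in
#' equivalent diameter with circularity below \code{circularityMin} fail QC.
#' \code{qcLogic} selects whether both defects are required (\code{"and"},
#' the default, reading the rule verbatim) or either suffices (\code{"or"}).
#'
#' @param mask A \linkS4class{LabeledMask}.
#' @param pixelSizeUm Pixel size in microns (> 0); defaults to the mask's.
#' @param minDiameterUm Diameter cutoff in microns (default 10).
#' @param circularityMin Circularity cutoff (default 0.95).
#' @param qcLogic \code{"and"} or \code{"or"} (see Description).
#' @param dropBorder If \code{TRUE}, nuclei touching the image border also
#'   fail QC (off by default; no border rule is applied otherwise).
#' @return data.frame with one row per label: \code{label, area_um2,
#'   equivalent_diameter_um, perimeter_um, circularity, centroid_x_px,
#'   centroid_y_px, bbox_x0, bbox_y0, bbox_x1, bbox_y1, on_border,
#'   passed_qc}.
#' @export
measureNuclei <- function(mask, pixelSizeUm = pixelSize(mask),
                          minDiameterUm = 10, circularityMin = 0.95,
                          qcLogic = c("and", "or"), dropBorder = FALSE) {
  qcLogic <- match.arg(qcLogic)
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  lab <- maskLabels(mask)
  K <- max(lab, 0L)
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      equivalent_diameter_um = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      centroid_x_px = numeric(), centroid_y_px = numeric(),
                      bbox_x0 = integer(), bbox_y0 = integer(),
                      bbox_x1 = integer(), bbox_y1 = integer(),
                      on_border = logical(), passed_qc = logical())
  if (K == 0L) return(empty)
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  labs <- lab[idx]
  out <- empty[rep(1L, K), ]
  for (k in seq_len(K)) {
    sel <- labs == k
    rk <- rows[sel]; ck <- cols[sel]
    areaPx <- length(rk)
    r0 <- min(rk); r1 <- max(rk); c0 <- min(ck); c1 <- max(ck)
    crop <- lab[r0:r1, c0:c1, drop = FALSE] == k
    perimPx <- croftonPerimeter(crop)
    areaUm2 <- areaPx * pixelSizeUm^2
    perimUm <- perimPx * pixelSizeUm
    circ <- min(4 * pi * areaUm2 / perimUm^2, 1.05)
    eqd <- 2 * sqrt(areaUm2 / pi)
    onBorder <- r0 == 1L || c0 == 1L || r1 == nr || c1 == nc
    small <- eqd < minDiameterUm
    notRound <- circ < circularityMin
    fail <- if (qcLogic == "and") small && notRound else small || notRound
    if (dropBorder && onBorder) fail <- TRUE
    out[k, ] <- list(k, areaUm2, eqd, perimUm, circ,
                     mean(ck) - 1, mean(rk) - 1,
                     c0 - 1L, r0 - 1L, c1 - 1L, r1 - 1L,
                     onBorder, !fail)
  }
  rownames(out) <- NULL
  out
}
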