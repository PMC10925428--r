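# Laplacian-of-Gaussian FISH spot detection with sub-pixel localization,
# and spot-to-nucleus assignment by containing mask pixel.

#' Scale-normalized Laplacian-of-Gaussian kernel
#'
#' Negated, zero-sum, sigma^2-normalized LoG kernel: convolution with it
#' gives a positive response at bright blobs of scale ~ sigma on a dark
#' background.
#'
#' @param sigmaPx Blob scale (Gaussian sd) in pixels; must be positive.
#' @return Odd-sized square kernel matrix.
#' @export
logKernel <- function(sigmaPx) {
  if (sigmaPx <= 0) stop("sigmaPx must be positive")
  half <- max(2L, ceiling(4 * sigmaPx))
  ax <- (-half):half
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigmaPx^2)) / (2 * pi * sigmaPx^2)
  k <- -sigmaPx^2 * ((r2 - 2 * sigmaPx^2) / sigmaPx^4) * g
  k - mean(k)  # zero response to constant background
}

# Otsu threshold of a numeric vector (via EBImage's histogram Otsu)
otsuVector <- function(v, levels = 256L) {
  mx <- max(v)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(matrix(v / mx, ncol = 1)),
                range = c(0, 1), levels = levels) * mx
}

#' Detect FISH spots with a single-scale LoG detector
#'
#' Computes the scale-normalized LoG response of the image, takes local
#' maxima within a \code{minSeparationPx} radius, keeps those above the
#' threshold, and refines each to sub-pixel precision with a separable
#' quadratic fit on the 3x3 response neighbourhood (falling back to the
#' integer position when the fit is not concave or the peak sits on the
#' image border).
#'
#' With \code{threshold = "auto"} the cutoff is the Otsu threshold of the
#' positive response values, floored at 6 robust (MAD) standard deviations
#' of the full response so that pure-noise images yield no detections.
#'
#' @param image A \linkS4class{ChannelImage} (DNA or RNA probe channel).
#' @param sigmaPx LoG scale in pixels, matched to the spot size (> 0).
#' @param threshold Numeric response cutoff, or \code{"auto"}.
#' @param minSeparationPx Minimum separation between reported spots.
#' @return data.frame with columns \code{spot_id, channel, x_px, y_px,
#'   x_um, y_um, peak_intensity, log_response, nucleus_label} (label 0
#'   until \code{\link{assignSpots}} is run).  Coordinates are 0-based.
#' @export
detectSpots <- function(image, sigmaPx = 1.5, threshold = "auto",
                        minSeparationPx = 3) {
  stopifnot(is(image, "ChannelImage"))
  if (sigmaPx <= 0) stop("sigmaPx must be positive")
  px <- image@pixels
  emptySpots <- function() data.frame(
    spot_id = integer(), channel = character(), x_px = numeric(),
    y_px = numeric(), x_um = numeric(), y_um = numeric(),
    peak_intensity = numeric(), log_response = numeric(),
    nucleus_label = integer())
  if (diff(range(px)) < 1e-12) return(emptySpots())

  resp <- EBImage::filter2(px, logKernel(sigmaPx), boundary = "replicate")
  resp <- matrix(as.numeric(resp), nrow(px), ncol(px))

  if (identical(threshold, "auto")) {
    pos <- resp[resp > 0]
    if (!length(pos)) return(emptySpots())
    noiseFloor <- 6 * mad(as.vector(resp), center = 0)
    threshold <- max(otsuVector(pos), noiseFloor)
  }

  # local maxima within the separation radius via grayscale dilation
  radius <- max(1L, ceiling(minSeparationPx))
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(resp, brush))
  cand <- which(resp >= dil & resp > threshold)
  if (!length(cand)) return(emptySpots())
  nr <- nrow(resp)
  ry <- ((cand - 1L) %% nr) + 1L
  rx <- ((cand - 1L) %/% nr) + 1L
  rv <- resp[cand]

  # deterministic dedup of plateau ties closer than the separation
  o <- order(-rv, ry, rx)
  ry <- ry[o]; rx <- rx[o]; rv <- rv[o]
  keep <- rep(TRUE, length(rv))
  for (i in seq_along(rv)) {
    if (!keep[i]) next
    if (i < length(rv)) {
      j <- (i + 1L):length(rv)
      tooClose <- keep[j] &
        (ry[j] - ry[i])^2 + (rx[j] - rx[i])^2 < minSeparationPx^2
      keep[j[tooClose]] <- FALSE
    }
  }
  ry <- ry[keep]; rx <- rx[keep]; rv <- rv[keep]

  # separable 3x3 quadratic sub-pixel refinement
  subOffset <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    if (den >= 0) return(0)  # non-concave: keep integer position
    off <- 0.5 * (fm - fp) / den
    if (abs(off) > 0.6) 0 else off
  }
  n <- length(rv)
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    r <- ry[i]; c <- rx[i]
    dy <- dx <- 0
    if (r > 1L && r < nrow(resp))
      dy <- subOffset(resp[r - 1L, c], resp[r, c], resp[r + 1L, c])
    if (c > 1L && c < ncol(resp))
      dx <- subOffset(resp[r, c - 1L], resp[r, c], resp[r, c + 1L])
    xs[i] <- (c - 1L) + dx
    ys[i] <- (r - 1L) + dy
  }
  data.frame(spot_id = seq_len(n), channel = image@channel,
             x_px = xs, y_px = ys,
             x_um = xs * image@pixelSizeUm, y_um = ys * image@pixelSizeUm,
             peak_intensity = px[cbind(ry, rx)], log_response = rv,
             nucleus_label = 0L)
}

#' Assign detected spots to nuclei
#'
#' Each spot receives the label of the mask pixel containing its rounded
#' center; spots over background get label 0 and are excluded from all
#' downstream allele analysis (spots not overlapping any nucleus are
#' filtered out).
#'
#' @param spots Spot data.frame from \code{\link{detectSpots}}.
#' @param mask A \linkS4class{LabeledMask} sharing the image coordinate
#'   frame.
#' @return The spot data.frame with \code{nucleus_label} filled in.
#' @export
assignSpots <- function(spots, mask) {
  lab <- maskLabels(mask)
  if (nrow(spots) == 0L) return(spots)
  r <- round(spots$y_px) + 1L
  c <- round(spots$x_px) + 1L
  if (any(r < 1L | r > nrow(lab) | c < 1L | c > ncol(lab)))
    stop("spot coordinate outside mask extent")
  spots$nucleus_label <- lab[cbind(r, c)]
  spots
}
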