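# Cross-correlation registration of sequential acquisition rounds on the
# DAPI channel.  The correlation surface over integer displacements
# (dx, dy) in [-maxShift, maxShift]^2 is
#
#     C(dx, dy) = sum_{x,y} A(x, y) * B(x - dx, y - dy)
#
# summed over the overlap region, so that the peak displacement is exactly
# the translation to apply to the moving image B:
# B_registered(x, y) = B(x - dx_peak, y - dy_peak) aligns with A.
# The FFT path (zero-padded linear correlation) is required to match this
# direct spatial-domain sum at every displacement.

#' Cross-correlation surface between two images
#'
#' @param a,b Numeric matrices of identical shape (reference, moving).
#' @param maxShift Non-negative half-width of the displacement window.
#' @param method \code{"fft"} (zero-padded FFT correlation) or
#'   \code{"direct"} (literal spatial-domain double sum; the oracle both
#'   paths must agree with).
#' @param correlation \code{"zero_mean"} (default; each image has its mean
#'   subtracted first, removing the bias of the raw sum toward
#'   maximal-overlap displacements for non-negative images) or \code{"raw"}
#'   (the verbatim product sum).
#' @return (2*maxShift+1)^2 matrix of correlation values; rows index dy,
#'   columns dx, both running from -maxShift to +maxShift (see dimnames).
#' @export
correlationSurface <- function(a, b, maxShift,
                               method = c("fft", "direct"),
                               correlation = c("zero_mean", "raw")) {
  method <- match.arg(method)
  correlation <- match.arg(correlation)
  if (!identical(dim(a), dim(b))) stop("image shape mismatch")
  if (maxShift < 0) stop("maxShift must be non-negative")
  if (correlation == "zero_mean") {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  m <- as.integer(maxShift)
  lags <- (-m):m
  nr <- nrow(a); nc <- ncol(a)
  if (method == "direct") {
    surf <- matrix(0, 2L * m + 1L, 2L * m + 1L)
    for (iy in seq_along(lags)) {
      dy <- lags[iy]
      ra <- max(1L, 1L + dy):min(nr, nr + dy)   # rows of A in overlap
      for (ix in seq_along(lags)) {
        dx <- lags[ix]
        ca <- max(1L, 1L + dx):min(nc, nc + dx)
        surf[iy, ix] <- sum(a[ra, ca, drop = FALSE] *
                            b[ra - dy, ca - dx, drop = FALSE])
      }
    }
  } else {
    p1 <- stats::nextn(nr + m, c(2, 3, 5))
    p2 <- stats::nextn(nc + m, c(2, 3, 5))
    pa <- matrix(0, p1, p2); pa[1:nr, 1:nc] <- a
    pb <- matrix(0, p1, p2); pb[1:nr, 1:nc] <- b
    cc <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)),
                        inverse = TRUE)) / (p1 * p2)
    ri <- ifelse(lags >= 0, lags + 1L, p1 + lags + 1L)
    ci <- ifelse(lags >= 0, lags + 1L, p2 + lags + 1L)
    surf <- cc[ri, ci, drop = FALSE]
  }
  dimnames(surf) <- list(dy = lags, dx = lags)
  surf
}

#' Estimate the translation between two DAPI images
#'
#' Finds the displacement maximizing the cross-correlation of the reference
#' and moving images within \code{[-maxShift, maxShift]^2}.  The returned
#' vector is the integer translation to apply to the moving image (see
#' \code{\link{applyShift}}) to align it with the reference.  Exact peak
#' ties are broken deterministically: smallest |dx| + |dy|, then smallest
#' dy, then smallest dx.
#'
#' @param reference,moving \linkS4class{ChannelImage}s (or matrices) of the
#'   same shape; the reference frame is left untouched downstream.
#' @param maxShift Search half-width in pixels (default 50).
#' @param correlation \code{"zero_mean"} (default) or \code{"raw"}; see
#'   \code{\link{correlationSurface}}.
#' @return A \linkS4class{TranslationVector}.
#' @export
estimateShift <- function(reference, moving, maxShift = 50L,
                          correlation = c("zero_mean", "raw")) {
  correlation <- match.arg(correlation)
  a <- if (is(reference, "ChannelImage")) reference@pixels else reference
  b <- if (is(moving, "ChannelImage")) moving@pixels else moving
  if (!identical(dim(a), dim(b))) stop("image shape mismatch")
  if (sd(a) == 0) stop("degenerate reference (constant image)")
  if (sd(b) == 0) stop("degenerate moving image (constant image)")
  surf <- correlationSurface(a, b, maxShift, method = "fft",
                             correlation = correlation)
  m <- as.integer(maxShift)
  peak <- max(surf)
  idx <- which(surf >= peak - abs(peak) * 1e-15, arr.ind = TRUE)
  dys <- idx[, 1] - m - 1L
  dxs <- idx[, 2] - m - 1L
  o <- order(abs(dxs) + abs(dys), dys, dxs)[1]
  dy <- dys[o]; dx <- dxs[o]
  # margin: peak minus best value outside the peak's 8-neighbourhood
  margin <- NA_real_
  if (length(surf) > 9) {
    allDy <- as.integer(rownames(surf))[row(surf)]
    allDx <- as.integer(colnames(surf))[col(surf)]
    far <- abs(allDy - dy) > 1 | abs(allDx - dx) > 1
    if (any(far)) margin <- peak - max(surf[far])
  }
  TranslationVector(dx, dy, peakValue = peak, correlationMargin = margin,
                    maxShift = m)
}

#' Apply an integer translation to an image
#'
#' Pixel-exact translation by the vector's (dx, dy): the output at (x, y)
#' is the input at (x - dx, y - dy); vacated boundary pixels are set to
#' zero.  Shape and metadata are preserved and the applied shift is
#' recorded on the image.
#'
#' @param moving A \linkS4class{ChannelImage}.
#' @param shift A \linkS4class{TranslationVector} (or integer pair).
#' @return The translated \linkS4class{ChannelImage}.
#' @export
applyShift <- function(moving, shift) {
  stopifnot(is(moving, "ChannelImage"))
  v <- if (is(shift, "TranslationVector")) shiftVector(shift) else
    as.integer(shift)
  if (any(abs(v) >= dim(moving@pixels)[c(2, 1)]))
    stop("shift exceeds image bounds")
  out <- moving
  out@pixels <- shiftMatrix(moving@pixels, v[1], v[2])
  out@registeredShift <- as.integer(v)
  out
}

#' Register a sequential-acquisition round pair
#'
#' Estimates the inter-round translation on the two DAPI images only, then
#' applies the same vector to every image of the moving (RNA) round; the
#' reference (DNA) round is left untouched as the common frame.
#'
#' @param rnaRound,dnaRound Lists of \linkS4class{ChannelImage} for the same
#'   (plate, well, field); each must contain a DAPI image.
#' @param maxShift Search half-width in pixels.
#' @param correlation Correlation variant; see \code{\link{estimateShift}}.
#' @return List with \code{rnaRound} (registered), \code{dnaRound}
#'   (untouched) and \code{shift} (the \linkS4class{TranslationVector}).
#' @export
registerRoundPair <- function(rnaRound, dnaRound, maxShift = 50L,
                              correlation = "zero_mean") {
  findDapi <- function(imgs, what) {
    i <- which(vapply(imgs, function(x) x@channel, "") == "DAPI")
    if (!length(i)) stop("missing DAPI image in ", what, " round")
    imgs[[i[1]]]
  }
  refDapi <- findDapi(dnaRound, "dna")
  movDapi <- findDapi(rnaRound, "rna")
  tv <- estimateShift(refDapi, movDapi, maxShift = maxShift,
                      correlation = correlation)
  list(rnaRound = lapply(rnaRound, applyShift, shift = tv),
       dnaRound = dnaRound, shift = tv)
}
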