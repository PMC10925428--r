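# Normalized radial nuclear position via the per-nucleus distance
# transform, shell binning, and two-sample comparison of radial
# distributions.

#' Normalized radial position map of one nucleus
#'
#' The Euclidean distance transform of the nucleus (distance of each
#' nucleus pixel to the nearest background pixel) is normalized by its
#' per-nucleus maximum and subtracted from 1: the deepest interior point
#' maps to 0 and the periphery to 1 (up to discretization).  Pixels outside
#' the nucleus are \code{NA} and must never be read.
#'
#' @param mask A \linkS4class{LabeledMask}.
#' @param label Nucleus label present in the mask.
#' @param metric Distance metric, \code{"euclidean"} (default) or
#'   \code{"manhattan"}.
#' @return Numeric matrix of the mask's shape with values in [0, 1] on the
#'   nucleus pixels and \code{NA} elsewhere.
#' @export
radialMap <- function(mask, label, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  lab <- maskLabels(mask)
  sel <- lab == label
  if (!any(sel)) stop("label ", label, " absent from mask")
  idx <- which(sel, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 1L); r1 <- min(nrow(lab), max(idx[, 1]) + 1L)
  c0 <- max(1L, min(idx[, 2]) - 1L); c1 <- min(ncol(lab), max(idx[, 2]) + 1L)
  crop <- sel[r0:r1, c0:c1, drop = FALSE]
  if (sum(crop) < 2L)
    stop("degenerate nucleus (label ", label,
         "): single-pixel mask has no radial structure")
  dt <- EBImage::distmap(crop, metric = metric)
  dt <- matrix(as.numeric(dt), nrow(crop), ncol(crop))
  mx <- max(dt)
  if (mx == 0) stop("degenerate nucleus (label ", label,
                    "): single-pixel distance transform")
  val <- 1 - dt / mx
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  out[r0:r1, c0:c1][crop] <- val[crop]
  out
}

#' Annotate alleles with radial position and shell
#'
#' Looks up each allele's DNA-spot radial value at its containing pixel in
#' the per-nucleus \code{\link{radialMap}}, and bins it into five shells of
#' width \code{shellWidth}: shell = 1 + floor(radial / width), with the
#' final bin right-closed so radial 1.0 falls in shell 5.
#'
#' @param alleles Allele data.frame from \code{\link{classifyAlleles}}
#'   (needs \code{x_px, y_px, nucleus_label}).
#' @param mask The \linkS4class{LabeledMask} the spots were assigned to.
#' @param shellWidth Shell width on the normalized radius (default 0.2).
#' @param metric Distance metric passed to \code{\link{radialMap}}.
#' @return \code{alleles} with columns \code{radial} and \code{shell} added.
#' @export
annotateRadial <- function(alleles, mask, shellWidth = 0.2,
                           metric = "euclidean") {
  if (nrow(alleles) == 0L) {
    alleles$radial <- numeric(0); alleles$shell <- integer(0)
    return(alleles)
  }
  radial <- numeric(nrow(alleles))
  for (labv in unique(alleles$nucleus_label)) {
    rm_ <- radialMap(mask, labv, metric = metric)
    sel <- which(alleles$nucleus_label == labv)
    r <- round(alleles$y_px[sel]) + 1L
    c <- round(alleles$x_px[sel]) + 1L
    v <- rm_[cbind(r, c)]
    if (anyNA(v))
      stop("spot pixel outside its nucleus (label ", labv, ")")
    radial[sel] <- v
  }
  alleles$radial <- radial
  alleles$shell <- radialShell(radial, shellWidth)
  alleles
}

#' Bin normalized radial positions into shells
#'
#' Shells are left-closed intervals of width \code{shellWidth} on [0, 1],
#' with the last shell right-closed: with the default width 0.2 the shells
#' are 1:[0,0.2), ..., 5:[0.8,1.0], so radial 1.0 maps to shell 5.
#'
#' @param radial Numeric vector of normalized radial positions in [0, 1].
#' @param shellWidth Shell width (default 0.2).
#' @return Integer shell indices.
#' @export
radialShell <- function(radial, shellWidth = 0.2) {
  if (any(radial < 0 | radial > 1, na.rm = TRUE))
    stop("radial values must lie in [0, 1]")
  nShell <- ceiling(1 / shellWidth)
  as.integer(pmin(floor(radial / shellWidth), nShell - 1L) + 1L)
}

#' Compare two radial-position distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test between two groups of
#' normalized radial positions (e.g. active vs inactive alleles), with the
#' per-group mean and sd summary.
#'
#' @param groupA,groupB Non-empty numeric vectors of radial values.
#' @param nameA,nameB Group names used in the returned table.
#' @return data.frame with one row per group (\code{n}, \code{mean},
#'   \code{sd}) and attributes-free columns \code{ks_statistic} and
#'   \code{p_value} repeated on both rows.
#' @export
compareRadial <- function(groupA, groupB, nameA = "A", nameB = "B") {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  kt <- suppressWarnings(ks.test(groupA, groupB,
                                 alternative = "two.sided", exact = FALSE))
  data.frame(group = c(nameA, nameB),
             n = c(length(groupA), length(groupB)),
             mean = c(mean(groupA), mean(groupB)),
             sd = c(sd(groupA), sd(groupB)),
             ks_statistic = unname(kt$statistic),
             p_value = kt$p.value)
}
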