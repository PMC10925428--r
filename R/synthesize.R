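# Synthetic FISH scene generator: seeded, ground-truthed stand-in for
# plate images.  Coordinates are 0-based (x = column, y = row); matrices
# are indexed [y + 1, x + 1].

# translate matrix content by (dx, dy) with zero fill
shiftMatrix <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  storage.mode(out) <- storage.mode(m)
  srcRows <- seq_len(nr) - dy
  srcCols <- seq_len(nc) - dx
  okR <- srcRows >= 1L & srcRows <= nr
  okC <- srcCols >= 1L & srcCols <= nc
  if (any(okR) && any(okC))
    out[which(okR), which(okC)] <- m[srcRows[okR], srcCols[okC]]
  out
}

# additive 2D isotropic Gaussian peak at 0-based (x0, y0)
addGaussianSpot <- function(m, x0, y0, amp, sigma) {
  halfw <- ceiling(4 * sigma)
  rows <- max(1L, floor(y0 + 1 - halfw)):min(nrow(m), ceiling(y0 + 1 + halfw))
  cols <- max(1L, floor(x0 + 1 - halfw)):min(ncol(m), ceiling(x0 + 1 + halfw))
  if (!length(rows) || !length(cols)) return(m)
  gy <- exp(-((rows - 1 - y0)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x0)^2) / (2 * sigma^2))
  m[rows, cols] <- m[rows, cols] + amp * outer(gy, gx)
  m
}

# scaled elliptical radius of pixel grid points around a nucleus;
# returns list(rows, cols, d) restricted to the bounding box
ellipseRadiusGrid <- function(dims, cx, cy, rx, ry, theta, pad = 3) {
  ext <- max(rx, ry) + pad
  rows <- max(1L, floor(cy + 1 - ext)):min(dims[1], ceiling(cy + 1 + ext))
  cols <- max(1L, floor(cx + 1 - ext)):min(dims[2], ceiling(cx + 1 + ext))
  dxm <- outer(rep(1, length(rows)), cols - 1 - cx)
  dym <- outer(rows - 1 - cy, rep(1, length(cols)))
  u <- dxm * cos(theta) + dym * sin(theta)
  v <- -dxm * sin(theta) + dym * cos(theta)
  list(rows = rows, cols = cols, d = sqrt((u / rx)^2 + (v / ry)^2))
}

# draw a normalized radius from a placement law list(power, rhoMax)
samplePlacementRadius <- function(n, law) {
  law$rhoMax * runif(n)^(1 / law$power)
}

#' Render a synthetic FISH scene
#'
#' Generates one synthetic field: DAPI nuclei as smooth bright ellipses on a
#' dark background, two DNA-probe spots per nucleus placed at a drawn
#' normalized radius, and 0/1/2 RNA-probe spots offset sub-micron from DNA
#' spots according to the nucleus expression state (silent / monoallelic /
#' biallelic), plus Gaussian read noise.  In sequential mode the DNA-probe
#' acquisition round (DAPI + DNA) is rigidly translated by
#' \code{interRoundShiftPx} with zero fill, emulating the stage offset
#' between two imaging sessions; noise is drawn independently per round so
#' the two DAPI images share structure but not pixels.
#'
#' Rendering is deterministic for a fixed spec (including its seed): the
#' ground truth (nucleus and spot placement) is drawn first from
#' \code{seed}, and per-round noise from seeds derived from it, so the same
#' spec renders the identical truth in both modes.
#'
#' @param spec A \linkS4class{SceneSpec}.
#' @param mode \code{"simultaneous"} (one acquisition: DAPI + DNA + RNA in a
#'   shared frame) or \code{"sequential"} (rna_round: DAPI + RNA at
#'   identity; dna_round: DAPI + DNA shifted).
#' @param plate,well,field Metadata stamped on the images.
#' @return List with \code{images} (named list of \linkS4class{ChannelImage};
#'   names \code{DAPI, DNA, RNA} in simultaneous mode, or
#'   \code{rna_DAPI, rna_RNA, dna_DAPI, dna_DNA} in sequential mode) and
#'   \code{truth} (a \linkS4class{SceneTruth}).
#' @examples
#' sc <- renderScene(SceneSpec(nNuclei = 2, seed = 7))
#' sc$truth
#' @export
renderScene <- function(spec, mode = c("simultaneous", "sequential"),
                        plate = "plate01", well = "A01", field = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  dims <- spec@imageSizePx
  pxum <- spec@pixelSizeUm

  set.seed(spec@seed)
  truth <- sampleSceneTruth(spec)
  nuc <- truth$nuclei; spots <- truth$spots

  # noiseless composites
  dapi <- matrix(0, dims[1], dims[2])
  if (nrow(nuc)) {
    edge <- 1.2  # sigmoid edge softness, px
    for (i in seq_len(nrow(nuc))) {
      g <- ellipseRadiusGrid(dims, nuc$cx_px[i], nuc$cy_px[i],
                             nuc$rx_px[i], nuc$ry_px[i], nuc$theta[i])
      rbar <- sqrt(nuc$rx_px[i] * nuc$ry_px[i])
      dapi[g$rows, g$cols] <- dapi[g$rows, g$cols] +
        spec@nucleusIntensity * stats::plogis((1 - g$d) * rbar / edge)
    }
  }
  clean <- list(DAPI = dapi,
                DNA = matrix(0, dims[1], dims[2]),
                RNA = matrix(0, dims[1], dims[2]))
  if (nrow(spots)) {
    for (i in seq_len(nrow(spots))) {
      ch <- spots$channel[i]
      clean[[ch]] <- addGaussianSpot(clean[[ch]], spots$x_px[i], spots$y_px[i],
                                     spots$amp[i], spec@spotSigmaPx)
    }
  }

  maxval <- 2^spec@bitDepth - 1
  finish <- function(m, noiseSeed) {
    set.seed(as.integer(noiseSeed))
    m <- m + spec@backgroundLevel +
      rnorm(length(m), sd = spec@noiseSigma)
    matrix(pmin(pmax(round(m), 0), maxval), nrow(m), ncol(m))
  }
  mk <- function(px, channel, round) {
    ChannelImage(px, plate = plate, well = well, field = field,
                 channel = channel, round = round, pixelSizeUm = pxum,
                 bitDepth = spec@bitDepth)
  }
  s0 <- (abs(as.numeric(spec@seed)) * 1009) %% 2147483600

  if (mode == "simultaneous") {
    images <- list(
      DAPI = mk(finish(clean$DAPI, s0 + 1L), "DAPI", "single"),
      DNA  = mk(finish(clean$DNA,  s0 + 2L), "DNA",  "single"),
      RNA  = mk(finish(clean$RNA,  s0 + 3L), "RNA",  "single"))
    shift <- c(0L, 0L)
  } else {
    sh <- spec@interRoundShiftPx
    images <- list(
      rna_DAPI = mk(finish(clean$DAPI, s0 + 4L), "DAPI", "rna_round"),
      rna_RNA  = mk(finish(clean$RNA,  s0 + 5L), "RNA",  "rna_round"),
      dna_DAPI = mk(finish(shiftMatrix(clean$DAPI, sh[1], sh[2]), s0 + 6L),
                    "DAPI", "dna_round"),
      dna_DNA  = mk(finish(shiftMatrix(clean$DNA, sh[1], sh[2]), s0 + 7L),
                    "DNA", "dna_round"))
    shift <- sh
  }
  spots$amp <- NULL
  list(images = images,
       truth = new("SceneTruth", nuclei = nuc, spots = spots,
                   shift = shift, mode = mode))
}

# draw nucleus placements, expression states and spot truths (consumes RNG)
sampleSceneTruth <- function(spec) {
  dims <- spec@imageSizePx
  pxum <- spec@pixelSizeUm
  n <- spec@nNuclei
  emptyNuc <- data.frame(nucleus = integer(), cx_px = numeric(),
                         cy_px = numeric(), rx_px = numeric(),
                         ry_px = numeric(), theta = numeric(),
                         state = character())
  emptySpot <- data.frame(nucleus = integer(), channel = character(),
                          x_px = numeric(), y_px = numeric(),
                          radial_true = numeric(), amp = numeric())
  if (n == 0L) return(list(nuclei = emptyNuc, spots = emptySpot))

  ecc <- spec@nucleusEccentricity
  axisStretch <- (1 - ecc^2)^(-0.25)  # rx = r * stretch, ry = r / stretch
  rUm <- pmax(pmin(rnorm(n, spec@nucleusRadiusUm[1], spec@nucleusRadiusUm[2]),
                   spec@nucleusRadiusUm[1] + 3 * spec@nucleusRadiusUm[2]),
              spec@nucleusRadiusUm[1] - 3 * spec@nucleusRadiusUm[2])
  rPx <- rUm / pxum
  rx <- rPx * axisStretch
  ry <- rPx / axisStretch
  theta <- runif(n, 0, pi)

  cx <- cy <- numeric(n)
  maxAttempts <- 200L * n
  attempts <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    margin <- rx[i] + 3
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("could not place ", n, " nuclei without overlap; ",
             "scene specification is over-dense")
      px <- runif(1, margin, dims[2] - 1 - margin)
      py <- runif(1, margin, dims[1] - 1 - margin)
      if (i == 1L ||
          all(sqrt((px - cx[seq_len(i - 1)])^2 + (py - cy[seq_len(i - 1)])^2) >
              rx[i] + rx[seq_len(i - 1)] + 4)) {
        cx[i] <- px; cy[i] <- py; placed <- TRUE
      }
    }
  }
  state <- sample(c("silent", "mono", "bi"), n, replace = TRUE,
                  prob = spec@expressionProbs)
  nuclei <- data.frame(nucleus = seq_len(n), cx_px = cx, cy_px = cy,
                       rx_px = rx, ry_px = ry, theta = theta, state = state)

  # spot truths: 2 DNA spots per nucleus at drawn normalized radius;
  # RNA spots offset from 1 (mono) or 2 (bi) DNA spots
  spotRows <- list()
  sigOffPx <- spec@rnaOffsetSigmaUm / pxum
  for (i in seq_len(n)) {
    law <- spec@radialPlacement[[state[i]]]
    sepPx <- spec@minDnaSeparationUm / pxum
    placeSpot <- function() {
      rho1 <- samplePlacementRadius(1, law)
      phi1 <- runif(1, 0, 2 * pi)
      ux1 <- rho1 * rx[i] * cos(phi1)
      uy1 <- rho1 * ry[i] * sin(phi1)
      c(cx[i] + ux1 * cos(theta[i]) - uy1 * sin(theta[i]),
        cy[i] + ux1 * sin(theta[i]) + uy1 * cos(theta[i]), rho1)
    }
    p1 <- placeSpot()
    p2 <- placeSpot()
    for (a in seq_len(100)) {  # homologous alleles sit in distinct territories
      if (sqrt(sum((p2[1:2] - p1[1:2])^2)) >= sepPx) break
      p2 <- placeSpot()
    }
    sx <- c(p1[1], p2[1]); sy <- c(p1[2], p2[2]); rho <- c(p1[3], p2[3])
    dna <- data.frame(nucleus = i, channel = "DNA", x_px = sx, y_px = sy,
                      radial_true = rho)
    nRna <- switch(state[i], silent = 0L, mono = 1L, bi = 2L)
    rna <- NULL
    if (nRna > 0L) {
      which_dna <- if (nRna == 1L) sample.int(2L, 1L) else 1:2
      rxp <- sx[which_dna] + rnorm(nRna, sd = sigOffPx)
      ryp <- sy[which_dna] + rnorm(nRna, sd = sigOffPx)
      rna <- data.frame(nucleus = i, channel = "RNA", x_px = rxp, y_px = ryp,
                        radial_true = scaledEllipseRadius(
                          rxp, ryp, cx[i], cy[i], rx[i], ry[i], theta[i]))
    }
    decoy <- NULL
    nDecoy <- if (spec@decoyRnaRate > 0) rpois(1, spec@decoyRnaRate) else 0L
    if (nDecoy > 0L) {
      dminPx <- 1.5 / pxum
      dxs <- dys <- numeric(0)
      for (k in seq_len(nDecoy)) {
        for (a in 1:50) {
          rhoD <- samplePlacementRadius(1, list(power = 1, rhoMax = 0.9))
          phiD <- runif(1, 0, 2 * pi)
          uxD <- rhoD * rx[i] * cos(phiD); uyD <- rhoD * ry[i] * sin(phiD)
          pxD <- cx[i] + uxD * cos(theta[i]) - uyD * sin(theta[i])
          pyD <- cy[i] + uxD * sin(theta[i]) + uyD * cos(theta[i])
          if (all(sqrt((pxD - sx)^2 + (pyD - sy)^2) >= dminPx)) {
            dxs <- c(dxs, pxD); dys <- c(dys, pyD); break
          }
        }
      }
      if (length(dxs))
        decoy <- data.frame(nucleus = i, channel = "RNA", x_px = dxs,
                            y_px = dys,
                            radial_true = scaledEllipseRadius(
                              dxs, dys, cx[i], cy[i], rx[i], ry[i], theta[i]))
    }
    spotRows[[i]] <- rbind(dna, rna, decoy)
  }
  spots <- do.call(rbind, spotRows)
  rownames(spots) <- NULL
  amps <- numeric(nrow(spots))
  for (ch in c("DNA", "RNA")) {
    idx <- spots$channel == ch
    si <- spec@spotIntensity[[ch]]
    amps[idx] <- pmax(rnorm(sum(idx), si[1], si[2]), si[1] / 4)
  }
  spots$amp <- amps
  list(nuclei = nuclei, spots = spots)
}

# normalized (scaled) elliptical radius of points w.r.t. a nucleus ellipse
scaledEllipseRadius <- function(x, y, cx, cy, rx, ry, theta) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sqrt((u / rx)^2 + (v / ry)^2)
}

#' Write a collection of images as a TIFF plate with a manifest
#'
#' Each image is written as a single-plane 16-bit TIFF named
#' \code{<plate>_<well>_f<field>_<round>_<channel>.tif}; a \code{manifest.csv}
#' lists every file with its metadata and pixel size.  The written plate
#' round-trips losslessly through \code{\link{loadManifest}} /
#' \code{\link{readPlateImages}}.
#'
#' @param images List of \linkS4class{ChannelImage}.
#' @param directory Output directory (created if absent).
#' @param force Overwrite an existing manifest (default \code{FALSE}).
#' @return The manifest data.frame, invisibly.
#' @export
writePlate <- function(images, directory, force = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  manifestPath <- file.path(directory, "manifest.csv")
  if (file.exists(manifestPath) && !force)
    stop("manifest already exists at ", manifestPath, "; use force = TRUE")
  rows <- lapply(images, function(im) {
    stopifnot(is(im, "ChannelImage"))
    data.frame(path = sprintf("%s_%s_f%d_%s_%s.tif", im@plate, im@well,
                              im@field, im@round, im@channel),
               plate = im@plate, well = im@well, field = im@field,
               round = im@round, channel = im@channel,
               pixel_size_um = im@pixelSizeUm)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), plate = character(), well = character(),
               field = integer(), round = character(), channel = character(),
               pixel_size_um = numeric())
  rownames(manifest) <- NULL
  key <- with(manifest, paste(plate, well, field, round, channel))
  if (anyDuplicated(key))
    stop("duplicate (plate, well, field, round, channel) keys in image set")
  for (i in seq_along(images))
    writeChannelTiff(images[[i]], file.path(directory, manifest$path[i]))
  write.csv(manifest, manifestPath, row.names = FALSE)
  invisible(manifest)
}

# single-plane 16-bit little-endian TIFF; pixels must be integer-valued
writeChannelTiff <- function(image, path) {
  maxval <- 2^image@bitDepth - 1
  tiff::writeTIFF(image@pixels / maxval, path,
                  bits.per.sample = image@bitDepth, compression = "none")
  invisible(path)
}
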