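# Shared fixtures: rasterized shapes, constructed images, and batches of
# rendered synthetic fields.

# binary disc mask (matrix) of radius r centred in a (2r+2*pad) square
discMask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad  # 0-based centre
  xs <- 0:(n - 1L)
  d2 <- outer((xs - ctr)^2, (xs - ctr)^2, "+")
  matrix(d2 <= r^2, n, n)
}

# LabeledMask with a single disc nucleus, label 1
discLabeledMask <- function(r, pad = 4L, pixelSizeUm = 0.108) {
  LabeledMask(matrix(as.integer(discMask(r, pad)), nrow = 2L * (r + pad) + 1L),
              pixelSizeUm = pixelSizeUm)
}

# ChannelImage with Gaussian peaks at 0-based (x, y) on constant background
peaksImage <- function(xy, amp = 1000, sigma = 1.5, size = 128L,
                       background = 300, noiseSd = 0, channel = "DNA",
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(background, size, size)
  if (length(xy)) {
    xy <- matrix(xy, ncol = 2L)
    for (i in seq_len(nrow(xy)))
      m <- HTFISH:::addGaussianSpot(m, xy[i, 1], xy[i, 2], amp, sigma)
  }
  if (noiseSd > 0) m <- m + rnorm(length(m), sd = noiseSd)
  ChannelImage(pmin(pmax(round(m), 0), 65535), channel = channel)
}

# render a batch of fields (list of image lists) plus pooled truth tables
renderFieldBatch <- function(nFields, baseSeed, mode = "simultaneous", ...) {
  wells <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), rep(1:24, 16))
  fields <- vector("list", nFields)
  truths <- vector("list", nFields)
  for (i in seq_len(nFields)) {
    sc <- renderScene(SceneSpec(seed = baseSeed + i, ...), mode = mode,
                      well = wells[(i - 1L) %% 384L + 1L],
                      field = (i - 1L) %/% 384L + 1L)
    fields[[i]] <- sc$images
    truths[[i]] <- sc$truth
  }
  list(fields = fields, truths = truths)
}

# greedy nearest matching of detected spots to truth positions (px)
matchSpots <- function(det, truthXY, tolPx = 2.5) {
  if (nrow(det) == 0L || nrow(truthXY) == 0L)
    return(list(tp = 0L, fp = nrow(det), fn = nrow(truthXY)))
  used <- rep(FALSE, nrow(truthXY))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    d <- sqrt((truthXY$x_px - det$x_px[i])^2 +
              (truthXY$y_px - det$y_px[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tolPx) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truthXY) - tp)
}
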