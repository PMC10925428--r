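test_that("identical images correlate best at zero displacement", {
  set.seed(1)
  a <- matrix(runif(64 * 64), 64)
  tv <- estimateShift(a, a, maxShift = 8)
  expect_identical(shiftVector(tv), c(dx = 0L, dy = 0L))
})

test_that("FFT and direct-sum correlation surfaces agree at every displacement", {
  set.seed(2)
  a <- matrix(runif(64 * 64), 64)
  b <- HTFISH:::shiftMatrix(a, 5, -3)
  for (corr in c("zero_mean", "raw")) {
    sf <- correlationSurface(a, b, maxShift = 8, method = "fft",
                             correlation = corr)
    sd_ <- correlationSurface(a, b, maxShift = 8, method = "direct",
                              correlation = corr)
    expect_lt(max(abs(sf - sd_)) / max(abs(sd_)), 1e-6)
    expect_equal(which.max(sf), which.max(sd_))
  }
})

test_that("estimate and apply are mutually consistent inverses", {
  set.seed(3)
  ref <- ChannelImage(matrix(as.integer(runif(96 * 96, 0, 5000)), 96))
  for (sh in list(c(5L, -3L), c(-7L, 2L), c(0L, 11L))) {
    moving <- applyShift(ref, sh)
    tv <- estimateShift(ref, moving, maxShift = 15)
    # the estimated vector, applied to the moving image, restores alignment
    back <- applyShift(moving, tv)
    rows <- (1 + abs(sh[2])):(96 - abs(sh[2]))
    cols <- (1 + abs(sh[1])):(96 - abs(sh[1]))
    expect_identical(pixels(back)[rows, cols], pixels(ref)[rows, cols])
    expect_identical(unname(shiftVector(tv)), -sh)
  }
})

test_that("applying a shift then its negation zeroes only the border bands", {
  set.seed(4)
  img <- ChannelImage(matrix(as.integer(runif(80 * 80, 1, 5000)), 80))
  fwd <- applyShift(img, c(5L, -3L))
  back <- applyShift(fwd, c(-5L, 3L))
  px <- pixels(back)
  expect_identical(px[4:80, 1:75], pixels(img)[4:80, 1:75])
  expect_true(all(px[, 76:80] == 0))   # vacated x band
  expect_true(all(px[1:3, ] == 0))     # vacated y band
})

test_that("translation moves pixels without scaling them", {
  img <- ChannelImage(matrix(0, 32, 32))
  px <- pixels(img); px[11, 11] <- 999   # 0-based (10, 10)
  img@pixels <- px
  out <- pixels(applyShift(img, c(2L, 1L)))
  expect_equal(out[12, 13], 999)          # 0-based (12, 11)
  expect_equal(sum(out > 0), 1L)
  # multiset of non-vacated values is conserved
  set.seed(9)
  rimg <- ChannelImage(matrix(as.integer(runif(64 * 64, 0, 100)), 64))
  shifted <- pixels(applyShift(rimg, c(6L, -4L)))
  expect_identical(sort(as.vector(shifted[1:60, 7:64])),
                   sort(as.vector(pixels(rimg)[5:64, 1:58])))
})

test_that("degenerate inputs are rejected", {
  flat <- matrix(1, 32, 32)
  set.seed(5); ok <- matrix(runif(32 * 32), 32)
  expect_error(estimateShift(flat, ok, 4), "degenerate reference")
  expect_error(estimateShift(ok, flat, 4), "degenerate moving")
  expect_error(estimateShift(ok, matrix(runif(16^2), 16), 4), "mismatch")
  expect_error(applyShift(ChannelImage(ok * 100), c(40L, 0L)), "bounds")
})

test_that("round-pair registration recovers the simulated inter-round shift", {
  spec <- SceneSpec(nNuclei = 5, interRoundShiftPx = c(7L, -4L),
                    expressionProbs = c(0, 0.5, 0.5), seed = 17)
  sc <- renderScene(spec, mode = "sequential")
  reg <- registerRoundPair(sc$images[c("rna_DAPI", "rna_RNA")],
                           sc$images[c("dna_DAPI", "dna_DNA")],
                           maxShift = 20)
  expect_identical(shiftVector(reg$shift), c(dx = 7L, dy = -4L))
  # registered RNA truth positions now live in the DNA-round frame
  tr <- sceneSpots(sc$truth)
  rna <- tr[tr$channel == "RNA", ]
  det <- detectSpots(reg$rnaRound$rna_RNA)
  m <- matchSpots(det, data.frame(x_px = rna$x_px + 7, y_px = rna$y_px - 4),
                  tolPx = 1)
  expect_equal(m$fn, 0L)
  expect_error(registerRoundPair(sc$images["rna_RNA"],
                                 sc$images[c("dna_DAPI", "dna_DNA")]),
               "missing DAPI")
})

test_that("zero true shift is recovered under independent noise realizations", {
  for (seed in 1:5) {
    sc <- renderScene(SceneSpec(nNuclei = 5, seed = 700 + seed),
                      mode = "sequential")
    tv <- estimateShift(sc$images$dna_DAPI, sc$images$rna_DAPI,
                        maxShift = 20)
    expect_identical(shiftVector(tv), c(dx = 0L, dy = 0L))
  }
})

test_that("peak ties break toward the smallest displacement", {
  # a constant-gradient-free periodic pattern gives equal peaks at +/- period
  m <- matrix(0, 40, 40)
  m[, seq(4, 40, by = 8)] <- 1
  tv <- estimateShift(m + 0.01 * matrix(seq_len(1600) %% 7, 40),
                      m + 0.01 * matrix(seq_len(1600) %% 7, 40),
                      maxShift = 16)
  expect_identical(shiftVector(tv), c(dx = 0L, dy = 0L))
})
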