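test_that("empty scene renders background and noise only, with empty truth", {
  sc <- renderScene(SceneSpec(nNuclei = 0, seed = 5))
  expect_equal(nrow(sceneNuclei(sc$truth)), 0L)
  expect_equal(nrow(sceneSpots(sc$truth)), 0L)
  for (im in sc$images) {
    px <- pixels(im)
    expect_lt(abs(mean(px) - 300), 2)        # background level
    expect_lt(max(px), 300 + 7 * 30)          # no structure above noise
  }
})

test_that("a forced biallelic nucleus has 2 DNA and 2 RNA truths, RNA near distinct DNA", {
  sc <- renderScene(SceneSpec(nNuclei = 1,
                              expressionProbs = c(0, 0, 1), seed = 11))
  sp <- sceneSpots(sc$truth)
  dna <- sp[sp$channel == "DNA", ]
  rna <- sp[sp$channel == "RNA", ]
  expect_equal(nrow(dna), 2L)
  expect_equal(nrow(rna), 2L)
  d <- sqrt(outer(rna$x_px, dna$x_px, "-")^2 +
            outer(rna$y_px, dna$y_px, "-")^2) * 0.108
  nearest <- apply(d, 1, which.min)
  expect_equal(sort(nearest), 1:2)            # distinct DNA partners
  expect_true(all(apply(d, 1, min) < 1.0))    # sub-micron offsets
})

test_that("expression-state fractions follow the specified probabilities", {
  probs <- c(silent = 0.66, mono = 0.27, bi = 0.07)
  batch <- renderFieldBatch(63, baseSeed = 100, nNuclei = 8,
                            expressionProbs = probs)
  states <- unlist(lapply(batch$truths, function(tr) sceneNuclei(tr)$state))
  n <- length(states)
  expect_gte(n, 500L)
  for (cls in names(probs)) {
    frac <- mean(states == cls)
    tol <- 3 * sqrt(probs[[cls]] * (1 - probs[[cls]]) / n)
    expect_lt(abs(frac - probs[[cls]]), tol)
  }
})

test_that("rendering is bit-identical for an identical spec", {
  s1 <- renderScene(SceneSpec(nNuclei = 3, seed = 42))
  s2 <- renderScene(SceneSpec(nNuclei = 3, seed = 42))
  for (nm in names(s1$images))
    expect_identical(pixels(s1$images[[nm]]), pixels(s2$images[[nm]]))
  expect_identical(sceneSpots(s1$truth), sceneSpots(s2$truth))
  s3 <- renderScene(SceneSpec(nNuclei = 3, seed = 43))
  expect_false(identical(pixels(s1$images$DAPI), pixels(s3$images$DAPI)))
})

test_that("sequential rounds differ by exactly the recorded translation before noise", {
  sh <- c(6L, -3L)
  spec <- SceneSpec(nNuclei = 4, interRoundShiftPx = sh, noiseSigma = 0,
                    seed = 9)
  sc <- renderScene(spec, mode = "sequential")
  expect_identical(sceneShift(sc$truth), sh)
  a <- pixels(sc$images$rna_DAPI)
  b <- pixels(sc$images$dna_DAPI)
  # compare on the overlap region (vacated band holds background only)
  rows <- (1 + max(0, sh[2])):(nrow(a) + min(0, sh[2]))
  cols <- (1 + max(0, sh[1])):(ncol(a) + min(0, sh[1]))
  expect_identical(b[rows, cols], a[rows - sh[2], cols - sh[1]])
})

test_that("sequential-mode truth equals simultaneous-mode truth for the same seed", {
  spec <- SceneSpec(nNuclei = 5, interRoundShiftPx = c(7L, -4L), seed = 21)
  t1 <- renderScene(spec, mode = "simultaneous")$truth
  t2 <- renderScene(spec, mode = "sequential")$truth
  expect_identical(sceneNuclei(t1), sceneNuclei(t2))
  expect_identical(sceneSpots(t1), sceneSpots(t2))
})

test_that("over-dense scenes are rejected with a clear error", {
  expect_error(renderScene(SceneSpec(imageSizePx = c(128L, 128L),
                                     nNuclei = 20, seed = 1)),
               "over-dense")
})

test_that("invalid scene specifications fail validity", {
  expect_error(SceneSpec(expressionProbs = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(SceneSpec(nucleusEccentricity = 1), "ccentricity")
  expect_error(SceneSpec(rnaOffsetSigmaUm = -1), "rnaOffsetSigmaUm")
})

test_that("decoy RNA spots land at least 1.5 um from any DNA spot", {
  sc <- renderScene(SceneSpec(nNuclei = 6, decoyRnaRate = 2,
                              expressionProbs = c(1, 0, 0), seed = 8))
  sp <- sceneSpots(sc$truth)
  rna <- sp[sp$channel == "RNA", ]
  dna <- sp[sp$channel == "DNA", ]
  expect_gt(nrow(rna), 0L)
  for (i in seq_len(nrow(rna))) {
    dn <- dna[dna$nucleus == rna$nucleus[i], ]
    d <- sqrt((dn$x_px - rna$x_px[i])^2 + (dn$y_px - rna$y_px[i])^2) * 0.108
    expect_gte(min(d), 1.5)
  }
})

test_that("writePlate writes one TIFF per image plus a lossless manifest", {
  dir <- withr::local_tempdir()
  sc <- renderScene(SceneSpec(nNuclei = 2, seed = 3))
  man <- writePlate(sc$images, dir)
  expect_equal(nrow(man), 3L)
  expect_length(list.files(dir, pattern = "\\.tif$"), 3L)
  back <- readPlateImages(loadManifest(dir))
  for (orig in sc$images) {
    stem <- sprintf("%s_%s_f%d_%s_%s", orig@plate, orig@well, orig@field,
                    orig@round, orig@channel)
    expect_identical(pixels(back[[stem]]), pixels(orig))
    expect_identical(back[[stem]]@channel, orig@channel)
    expect_identical(back[[stem]]@well, orig@well)
  }
  expect_error(writePlate(sc$images, dir), "force")
  expect_silent(writePlate(sc$images, dir, force = TRUE))
})

test_that("writePlate with an empty collection writes an empty manifest", {
  dir <- withr::local_tempdir()
  man <- writePlate(list(), dir)
  expect_equal(nrow(man), 0L)
  expect_length(list.files(dir, pattern = "\\.tif$"), 0L)
  expect_equal(nrow(loadManifest(dir)), 0L)
})
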