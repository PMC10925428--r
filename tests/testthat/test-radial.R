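test_that("the radial map of a disc matches the closed form r/R", {
  for (R in c(30L, 40L, 60L)) {
    mask <- discLabeledMask(R)
    rm_ <- radialMap(mask, 1L)
    ctr <- R + 4  # 0-based centre
    expect_equal(rm_[ctr + 1, ctr + 1], 0)
    # pixel adjacent to the boundary
    expect_gte(rm_[ctr + 1, ctr + R], 1 - 1.5 / R)
    # closed form: distance transform of a disc is R - r
    idx <- which(!is.na(rm_), arr.ind = TRUE)
    r <- sqrt((idx[, 1] - 1 - ctr)^2 + (idx[, 2] - 1 - ctr)^2)
    err <- abs(rm_[idx] - r / R)
    expect_lt(mean(err), 2 / R)
    expect_true(all(rm_[idx] >= 0 & rm_[idx] <= 1))
  }
})

test_that("radial map errors on absent labels and degenerate nuclei", {
  mask <- discLabeledMask(20)
  expect_error(radialMap(mask, 7L), "absent")
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_error(radialMap(LabeledMask(single), 1L), "degenerate")
})

test_that("shell binning is left-closed with a right-closed final bin", {
  expect_identical(radialShell(c(0, 0.35, 0.2, 0.799, 0.8, 1.0)),
                   c(1L, 2L, 2L, 4L, 5L, 5L))
  expect_error(radialShell(1.2), "0, 1")
  # shell counts partition the alleles
  set.seed(30)
  x <- runif(500)
  expect_equal(sum(table(radialShell(x))), 500L)
  expect_true(all(radialShell(x) %in% 1:5))
})

test_that("allele annotation reads the map at the containing pixel", {
  R <- 40L
  mask <- discLabeledMask(R)
  ctr <- R + 4
  alleles <- data.frame(nucleus_label = 1L,
                        x_px = ctr + c(0, R / 2, R - 1),
                        y_px = rep(ctr, 3))
  out <- annotateRadial(alleles, mask)
  expect_equal(out$radial[1], 0)
  expect_lt(abs(out$radial[2] - 0.5), 2 / R)
  expect_gt(out$radial[3], 0.9)
  expect_identical(out$shell[1], 1L)
  expect_identical(out$shell[3], 5L)
  outside <- data.frame(nucleus_label = 1L, x_px = 1, y_px = 1)
  expect_error(annotateRadial(outside, mask), "outside")
})

test_that("radial values are rotation invariant within rasterization tolerance", {
  # ellipse mask and its 90-degree rotation
  n <- 121L; a <- 45; b <- 30
  xs <- 0:(n - 1L); ctr <- 60
  d2 <- outer(((xs - ctr) / b)^2, ((xs - ctr) / a)^2, "+")   # rows=y
  ell <- matrix(as.integer(d2 <= 1), n, n)
  mask <- LabeledMask(ell)
  maskRot <- LabeledMask(t(ell))
  pts <- rbind(c(20, 0), c(-10, 5), c(0, -22), c(30, 10))  # offsets (dx, dy)
  for (i in seq_len(nrow(pts))) {
    v1 <- annotateRadial(data.frame(nucleus_label = 1L,
                                    x_px = ctr + pts[i, 1],
                                    y_px = ctr + pts[i, 2]), mask)$radial
    v2 <- annotateRadial(data.frame(nucleus_label = 1L,
                                    x_px = ctr + pts[i, 2],
                                    y_px = ctr + pts[i, 1]), maskRot)$radial
    expect_lt(abs(v1 - v2), 0.02)
  }
})

test_that("true placement radii are recovered end to end on rendered scenes", {
  errs <- numeric()
  for (seed in 1:4) {
    sc <- renderScene(SceneSpec(nNuclei = 6, seed = 900 + seed))
    mask <- segmentNuclei(sc$images$DAPI)
    tr <- sceneSpots(sc$truth)
    dna <- tr[tr$channel == "DNA", ]
    al <- data.frame(nucleus_label = maskLabels(mask)[cbind(
      round(dna$y_px) + 1L, round(dna$x_px) + 1L)],
      x_px = dna$x_px, y_px = dna$y_px)
    keep <- al$nucleus_label > 0L
    out <- annotateRadial(al[keep, ], mask)
    errs <- c(errs, abs(out$radial - dna$radial_true[keep]))
  }
  expect_lt(median(errs), 0.05)
})

test_that("the KS comparison separates distinct radial laws and calibrates under the null", {
  set.seed(41)
  a <- runif(2000)
  b <- sqrt(runif(2000))   # periphery-skewed
  cmp <- compareRadial(a, b, "uniform", "periphery")
  expect_lt(cmp$p_value[1], 1e-6)
  expect_gt(cmp$mean[2], cmp$mean[1])

  same <- compareRadial(a, a)
  expect_equal(same$ks_statistic[1], 0)
  expect_equal(same$p_value[1], 1)

  set.seed(42)
  rej <- mean(replicate(100, {
    compareRadial(runif(200), runif(200))$p_value[1] < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.12)
  expect_error(compareRadial(numeric(), a), "non-empty")
})
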