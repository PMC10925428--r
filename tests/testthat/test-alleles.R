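# constructed cells: a nucleus table (all passing QC) and assigned spots
makeNuclei <- function(labels) {
  data.frame(plate = "p1", well = "A01", field = 1L, nucleus_label = labels,
             passed_qc = TRUE)
}
makeSpots <- function(label, channel, xUm, yUm) {
  n <- length(xUm)
  data.frame(plate = "p1", well = "A01", field = 1L, channel = channel,
             spot_id = seq_len(n), x_px = xUm / 0.108, y_px = yUm / 0.108,
             x_um = xUm, y_um = yUm, peak_intensity = 1000,
             log_response = 100, nucleus_label = label)
}

test_that("spot counts are binned 0/1/2/>=3 and gating follows the 2-DNA rule", {
  nuclei <- makeNuclei(1:4)
  spots <- rbind(
    makeSpots(1L, "DNA", c(1, 2), c(0, 0)),     # 2 DNA, 1 RNA -> gated
    makeSpots(1L, "RNA", 1.5, 0),
    makeSpots(2L, "DNA", c(1, 2, 3, 4), c(0, 0, 0, 0)),  # 4 DNA -> ">=3"
    makeSpots(3L, "DNA", c(1, 2), c(0, 0)),     # 2 DNA, 3 RNA -> not gated
    makeSpots(3L, "RNA", c(1, 2, 3), c(1, 1, 1)),
    makeSpots(0L, "DNA", c(5, 6), c(5, 5)))     # unassigned: ignored
  cells <- summarizeCells(nuclei, spots)
  cells <- cells[order(cells$nucleus_label), ]
  expect_equal(cells$dna_bin, c("2", ">=3", "2", "0"))
  expect_equal(cells$rna_bin, c("1", "0", ">=3", "0"))
  expect_equal(cells$gated, c(TRUE, FALSE, FALSE, FALSE))
  # nucleus 4 has no spots at all: counted as 0/0, gated FALSE
  expect_equal(cells$n_dna_spots[4], 0L)
})

test_that("QC-failing nuclei are excluded from cell summaries", {
  nuclei <- makeNuclei(1:2)
  nuclei$passed_qc[2] <- FALSE
  cells <- summarizeCells(nuclei, makeSpots(1L, "DNA", c(1, 2), c(0, 0)))
  expect_equal(cells$nucleus_label, 1L)
})

test_that("activity classification follows the distance rules exactly", {
  nuclei <- makeNuclei(1:4)
  spots <- rbind(
    # cell 1: RNA 0.5 um from DNA1 -> Active; DNA2 3 um away -> Inactive
    makeSpots(1L, "DNA", c(0, 3), c(0, 0)),
    makeSpots(1L, "RNA", 0.5, 0),
    # cell 2: no RNA -> both NoTranscription
    makeSpots(2L, "DNA", c(0, 3), c(0, 0)),
    # cell 3: RNA at exactly 1.0 um -> Inactive (strict below-threshold)
    makeSpots(3L, "DNA", c(0, 5), c(0, 0)),
    makeSpots(3L, "RNA", 1.0, 0),
    # cell 4: all four pairwise distances; per-DNA minima 0.2 and 0.3
    makeSpots(4L, "DNA", c(0, 5), c(0, 0)),
    makeSpots(4L, "RNA", c(0.2, 5.3), c(0, 0)))
  al <- classifyAlleles(summarizeCells(nuclei, spots), spots)
  expect_equal(nrow(al), 8L)
  get <- function(nuc) al[al$nucleus_label == nuc, ]
  expect_setequal(get(1)$status, c("Active", "Inactive"))
  expect_equal(get(1)$min_rna_distance_um[get(1)$status == "Active"], 0.5)
  expect_equal(get(2)$status, rep("NoTranscription", 2))
  expect_true(all(is.na(get(2)$min_rna_distance_um)))
  s3 <- get(3)
  expect_equal(s3$status[s3$x_px == 0], "Inactive")
  s4 <- get(4)[order(get(4)$x_px), ]
  expect_equal(s4$min_rna_distance_um, c(0.2, 0.3), tolerance = 1e-12)
  expect_equal(s4$status, c("Active", "Active"))
})

test_that("allele records are conserved and fractions sum to one", {
  nuclei <- makeNuclei(1:10)
  rows <- list()
  for (i in 1:10) {
    rows[[length(rows) + 1]] <- makeSpots(i, "DNA", c(0, 4) + i * 20, c(0, 0))
    if (i <= 2)        # biallelic: RNA at both DNA spots
      rows[[length(rows) + 1]] <- makeSpots(i, "RNA", c(0.1, 4.1) + i * 20,
                                            c(0, 0))
    else if (i <= 5)   # monoallelic
      rows[[length(rows) + 1]] <- makeSpots(i, "RNA", 0.1 + i * 20, 0)
  }
  spots <- do.call(rbind, rows)
  cells <- summarizeCells(nuclei, spots)
  al <- classifyAlleles(cells, spots)
  expect_equal(nrow(al), 2L * sum(cells$gated))
  fr <- recoverStateFractions(al)
  expect_equal(unname(fr), c(0.2, 0.3, 0.5))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("all-silent input gives fractions (0, 0, 1)", {
  nuclei <- makeNuclei(1:3)
  spots <- do.call(rbind, lapply(1:3, function(i)
    makeSpots(i, "DNA", c(0, 4) + i * 10, c(0, 0))))
  al <- classifyAlleles(summarizeCells(nuclei, spots), spots)
  expect_true(all(al$status == "NoTranscription"))
  expect_equal(unname(recoverStateFractions(al)), c(0, 0, 1))
})

test_that("raising the activity threshold never decreases the Active count", {
  set.seed(20)
  nuclei <- makeNuclei(1:12)
  rows <- list()
  for (i in 1:12) {
    rows[[length(rows) + 1]] <- makeSpots(i, "DNA",
                                          c(0, 6) + i * 30, c(0, 0))
    rows[[length(rows) + 1]] <- makeSpots(i, "RNA",
                                          runif(2, 0, 8) + i * 30,
                                          runif(2, 0, 2))
  }
  spots <- do.call(rbind, rows)
  cells <- summarizeCells(nuclei, spots)
  nActive <- vapply(c(0.25, 0.5, 1, 2, 4), function(th)
    sum(classifyAlleles(cells, spots, activityThresholdUm = th)$status ==
        "Active"), 0L)
  expect_true(all(diff(nActive) >= 0))
})

test_that("a gated cell with a wrong DNA count triggers an internal error", {
  cells <- data.frame(plate = "p1", well = "A01", field = 1L,
                      nucleus_label = 1L, n_dna_spots = 2L, n_rna_spots = 0L,
                      dna_bin = "2", rna_bin = "0", gated = TRUE)
  spots <- makeSpots(1L, "DNA", 1, 1)   # only one DNA spot present
  expect_error(classifyAlleles(cells, spots), "gating violation")
})
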