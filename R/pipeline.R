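# End-to-end orchestration: (register) -> segment -> detect -> classify ->
# radial -> report, for simultaneous and sequential acquisition modes.

#' Build a pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated list.
#' Detection parameters are per channel (DNA and RNA probes are tuned
#' independently, as each plate is in practice).
#'
#' @param mode \code{"simultaneous"} or \code{"sequential"}.
#' @param segmentation List: \code{minAreaPx}, \code{smoothingSigmaPx},
#'   \code{watershedTolerance}.
#' @param qc List: \code{minDiameterUm}, \code{circularityMin},
#'   \code{logic} ("and"/"or"), \code{dropBorder}.
#' @param detection List with entries \code{DNA} and \code{RNA}, each a
#'   list \code{sigmaPx}, \code{threshold}, \code{minSeparationPx}.
#' @param registration List: \code{maxShift}, \code{correlation}.
#' @param activityThresholdUm Allele activity distance threshold (microns).
#' @param shellWidth Radial shell width (default 0.2, i.e. 5 shells).
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return A list of class \code{htfishConfig}.
#' @export
htfishConfig <- function(mode = c("simultaneous", "sequential"),
                         segmentation = list(),
                         qc = list(),
                         detection = list(),
                         registration = list(),
                         activityThresholdUm = 1.0,
                         shellWidth = 0.2,
                         seed = 1L) {
  mode <- match.arg(mode)
  segmentation <- utils::modifyList(
    list(minAreaPx = 500L, smoothingSigmaPx = 2, watershedTolerance = 1),
    segmentation)
  qc <- utils::modifyList(
    list(minDiameterUm = 10, circularityMin = 0.95, logic = "and",
         dropBorder = FALSE), qc)
  detDefault <- list(sigmaPx = 1.5, threshold = "auto", minSeparationPx = 3)
  detection <- list(
    DNA = utils::modifyList(detDefault, detection$DNA %||% list()),
    RNA = utils::modifyList(detDefault, detection$RNA %||% list()))
  registration <- utils::modifyList(
    list(maxShift = 50L, correlation = "zero_mean"), registration)
  cfg <- list(mode = mode, segmentation = segmentation, qc = qc,
              detection = detection, registration = registration,
              activityThresholdUm = activityThresholdUm,
              shellWidth = shellWidth, seed = as.integer(seed))
  class(cfg) <- "htfishConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from a YAML file
#'
#' Top-level YAML keys mirror the arguments of \code{\link{htfishConfig}};
#' absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return A validated \code{htfishConfig} list.
#' @export
htfishConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(htfishConfig, y)
}

# djb2-style hash of the serialized configuration, for output provenance
configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

# analyze one field-of-view given its ChannelImages
analyzeField <- function(fieldImages, config) {
  rounds <- vapply(fieldImages, function(x) x@round, "")
  channels <- vapply(fieldImages, function(x) x@channel, "")
  sequential <- config$mode == "sequential"
  if (sequential) {
    if (!all(c("rna_round", "dna_round") %in% rounds))
      stop("sequential mode requires rna_round and dna_round images")
    reg <- registerRoundPair(fieldImages[rounds == "rna_round"],
                             fieldImages[rounds == "dna_round"],
                             maxShift = config$registration$maxShift,
                             correlation = config$registration$correlation)
    dnaRound <- reg$dnaRound
    dapi <- dnaRound[[which(vapply(dnaRound, function(x) x@channel, "") ==
                            "DAPI")[1]]]
    probe <- list(
      DNA = dnaRound[[which(vapply(dnaRound, function(x) x@channel, "") ==
                            "DNA")[1]]],
      RNA = reg$rnaRound[[which(vapply(reg$rnaRound,
                                       function(x) x@channel, "") ==
                                "RNA")[1]]])
    shift <- reg$shift
  } else {
    if (any(rounds != "single"))
      stop("simultaneous mode expects single-round images only")
    if (!all(c("DAPI", "DNA", "RNA") %in% channels))
      stop("simultaneous mode requires DAPI, DNA and RNA images")
    dapi <- fieldImages[[which(channels == "DAPI")[1]]]
    probe <- list(DNA = fieldImages[[which(channels == "DNA")[1]]],
                  RNA = fieldImages[[which(channels == "RNA")[1]]])
    shift <- NULL
  }

  seg <- config$segmentation
  mask <- segmentNuclei(dapi, minAreaPx = seg$minAreaPx,
                        smoothingSigmaPx = seg$smoothingSigmaPx,
                        watershedTolerance = seg$watershedTolerance)
  nuc <- measureNuclei(mask, minDiameterUm = config$qc$minDiameterUm,
                       circularityMin = config$qc$circularityMin,
                       qcLogic = config$qc$logic,
                       dropBorder = config$qc$dropBorder)
  nuc$nucleus_label <- nuc$label
  nuc$plate <- dapi@plate; nuc$well <- dapi@well; nuc$field <- dapi@field
  nuc$pixel_size_um <- dapi@pixelSizeUm

  spotTabs <- lapply(c("DNA", "RNA"), function(ch) {
    p <- config$detection[[ch]]
    s <- detectSpots(probe[[ch]], sigmaPx = p$sigmaPx,
                     threshold = p$threshold,
                     minSeparationPx = p$minSeparationPx)
    s <- assignSpots(s, mask)
    if (nrow(s)) {
      s$plate <- dapi@plate; s$well <- dapi@well; s$field <- dapi@field
      s$pixel_size_um <- dapi@pixelSizeUm
    }
    s
  })
  spots <- do.call(rbind, spotTabs[vapply(spotTabs, nrow, 0L) > 0])
  if (is.null(spots))
    spots <- cbind(detectSpots(probe$DNA, threshold = Inf)[0, ],
                   data.frame(plate = character(), well = character(),
                              field = integer(), pixel_size_um = numeric()))

  cells <- summarizeCells(nuc, spots)
  alleles <- classifyAlleles(cells, spots,
                             pixelSizeUm = dapi@pixelSizeUm,
                             activityThresholdUm = config$activityThresholdUm)
  alleles <- annotateRadial(alleles, mask, shellWidth = config$shellWidth)
  shiftRow <- if (is.null(shift)) NULL else
    data.frame(plate = dapi@plate, well = dapi@well, field = dapi@field,
               dx_px = shift@dxPx, dy_px = shift@dyPx,
               peak_value = shift@peakValue,
               correlation_margin = shift@correlationMargin)
  list(nuclei = nuc, spots = spots, cells = cells, alleles = alleles,
       shifts = shiftRow, mask = mask)
}

#' Run the full analysis pipeline
#'
#' Orchestrates registration (sequential mode only), nucleus segmentation
#' and QC, per-channel LoG spot detection and assignment, cell gating,
#' allele classification, and radial annotation over every field of a
#' plate, then assembles plate-level tables and the radial active-vs-
#' inactive comparison.  The analysis is deterministic: identical inputs
#' and configuration yield byte-identical outputs.
#'
#' @param config A \code{\link{htfishConfig}} list.
#' @param directory Plate directory containing \code{manifest.csv} (written
#'   by \code{\link{writePlate}}); alternative to \code{fields}.
#' @param fields List of fields, each a list of \linkS4class{ChannelImage}
#'   (e.g. the \code{images} element of \code{\link{renderScene}});
#'   alternative to \code{directory}.
#' @param outDir Optional output directory for per-well tables, allele and
#'   cell tables, shift log, radial comparison and summary files.
#' @return List with \code{nuclei}, \code{spots}, \code{cells},
#'   \code{alleles}, \code{shifts}, \code{radialComparison},
#'   \code{summary}, \code{configHash}.
#' @export
runPipeline <- function(config, directory = NULL, fields = NULL,
                        outDir = NULL) {
  stopifnot(inherits(config, "htfishConfig"))
  if (is.null(fields)) {
    if (is.null(directory)) stop("give either a plate directory or fields")
    manifest <- loadManifest(directory)
    wanted <- if (config$mode == "sequential")
      c("rna_round", "dna_round") else "single"
    if (!all(manifest$round %in% wanted))
      stop("manifest rounds do not match mode '", config$mode, "'")
    grp <- with(manifest, paste(plate, well, field, sep = "\r"))
    fields <- lapply(split(seq_len(nrow(manifest)), grp), function(i)
      readPlateImages(manifest[i, ], directory = directory))
  }
  ids <- vapply(fields, function(f)
    paste(f[[1]]@plate, f[[1]]@well, f[[1]]@field), "")
  if (anyDuplicated(ids))
    stop("duplicate (plate, well, field) identity across fields: ",
         paste(unique(ids[duplicated(ids)]), collapse = "; "))
  res <- lapply(fields, function(f) {
    tryCatch(analyzeField(f, config), error = function(e) {
      im <- f[[1]]
      stop("field ", im@plate, "/", im@well, " f", im@field, ": ",
           conditionMessage(e), call. = FALSE)
    })
  })
  bindAll <- function(name) {
    tabs <- lapply(res, `[[`, name)
    tabs <- tabs[!vapply(tabs, is.null, TRUE)]
    if (!length(tabs)) return(NULL)
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  out <- list(nuclei = bindAll("nuclei"), spots = bindAll("spots"),
              cells = bindAll("cells"), alleles = bindAll("alleles"),
              shifts = bindAll("shifts"))

  al <- out$alleles
  out$radialComparison <- if (!is.null(al) && nrow(al) &&
                              any(al$status == "Active") &&
                              any(al$status != "Active")) {
    compareRadial(al$radial[al$status == "Active"],
                  al$radial[al$status != "Active"],
                  nameA = "Active", nameB = "Inactive")
  } else NULL
  out$summary <- reportSummary(out)
  out$configHash <- configHash(config)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeWellTables(out$nuclei, out$spots, outDir)
    if (!is.null(out$alleles))
      writeCommentedCsv(out$alleles, file.path(outDir, "alleles.csv"))
    if (!is.null(out$cells))
      writeCommentedCsv(out$cells, file.path(outDir, "cells.csv"))
    if (!is.null(out$shifts))
      writeCommentedCsv(out$shifts, file.path(outDir, "shifts.csv"))
    if (!is.null(out$radialComparison))
      writeCommentedCsv(out$radialComparison,
                        file.path(outDir, "radial_comparison.csv"))
    writeCommentedCsv(out$summary, file.path(outDir, "summary.csv"))
    writeLines(c(sprintf("config_hash: %s", out$configHash),
                 sprintf("mode: %s", config$mode),
                 sprintf("seed: %d", config$seed)),
               file.path(outDir, "run_info.txt"))
    writeLines(renderSummaryMarkdown(out$summary),
               file.path(outDir, "summary.md"))
  }
  out
}

#' Plate-level summary of a pipeline run
#'
#' One row per plate: cells analyzed, percentage of nuclei by DNA spot-count
#' bin, percentage of gated cells by expression state, mean and sd radial
#' position by activity class, and the active-vs-inactive KS p-value
#' (NA when either group is empty).
#'
#' @param results Pipeline results list (\code{cells}, \code{alleles}).
#' @return data.frame summary.
#' @export
reportSummary <- function(results) {
  cells <- results$cells; alleles <- results$alleles
  if (is.null(cells) || nrow(cells) == 0L) {
    return(data.frame(plate = NA_character_, n_cells = 0L, n_gated = 0L,
                      pct_dna_0 = NA_real_, pct_dna_1 = NA_real_,
                      pct_dna_2 = NA_real_, pct_dna_3plus = NA_real_,
                      pct_biallelic = NA_real_, pct_monoallelic = NA_real_,
                      pct_silent = NA_real_, n_alleles = 0L,
                      mean_radial_active = NA_real_,
                      sd_radial_active = NA_real_,
                      mean_radial_inactive = NA_real_,
                      sd_radial_inactive = NA_real_,
                      ks_p_active_vs_inactive = NA_real_))
  }
  plates <- sort(unique(cells$plate))
  rows <- lapply(plates, function(pl) {
    cc <- cells[cells$plate == pl, , drop = FALSE]
    binPct <- function(bin) 100 * mean(cc$dna_bin == bin)
    al <- if (is.null(alleles)) alleles else
      alleles[alleles$plate == pl, , drop = FALSE]
    fr <- if (!is.null(al) && nrow(al)) recoverStateFractions(al) else
      c(biallelic = NA_real_, monoallelic = NA_real_, silent = NA_real_)
    act <- if (!is.null(al)) al$radial[al$status == "Active"] else numeric()
    ina <- if (!is.null(al)) al$radial[al$status != "Active"] else numeric()
    ksP <- if (length(act) && length(ina))
      suppressWarnings(ks.test(act, ina, exact = FALSE)$p.value) else
        NA_real_
    data.frame(plate = pl, n_cells = nrow(cc), n_gated = sum(cc$gated),
               pct_dna_0 = binPct("0"), pct_dna_1 = binPct("1"),
               pct_dna_2 = binPct("2"), pct_dna_3plus = binPct(">=3"),
               pct_biallelic = 100 * fr[["biallelic"]],
               pct_monoallelic = 100 * fr[["monoallelic"]],
               pct_silent = 100 * fr[["silent"]],
               n_alleles = if (is.null(al)) 0L else nrow(al),
               mean_radial_active = if (length(act)) mean(act) else NA_real_,
               sd_radial_active = if (length(act) > 1) sd(act) else NA_real_,
               mean_radial_inactive = if (length(ina)) mean(ina) else
                 NA_real_,
               sd_radial_inactive = if (length(ina) > 1) sd(ina) else
                 NA_real_,
               ks_p_active_vs_inactive = ksP)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a pipeline summary as markdown
#'
#' @param summary Summary data.frame from \code{\link{reportSummary}}.
#' @return Character vector of markdown lines.
#' @export
renderSummaryMarkdown <- function(summary) {
  fmt <- function(x) ifelse(is.na(x), "n/a",
                            ifelse(abs(x) < 1, sprintf("%.3g", x),
                                   sprintf("%.1f", x)))
  lines <- c("# Plate summary", "")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    lines <- c(lines,
      sprintf("## Plate %s", s$plate),
      sprintf("- cells analyzed: %d (gated: %d)", s$n_cells, s$n_gated),
      sprintf("- %% nuclei with 0/1/2/>=3 DNA spots: %s / %s / %s / %s",
              fmt(s$pct_dna_0), fmt(s$pct_dna_1), fmt(s$pct_dna_2),
              fmt(s$pct_dna_3plus)),
      sprintf("- %% cells biallelic / monoallelic / silent: %s / %s / %s",
              fmt(s$pct_biallelic), fmt(s$pct_monoallelic),
              fmt(s$pct_silent)),
      sprintf("- mean radial (active): %s +/- %s; (inactive): %s +/- %s",
              fmt(s$mean_radial_active), fmt(s$sd_radial_active),
              fmt(s$mean_radial_inactive), fmt(s$sd_radial_inactive)),
      sprintf("- KS p (active vs inactive radial): %s",
              fmt(s$ks_p_active_vs_inactive)),
      "")
  }
  lines
}
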