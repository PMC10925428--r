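# Per-cell spot accounting, gating, DNA-RNA distance computation and
# allele activity classification.

binSpotCount <- function(n) ifelse(n <= 2L, as.character(n), ">=3")

cellKey <- function(df) paste(df$plate, df$well, df$field, df$nucleus_label,
                              sep = "\r")

#' Summarize spot counts per cell
#'
#' Counts DNA and RNA spots per QC-passing nucleus (over nucleus-assigned
#' spots only), bins the counts into "0" / "1" / "2" / ">=3", and flags the
#' cells admitted to allele analysis: exactly 2 DNA spots and at most 2 RNA
#' spots.
#'
#' @param nuclei Nucleus table with \code{plate, well, field, nucleus_label,
#'   passed_qc} (see \code{\link{measureNuclei}}; \code{label} is accepted
#'   for \code{nucleus_label} when provenance columns are absent).
#' @param spots Assigned spot table (\code{channel}, \code{nucleus_label}
#'   filled; label 0 rows are ignored).
#' @return data.frame with one row per QC-passing nucleus: \code{plate,
#'   well, field, nucleus_label, n_dna_spots, n_rna_spots, dna_bin,
#'   rna_bin, gated}.
#' @export
summarizeCells <- function(nuclei, spots) {
  nuclei <- normalizeProvenance(nuclei)
  spots <- normalizeProvenance(spots)
  nuclei <- nuclei[nuclei$passed_qc, , drop = FALSE]
  out <- data.frame(plate = nuclei$plate, well = nuclei$well,
                    field = nuclei$field,
                    nucleus_label = nuclei$nucleus_label)
  if (nrow(out) == 0L) {
    out$n_dna_spots <- integer(); out$n_rna_spots <- integer()
    out$dna_bin <- character(); out$rna_bin <- character()
    out$gated <- logical()
    return(out)
  }
  spots <- spots[spots$nucleus_label > 0L, , drop = FALSE]
  key <- cellKey(out)
  countFor <- function(channel) {
    s <- spots[spots$channel == channel, , drop = FALSE]
    if (!nrow(s)) return(integer(nrow(out)))
    tab <- table(factor(cellKey(s), levels = key))
    as.integer(tab)
  }
  out$n_dna_spots <- countFor("DNA")
  out$n_rna_spots <- countFor("RNA")
  out$dna_bin <- binSpotCount(out$n_dna_spots)
  out$rna_bin <- binSpotCount(out$n_rna_spots)
  out$gated <- out$n_dna_spots == 2L & out$n_rna_spots <= 2L
  out
}

# fill plate/well/field provenance defaults and unify the label column
normalizeProvenance <- function(df) {
  if (!"nucleus_label" %in% names(df) && "label" %in% names(df))
    df$nucleus_label <- df$label
  for (col in c("plate", "well", "field")) {
    if (!col %in% names(df))
      df[[col]] <- if (col == "field") 1L else
        c(plate = "plate01", well = "A01")[[col]]
  }
  df
}

#' Classify alleles as Active / Inactive / NoTranscription
#'
#' For each gated cell, all pairwise 2D Euclidean distances between its two
#' DNA spots and its 0--2 RNA spots are computed in microns; each DNA spot
#' takes the minimum over RNA spots.  DNA spots in cells without RNA spots
#' get an undefined (NA) distance and are classified NoTranscription; a
#' distance strictly below \code{activityThresholdUm} classifies the allele
#' Active (proximity to a transcription site), otherwise Inactive.  RNA
#' spots are not exclusively matched: the per-DNA-spot minimum allows two
#' DNA spots to claim the same RNA spot.
#'
#' @param summaries Cell summaries from \code{\link{summarizeCells}}; only
#'   gated cells are processed.
#' @param spots Assigned spot table with \code{x_um, y_um} (or \code{x_px,
#'   y_px} plus \code{pixelSizeUm} to convert).
#' @param pixelSizeUm Pixel size used when micron coordinates are absent.
#' @param activityThresholdUm Activity distance threshold in microns
#'   (default 1.0, strict inequality).
#' @return data.frame with two rows per gated cell: \code{plate, well,
#'   field, nucleus_label, dna_spot_id, x_px, y_px, min_rna_distance_um,
#'   status}.
#' @export
classifyAlleles <- function(summaries, spots, pixelSizeUm = 0.108,
                            activityThresholdUm = 1.0) {
  spots <- normalizeProvenance(spots)
  if (!all(c("x_um", "y_um") %in% names(spots))) {
    spots$x_um <- spots$x_px * pixelSizeUm
    spots$y_um <- spots$y_px * pixelSizeUm
  }
  gatedCells <- summaries[summaries$gated, , drop = FALSE]
  empty <- data.frame(plate = character(), well = character(),
                      field = integer(), nucleus_label = integer(),
                      dna_spot_id = integer(), x_px = numeric(),
                      y_px = numeric(), min_rna_distance_um = numeric(),
                      status = character())
  if (nrow(gatedCells) == 0L) return(empty)
  spots <- spots[spots$nucleus_label > 0L, , drop = FALSE]
  skey <- cellKey(spots)
  gkey <- cellKey(gatedCells)
  rows <- vector("list", nrow(gatedCells))
  for (i in seq_len(nrow(gatedCells))) {
    cs <- spots[skey == gkey[i], , drop = FALSE]
    dna <- cs[cs$channel == "DNA", , drop = FALSE]
    rna <- cs[cs$channel == "RNA", , drop = FALSE]
    if (nrow(dna) != 2L)
      stop("gating violation: gated cell with ", nrow(dna), " DNA spots")
    if (nrow(rna) == 0L) {
      mind <- rep(NA_real_, 2L)
    } else {
      d <- sqrt(outer(dna$x_um, rna$x_um, "-")^2 +
                outer(dna$y_um, rna$y_um, "-")^2)
      mind <- apply(d, 1, min)
    }
    status <- ifelse(is.na(mind), "NoTranscription",
                     ifelse(mind < activityThresholdUm, "Active",
                            "Inactive"))
    rows[[i]] <- data.frame(plate = gatedCells$plate[i],
                            well = gatedCells$well[i],
                            field = gatedCells$field[i],
                            nucleus_label = gatedCells$nucleus_label[i],
                            dna_spot_id = dna$spot_id,
                            x_px = dna$x_px, y_px = dna$y_px,
                            min_rna_distance_um = mind, status = status)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression-state fractions from classified alleles
#'
#' Per nucleus: biallelic = both alleles Active, monoallelic = exactly one,
#' silent = none.  Fractions are over gated nuclei and sum to 1.
#'
#' @param alleles Allele table from \code{\link{classifyAlleles}}.
#' @return Named numeric \code{c(biallelic, monoallelic, silent)} (all NA
#'   when no alleles are given).
#' @export
recoverStateFractions <- function(alleles) {
  if (nrow(alleles) == 0L)
    return(c(biallelic = NA_real_, monoallelic = NA_real_,
             silent = NA_real_))
  nActive <- tapply(alleles$status == "Active", cellKey(alleles), sum)
  n <- length(nActive)
  c(biallelic = sum(nActive == 2L) / n,
    monoallelic = sum(nActive == 1L) / n,
    silent = sum(nActive == 0L) / n)
}
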