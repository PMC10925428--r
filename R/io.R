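# Plate-organized I/O: TIFF images via a CSV manifest, and per-well flat
# CSV result tables (one file per well for nuclei, one per well and per
# channel for spots).

COORD_COMMENT <- "# coordinates: 0-based pixels, x = column, y = row; lengths in um where suffixed _um"

NUCLEUS_COLS <- c("plate", "well", "field", "nucleus_label", "area_um2",
                  "equivalent_diameter_um", "perimeter_um", "circularity",
                  "centroid_x_px", "centroid_y_px", "bbox_x0", "bbox_y0",
                  "bbox_x1", "bbox_y1", "passed_qc", "pixel_size_um")
SPOT_COLS <- c("plate", "well", "field", "channel", "spot_id", "x_px", "y_px",
               "x_um", "y_um", "peak_intensity", "log_response",
               "nucleus_label", "pixel_size_um")

#' Load and validate a plate manifest
#'
#' Reads \code{manifest.csv} from a plate directory written by
#' \code{\link{writePlate}}, checking that every referenced TIFF exists, that
#' well labels parse against the 384-well grid, and that the
#' (plate, well, field, round, channel) key is unique.
#'
#' @param directory Plate directory containing \code{manifest.csv}.
#' @return The manifest data.frame with an attribute \code{directory}.
#' @export
loadManifest <- function(directory) {
  manifestPath <- file.path(directory, "manifest.csv")
  if (!file.exists(manifestPath))
    stop("no manifest.csv found in ", directory)
  manifest <- read.csv(manifestPath, stringsAsFactors = FALSE)
  needed <- c("path", "plate", "well", "field", "round", "channel",
              "pixel_size_um")
  if (!all(needed %in% names(manifest)))
    stop("manifest missing columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "))
  if (nrow(manifest)) {
    parseWell(manifest$well)
    key <- with(manifest, paste(plate, well, field, round, channel))
    if (anyDuplicated(key))
      stop("duplicate manifest keys: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    missing <- !file.exists(file.path(directory, manifest$path))
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(manifest$path[missing], collapse = ", "))
  }
  attr(manifest, "directory") <- directory
  manifest
}

#' Read images referenced by a manifest
#'
#' @param manifest A manifest from \code{\link{loadManifest}} (or a subset of
#'   its rows, retaining the \code{directory} attribute).
#' @param directory Plate directory; defaults to the manifest's attribute.
#' @return Named list of \linkS4class{ChannelImage} (names are file stems).
#' @export
readPlateImages <- function(manifest, directory = attr(manifest, "directory")) {
  if (is.null(directory)) stop("no directory given or attached to manifest")
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    px <- tiff::readTIFF(file.path(directory, r$path), as.is = TRUE)
    storage.mode(px) <- "double"
    ChannelImage(px, plate = r$plate, well = r$well, field = r$field,
                 channel = r$channel, round = r$round,
                 pixelSizeUm = r$pixel_size_um)
  })
  names(images) <- sub("\\.tif$", "", manifest$path)
  images
}

# write a data.frame as CSV with a coordinate-convention comment header and
# full double precision, so concatenate-and-read reproduces it exactly
writeCommentedCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COORD_COMMENT, con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

readCommentedCsv <- function(path, colClasses = NA) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           colClasses = colClasses)
}

#' Write per-well flat result tables
#'
#' Mirrors the one-file-per-well output convention: nucleus records go to
#' \code{<plate>_<well>_nuclei.csv} (one per well) and spot records to
#' \code{<plate>_<well>_spots_<channel>.csv} (one per well per channel).
#' Column order is fixed and documented; concatenating all written files
#' reproduces the input tables exactly.
#'
#' @param nuclei Nucleus table with the columns of
#'   \code{\link{measureNuclei}} output plus \code{plate}, \code{well},
#'   \code{field}, \code{pixel_size_um}.
#' @param spots Spot table (output of \code{\link{assignSpots}} plus
#'   provenance columns).
#' @param directory Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
writeWellTables <- function(nuclei, spots, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- character()
  if (is.null(nuclei) || nrow(nuclei) == 0L) {
    if (is.null(spots) || nrow(spots) == 0L) {
      warning("empty tables: no well files written")
      return(invisible(paths))
    }
  }
  if (!is.null(nuclei) && nrow(nuclei)) {
    nuclei <- nuclei[, NUCLEUS_COLS]
    for (key in unique(paste(nuclei$plate, nuclei$well, sep = "_"))) {
      sub <- nuclei[paste(nuclei$plate, nuclei$well, sep = "_") == key, ]
      p <- file.path(directory, paste0(key, "_nuclei.csv"))
      writeCommentedCsv(sub, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(spots) && nrow(spots)) {
    spots <- spots[, SPOT_COLS]
    gk <- paste(spots$plate, spots$well, spots$channel, sep = "_")
    for (key in unique(gk)) {
      sub <- spots[gk == key, ]
      p <- file.path(directory,
                     paste0(sub$plate[1], "_", sub$well[1], "_spots_",
                            sub$channel[1], ".csv"))
      writeCommentedCsv(sub, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read and concatenate per-well flat tables
#'
#' @param directory Directory written by \code{\link{writeWellTables}}.
#' @return List with \code{nuclei} and \code{spots} data.frames (possibly
#'   empty), concatenated over all well files in deterministic (sorted
#'   filename) order.
#' @export
readWellTables <- function(directory) {
  nf <- sort(list.files(directory, pattern = "_nuclei\\.csv$",
                        full.names = TRUE))
  sf <- sort(list.files(directory, pattern = "_spots_[A-Za-z]+\\.csv$",
                        full.names = TRUE))
  nuclei <- if (length(nf)) do.call(rbind, lapply(nf, readCommentedCsv)) else
    NULL
  spots <- if (length(sf)) do.call(rbind, lapply(sf, readCommentedCsv)) else
    NULL
  if (!is.null(nuclei)) rownames(nuclei) <- NULL
  if (!is.null(spots)) rownames(spots) <- NULL
  list(nuclei = nuclei, spots = spots)
}
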