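# Calibrated two-channel TIFF I/O, tiling, and ROI selection.

.sidecarPath <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  else paste0(path, ".json")
}

#' Read / write a calibrated two-channel section
#'
#' Sections are stored as a two-page 8-bit grayscale TIFF (page 1 = SHG,
#' page 2 = TPEF) plus a JSON sidecar carrying the microns-per-pixel
#' calibration; the sidecar keeps the calibration dialect-proof and
#' bit-exact. The round trip is lossless on raster values and calibration.
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param path TIFF file path; the sidecar sits next to it with a
#'   \code{.json} extension.
#' @return \code{writeSection} returns \code{path} invisibly;
#'   \code{readSection} returns a \linkS4class{ChannelImage}.
#' @export
writeSection <- function(image, path) {
  stopifnot(is(image, "ChannelImage"))
  tiff::writeTIFF(list(shgChannel(image) / 255, tpefChannel(image) / 255),
                  path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size_um = pixelSize(image),
                            channels = c("SHG", "TPEF")),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSection
#' @export
readSection <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("calibration sidecar not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um) || !is.numeric(meta$pixel_size_um) ||
      meta$pixel_size_um <= 0)
    stop("sidecar is missing a positive pixel_size_um calibration")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop(sprintf("expected a two-page TIFF (SHG, TPEF); found %d page(s)",
                 length(pages)))
  shg <- round(pages[[1]] * 255)
  tpef <- round(pages[[2]] * 255)
  if (!identical(dim(shg), dim(tpef)))
    stop("TIFF pages have mismatched dimensions")
  ChannelImage(shg, tpef, meta$pixel_size_um)
}

#' Write / read a zone label raster
#'
#' Single-page 8-bit TIFF of zone codes with a JSON sidecar carrying the
#' calibration, band width and label legend.
#'
#' @param zoneMap a \linkS4class{ZoneMap}.
#' @param path TIFF file path.
#' @export
writeZoneMap <- function(zoneMap, path) {
  tiff::writeTIFF(zoneLabels(zoneMap) / 255, path, bits.per.sample = 8L)
  leg <- as.list(stats::setNames(names(.ZONE), .ZONE))
  jsonlite::write_json(list(pixel_size_um = zoneMap@pixelSize,
                            band_um = zoneMap@bandUm, legend = leg),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeZoneMap
#' @export
readZoneMap <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) stop("zone-map sidecar not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  lab <- round(tiff::readTIFF(path) * 255)
  storage.mode(lab) <- "integer"
  new("ZoneMap", labels = lab, pixelSize = meta$pixel_size_um,
      bandUm = meta$band_um, landmarks = data.frame())
}

#' Partition a section into square tiles
#'
#' Non-overlapping tiles of side \code{round(tileUm / pixelSize)} pixels
#' anchored at the image origin; partial tiles at the right/bottom edges
#' are discarded (padding would bias collagen percentages with dark
#' borders).
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param tileUm tile side in microns (default 200, so a 512 x 512 px tile
#'   at 0.390625 um/px spans one tile).
#' @return A \linkS4class{TileGrid}.
#' @export
tileSection <- function(image, tileUm = 200) {
  ps <- pixelSize(image)
  side <- as.integer(round(tileUm / ps))
  d <- dim(shgChannel(image))
  if (d[1] < side || d[2] < side)
    stop("image smaller than one tile")
  new("TileGrid", sidePx = side,
      nTileRow = as.integer(d[1] %/% side),
      nTileCol = as.integer(d[2] %/% side),
      pixelSize = ps, tileUm = tileUm)
}

#' Select regions of interest on a tile grid
#'
#' Candidate ROIs are 5 x 5-tile windows aligned on tile boundaries
#' (1 mm x 1 mm at the default tile size). Windows with tissue coverage
#' below \code{minTissueFraction} are discarded; the rest are taken
#' greedily by decreasing tissue fraction (ties by row then column index)
#' subject to pairwise disjointness, mimicking manual tissue-biased
#' placement, and finally thinned to \code{nRois} by a seeded uniform
#' draw. Per-slide statistics are reported as means over the selected
#' ROIs.
#'
#' @param grid a \linkS4class{TileGrid}.
#' @param nRois number of ROIs requested (typically 10--15 per slide).
#' @param tissue logical tissue mask at image resolution.
#' @param minTissueFraction minimum tissue coverage per ROI.
#' @param seed RNG seed for the thinning draw.
#' @return A \linkS4class{RoiSet}; when fewer qualifying disjoint windows
#'   exist than requested, all of them are returned with a warning and
#'   \code{complete = FALSE}.
#' @export
selectRois <- function(grid, nRois = 10, tissue, minTissueFraction = 0.6,
                       seed = 1) {
  side <- grid@sidePx
  k <- 5L
  nwr <- grid@nTileRow - k + 1L
  nwc <- grid@nTileCol - k + 1L
  empty <- data.frame(tileRow = integer(), tileCol = integer(),
                      row0 = integer(), col0 = integer(), sidePx = integer(),
                      tissueFraction = numeric())
  if (nwr < 1L || nwc < 1L) {
    warning("image too small for any 5x5-tile ROI window")
    return(new("RoiSet", windows = empty, tileUm = grid@tileUm,
               tilesPerSide = k, complete = FALSE))
  }
  # summed-area table for window tissue fractions
  sat <- apply(apply(tissue * 1, 2, cumsum), 1, cumsum)
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  winSum <- function(r0, c0, n) {
    r1 <- r0 + n; c1 <- c0 + n
    sat[r1 + 1L, c1 + 1L] - sat[r0 + 1L, c1 + 1L] -
      sat[r1 + 1L, c0 + 1L] + sat[r0 + 1L, c0 + 1L]
  }
  win <- expand.grid(tileRow = seq_len(nwr), tileCol = seq_len(nwc))
  wpx <- k * side
  win$row0 <- (win$tileRow - 1L) * side
  win$col0 <- (win$tileCol - 1L) * side
  win$tissueFraction <- mapply(function(r0, c0) winSum(r0, c0, wpx),
                               win$row0, win$col0) / wpx^2
  win <- win[win$tissueFraction >= minTissueFraction, , drop = FALSE]
  win <- win[order(-win$tissueFraction, win$tileRow, win$tileCol), ,
             drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(win))) {
    ok <- TRUE
    for (j in chosen) {
      if (abs(win$tileRow[i] - win$tileRow[j]) < k &&
          abs(win$tileCol[i] - win$tileCol[j]) < k) { ok <- FALSE; break }
    }
    if (ok) chosen <- c(chosen, i)
  }
  sel <- win[chosen, , drop = FALSE]
  complete <- nrow(sel) >= nRois
  if (!complete)
    warning(sprintf("only %d qualifying disjoint ROI windows (requested %d)",
                    nrow(sel), nRois))
  if (nrow(sel) > nRois)
    sel <- withSeed(seed, sel[sort(sample.int(nrow(sel), nRois)), ,
                              drop = FALSE])
  sel$sidePx <- rep(wpx, nrow(sel))
  rownames(sel) <- NULL
  new("RoiSet", windows = sel[, c("tileRow", "tileCol", "row0", "col0",
                                  "sidePx", "tissueFraction")],
      tileUm = grid@tileUm, tilesPerSide = k, complete = complete)
}

#' Crop one ROI out of a section
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param rois a \linkS4class{RoiSet}.
#' @param i ROI index.
#' @return A \linkS4class{ChannelImage} covering the ROI window.
#' @export
cropRoi <- function(image, rois, i) {
  w <- rois@windows[i, ]
  rr <- (w$row0 + 1L):(w$row0 + w$sidePx)
  cc <- (w$col0 + 1L):(w$col0 + w$sidePx)
  ChannelImage(shgChannel(image)[rr, cc], tpefChannel(image)[rr, cc],
               pixelSize(image))
}
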