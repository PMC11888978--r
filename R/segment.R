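# Tissue / collagen segmentation with SHG noise removal.

# Fill background components strictly smaller than maxPx that do not touch
# the image border (enclosed holes); larger holes are genuine cavities.
fillSmallHoles <- function(mask, maxPx) {
  l <- label8(!mask)
  n <- max(l)
  if (n == 0L) return(mask)
  border <- unique(c(l[1, ], l[nrow(l), ], l[, 1], l[, ncol(l)]))
  sz <- tabulate(l[l > 0L], n)
  fill <- setdiff(which(sz < maxPx), border)
  if (length(fill)) mask[matrix(l %in% fill, nrow(l), ncol(l))] <- TRUE
  mask
}

dropSmallComponents <- function(mask, minPx) {
  l <- label8(mask)
  n <- max(l)
  if (n == 0L) return(mask)
  sz <- tabulate(l[l > 0L], n)
  drop <- which(sz < minPx)
  if (length(drop)) mask[matrix(l %in% drop, nrow(l), ncol(l))] <- FALSE
  mask
}

#' Tissue mask from the TPEF channel
#'
#' Otsu-thresholds the (8-bit quantized) TPEF raster, fills enclosed holes
#' smaller than \code{maxHoleUm2} (intracellular dark spots; larger holes
#' are kept as candidate cavities) and removes foreground fragments smaller
#' than \code{minTissueUm2}.
#'
#' @param tpef numeric matrix, TPEF intensities.
#' @param pixelSizeUm microns per pixel.
#' @param maxHoleUm2 holes strictly smaller than this are filled.
#' @param minTissueUm2 foreground components strictly smaller are removed.
#' @return Logical matrix with attribute \code{threshold} (the Otsu level).
#' @export
tissueMask <- function(tpef, pixelSizeUm, maxHoleUm2 = 400,
                       minTissueUm2 = 10000) {
  t <- otsuThreshold(imageHistogram(tpef))
  fg <- quantize8(tpef) >= t
  px2 <- pixelSizeUm^2
  m <- fillSmallHoles(fg, maxHoleUm2 / px2)
  m <- dropSmallComponents(m, minTissueUm2 / px2)
  attr(m, "threshold") <- t
  m
}

#' Section support: tissue plus enclosed cavities
#'
#' Morphological closing of the tissue mask (bridging cavity mouths such as
#' cracks opening onto the section edge) followed by hole filling. This is
#' the raster on which cavities are detected and zones are assigned: lumens
#' and vacuoles belong to the section even though they are dark on TPEF.
#'
#' @param tissue logical tissue mask.
#' @param pixelSizeUm microns per pixel.
#' @param closeUm closing radius in microns.
#' @return Logical matrix.
#' @export
sectionSupport <- function(tissue, pixelSizeUm, closeUm = 15) {
  m <- matrix(as.numeric(tissue), nrow(tissue), ncol(tissue))
  rpx <- as.integer(round(closeUm / pixelSizeUm))
  if (rpx >= 1L) {
    brush <- EBImage::makeBrush(2L * rpx + 1L, "disc")
    m <- EBImage::closing(m, brush)
  }
  m <- EBImage::fillHull(m)
  matrix(as.numeric(EBImage::imageData(m)) > 0, nrow(tissue), ncol(tissue))
}

#' Collagen mask from the SHG channel
#'
#' Otsu-thresholds the SHG raster and removes noise: signal outside the
#' tissue mask (stray specks beyond the specimen) is discarded, as are
#' connected components smaller than \code{minFibrilUm2} (8-connected, so
#' thin diagonal fibrils survive).
#'
#' @param shg numeric matrix, SHG intensities.
#' @param tissue logical tissue mask from \code{\link{tissueMask}}.
#' @param pixelSizeUm microns per pixel.
#' @param minFibrilUm2 components strictly smaller are removed as noise.
#' @return Logical matrix (subset of \code{tissue}) with attribute
#'   \code{threshold}.
#' @export
collagenMask <- function(shg, tissue, pixelSizeUm, minFibrilUm2 = 5) {
  t <- otsuThreshold(imageHistogram(shg))
  m <- (quantize8(shg) >= t) & tissue
  m <- dropSmallComponents(m, minFibrilUm2 / pixelSizeUm^2)
  attr(m, "threshold") <- t
  m
}
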