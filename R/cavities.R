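# Detection of tissue cavities ("hollows") on the TPEF channel.

# Shoelace area of a point polygon (pixel centers).
.polyArea <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Detect tissue cavities with morphological features
#'
#' Deparaffinized lipid vacuoles, vessel and duct lumens, portal-tract and
#' central-vein lumens, and tissue cracks all appear as dark "hollows"
#' against the bright hepatocyte cytoplasm on TPEF. This finds connected
#' dark regions enclosed by the section support and computes, per object:
#' area, area-equivalent diameter, circularity \eqn{4\pi A/P^2} (chain-code
#' perimeter, Kulpa-corrected, clamped at the 1.05 discretization ceiling),
#' convex solidity, the fraction of a thin outer annulus covered by
#' collagen ("surrounding collagen"), and a border-contact flag. Objects
#' touching the image edge or the section boundary are flagged and are
#' never subsequently classified as vacuoles.
#'
#' @param tpef numeric matrix, TPEF intensities.
#' @param tissue logical tissue mask (\code{\link{tissueMask}}).
#' @param collagen logical collagen mask (\code{\link{collagenMask}}).
#' @param pixelSizeUm microns per pixel.
#' @param minCavityUm2 dark regions strictly smaller are ignored.
#' @param ringUm thickness of the outer collagen annulus in microns.
#' @param support optional precomputed \code{\link{sectionSupport}} raster.
#' @return A \linkS4class{CavitySet}.
#' @export
detectCavities <- function(tpef, tissue, collagen, pixelSizeUm,
                           minCavityUm2 = 15, ringUm = 5, support = NULL) {
  t <- otsuThreshold(imageHistogram(tpef))
  fg <- quantize8(tpef) >= t
  if (is.null(support)) support <- sectionSupport(tissue, pixelSizeUm)
  l <- label8(support & !fg)
  nr <- nrow(l); nc <- ncol(l)
  px2 <- pixelSizeUm^2
  n <- max(l)
  emptyTab <- data.frame(id = integer(), centroid_x_um = numeric(),
                         centroid_y_um = numeric(), area_um2 = numeric(),
                         equiv_diameter_um = numeric(), circularity = numeric(),
                         solidity = numeric(), collagen_ring_fraction = numeric(),
                         border_flag = logical())
  if (n == 0L)
    return(new("CavitySet", table = emptyTab, labels = l, pixelSize = pixelSizeUm))
  sz <- tabulate(l[l > 0L], n)
  keep <- which(sz * px2 >= minCavityUm2)
  map <- integer(n); map[keep] <- seq_along(keep)
  l[l > 0L] <- map[l[l > 0L]]
  k <- length(keep)
  if (k == 0L)
    return(new("CavitySet", table = emptyTab, labels = l, pixelSize = pixelSizeUm))

  perim <- contourPerimeters(l)
  # pixels adjacent (8-connected) to non-support background
  outside <- !support
  nearOut <- if (any(outside)) distToSet(outside, 1) <= 1.5 else
    matrix(FALSE, nr, nc)

  pos <- which(l > 0L)
  lab <- l[pos]
  rows <- (pos - 1L) %% nr + 1L
  cols <- (pos - 1L) %/% nr + 1L
  idx <- split(seq_along(pos), lab)
  ringPx <- ringUm / pixelSizeUm

  tab <- lapply(seq_len(k), function(i) {
    sel <- idx[[as.character(i)]]
    r <- rows[sel]; cc <- cols[sel]
    apx <- length(sel)
    P <- perim[i]
    circ <- min(1.05, 4 * pi * apx / P^2)
    # convex solidity; hull area corrected from pixel centers to pixel extents
    sol <- if (apx < 5L) 1 else {
      pts <- cbind(r, cc)
      h <- grDevices::chull(pts)
      hp <- pts[h, , drop = FALSE]
      hullA <- .polyArea(hp) + P / (2 * .KULPA) + 1
      min(1, apx / hullA)
    }
    border <- any(r == 1L | r == nr | cc == 1L | cc == nc) ||
      any(nearOut[cbind(r, cc)])
    # collagen coverage of the outer annulus, within a local window
    r0 <- max(1L, min(r) - as.integer(ceiling(ringPx)) - 2L)
    r1 <- min(nr, max(r) + as.integer(ceiling(ringPx)) + 2L)
    c0 <- max(1L, min(cc) - as.integer(ceiling(ringPx)) - 2L)
    c1 <- min(nc, max(cc) + as.integer(ceiling(ringPx)) + 2L)
    objw <- l[r0:r1, c0:c1, drop = FALSE] == i
    dw <- distToSet(objw, 1)
    ann <- dw > 0 & dw <= ringPx & support[r0:r1, c0:c1, drop = FALSE]
    ringFrac <- if (any(ann))
      sum(collagen[r0:r1, c0:c1, drop = FALSE][ann]) / sum(ann) else 0
    data.frame(id = i,
               centroid_x_um = pxToUm(mean(r), pixelSizeUm),
               centroid_y_um = pxToUm(mean(cc), pixelSizeUm),
               area_um2 = apx * px2,
               equiv_diameter_um = 2 * sqrt(apx * px2 / pi),
               circularity = circ, solidity = sol,
               collagen_ring_fraction = ringFrac, border_flag = border)
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  new("CavitySet", table = tab, labels = l, pixelSize = pixelSizeUm)
}
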