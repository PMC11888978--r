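# Internal raster and RNG helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic operations route their randomness through this so
# that no global state leaks between calls.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Quantize intensities to 8-bit levels 0..255 (clamped). All thresholding
# operates on this representation so the 256-bin histogram is exact.
quantize8 <- function(x) {
  q <- round(x)
  q[q < 0] <- 0
  q[q > 255] <- 255
  storage.mode(q) <- "integer"
  q
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# label adjacencies are merged with a union-find pass so thin diagonal
# fibrils stay connected.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  l <- EBImage::imageData(EBImage::bwlabel(m))
  l <- matrix(as.integer(l), nrow(m), ncol(m))
  n <- max(l)
  if (n <= 1L) return(l)
  nr <- nrow(l); nc <- ncol(l)
  a1 <- cbind(as.vector(l[-nr, -nc]), as.vector(l[-1, -1]))
  a2 <- cbind(as.vector(l[-nr, -1]), as.vector(l[-1, -nc]))
  pr <- rbind(a1, a2)
  pr <- pr[pr[, 1L] > 0L & pr[, 2L] > 0L & pr[, 1L] != pr[, 2L], , drop = FALSE]
  if (nrow(pr)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pr))) {
      a <- find(pr[k, 1L]); b <- find(pr[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    map <- match(root, sort(unique(root)))
    l[l > 0L] <- map[l[l > 0L]]
  }
  l
}

# Euclidean distance (in microns) from every pixel to the nearest TRUE pixel
# of `mask`; Inf when the mask is empty. EBImage::distmap is an exact
# Euclidean distance transform (verified against brute force in the tests).
distToSet <- function(mask, pixelSizeUm) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  matrix(as.numeric(EBImage::imageData(d)), nrow(mask), ncol(mask)) * pixelSizeUm
}

# Stamp a filled disc into a logical/integer matrix. Centers are fractional
# pixel coordinates (1-based matrix indexing), radius in pixels.
stampDisc <- function(mask, cx, cy, rpx, value = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, as.integer(floor(cx - rpx))); r1 <- min(nr, as.integer(ceiling(cx + rpx)))
  c0 <- max(1L, as.integer(floor(cy - rpx))); c1 <- min(nc, as.integer(ceiling(cy + rpx)))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  sub <- outer((rr - cx)^2, (cc - cy)^2, "+") <= rpx^2
  block <- mask[rr, cc, drop = FALSE]
  block[sub] <- value
  mask[rr, cc] <- block
  mask
}

# Digital perimeter of each labeled object: 8-connected chain-code contour
# length (EBImage::ocontour) with Kulpa's corrective coefficient, which
# removes the systematic overestimation of smooth boundaries.
.KULPA <- 0.9481
contourPerimeters <- function(labels) {
  oc <- EBImage::ocontour(labels)
  vapply(oc, function(p) {
    if (is.null(p) || nrow(p) < 3L) return(4)
    d <- rbind(diff(p), p[1L, ] - p[nrow(p), ])
    sum(sqrt(rowSums(d^2))) * .KULPA
  }, numeric(1))
}

# Convert between physical (micron) coordinates and 1-based pixel indices.
# Pixel centers sit at (i - 0.5) * pixelSizeUm.
umToPx <- function(u, pixelSizeUm) u / pixelSizeUm + 0.5
pxToUm <- function(i, pixelSizeUm) (i - 0.5) * pixelSizeUm

# Zone label codes shared by the generator and the analysis.
.ZONE <- c(background = 0L, PT = 1L, PP = 2L, TS = 3L, PC = 4L, CV = 5L)

#' Zone label codes
#'
#' Integer codes used in zone label rasters: 0 background, 1 portal tract
#' (PT), 2 periportal (PP), 3 transitional (TS), 4 pericentral (PC),
#' 5 central vein (CV).
#'
#' @return Named integer vector of length six.
#' @export
zoneCodes <- function() .ZONE
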