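#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the 8-bit threshold level maximizing the between-class variance
#' of the two-class split, the classic automatic threshold for bimodal
#' microscopy histograms. The background class is \code{level < t} and the
#' foreground \code{level >= t}; among equally good splits the lowest
#' qualifying level is returned.
#'
#' @param counts numeric vector of exactly 256 non-negative bin counts for
#'   levels 0..255.
#' @return Integer threshold level in 1..255; pixels with quantized level
#'   \code{>= t} are foreground.
#' @examples
#' h <- numeric(256); h[11] <- 50; h[201] <- 50  # levels 10 and 200
#' otsuThreshold(h)  # 11: lowest level separating the two spikes
#' @export
otsuThreshold <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 256L)
    stop("'counts' must have exactly 256 bins (levels 0..255)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("bin counts must be finite and non-negative")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: fewer than two populated intensity levels")
  lev <- 0:255
  total <- sum(counts)
  w0 <- cumsum(counts) / total
  m0 <- cumsum(lev * counts) / total
  mt <- m0[256L]
  # between-class variance for background = levels <= i-1 (threshold t = i)
  bcv <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  as.integer(which.max(bcv[1:255]))
}

# 256-bin histogram of an 8-bit-quantized raster.
imageHistogram <- function(x) tabulate(quantize8(x) + 1L, 256L)
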