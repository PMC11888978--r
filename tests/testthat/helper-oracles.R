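# Independent oracles and fixture builders used across the suite.

# Exhaustive-search Otsu: try every threshold, compute the between-class
# variance from first principles, return the lowest argmax.
bruteOtsu <- function(h) {
  tot <- sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- tot - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:(t - 1)) * h[1:t]) / w0
    mu1 <- sum((t:255) * h[(t + 1):256]) / w1
    v <- (w0 / tot) * (w1 / tot) * (mu0 - mu1)^2
    if (v > best + 1e-9 * max(best, 1)) { best <- v; bt <- t }
  }
  bt
}

# Per-pixel brute-force zone labeling: nearest-landmark-pixel distances
# computed by direct search (no distance transform).
bruteZones <- function(mask, ptMask, cvMask, bandUm, pixelSizeUm = 1) {
  n <- nrow(mask); m <- ncol(mask)
  pp <- which(ptMask, arr.ind = TRUE)
  cp <- which(cvMask, arr.ind = TRUE)
  z <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    if (ptMask[i, j]) { z[i, j] <- 1L; next }
    if (cvMask[i, j]) { z[i, j] <- 5L; next }
    dp <- if (nrow(pp)) sqrt(min((pp[, 1] - i)^2 + (pp[, 2] - j)^2)) * pixelSizeUm else Inf
    dc <- if (nrow(cp)) sqrt(min((cp[, 1] - i)^2 + (cp[, 2] - j)^2)) * pixelSizeUm else Inf
    z[i, j] <- if (dp <= bandUm && (dc > bandUm || dp <= dc)) 2L
      else if (dc <= bandUm) 4L else 3L
  }
  z
}

# Small (0.5 mm) section for fast unit tests.
smallSection <- function(profile = getProfile("PHx+Gln", 2), seed = 42, ...) {
  generateSection(profile, 0.5, 0.5, 1, seed = seed,
                  opts = sectionOptions(tissueMarginUm = 20, saltCount = 200,
                                        ...))
}

# Label detected cavities with their ground-truth class by matching to the
# planted geometry (landmark discs, vessel discs, vacuole mask, crack).
truthClasses <- function(section, cavities) {
  tab <- cavityTable(cavities)
  tr <- section$truth
  lm <- tr@landmarks
  ves <- tr@params$vessels
  vac <- tr@vacuoleMask
  vapply(seq_len(nrow(tab)), function(i) {
    x <- tab$centroid_x_um[i]; y <- tab$centroid_y_um[i]
    if (nrow(lm)) {
      d <- sqrt((lm$x_um - x)^2 + (lm$y_um - y)^2)
      j <- which.min(d)
      if (d[j] <= lm$radius_um[j] + 5)
        return(ifelse(lm$class[j] == "PT", "PT", "CV"))
    }
    if (!is.null(ves) && nrow(ves)) {
      d <- sqrt((ves$x_um - x)^2 + (ves$y_um - y)^2)
      if (min(d) <= ves$radius_um[which.min(d)] + 5) return("vessel_duct")
    }
    r <- round(x + 0.5); c <- round(y + 0.5)
    r <- min(max(r, 1), nrow(vac)); c <- min(max(c, 1), ncol(vac))
    if (vac[r, c]) return("vacuole")
    "crack"
  }, character(1))
}

# Minimal cavity feature row for rule-tree unit cases.
featureRow <- function(area_um2, circularity = 1, ring = 0, border = FALSE,
                       solidity = 1) {
  data.frame(id = 1L, centroid_x_um = 0, centroid_y_um = 0,
             area_um2 = area_um2,
             equiv_diameter_um = 2 * sqrt(area_um2 / pi),
             circularity = circularity, solidity = solidity,
             collagen_ring_fraction = ring, border_flag = border)
}

# Two-group, two-day null profiles (no group separation) for calibration.
nullProfiles <- function(sd = 2) {
  mk <- function(g, d) conditionProfile(g, d, endpointMeans = data.frame(
    endpoint = "pcna_pct", mean = 10 + d, sem = sd, n = 6))
  p <- list(mk("PHx+Gln", 2), mk("PHx+Gln", 4),
            mk("PHx-Gln", 2), mk("PHx-Gln", 4))
  names(p) <- c("PHx+Gln:D2", "PHx+Gln:D4", "PHx-Gln:D2", "PHx-Gln:D4")
  p
}
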