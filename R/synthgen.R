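# Synthetic two-channel liver-section generator with full ground truth.

#' Rendering options for the section generator
#'
#' Geometry, texture and noise parameters of \code{\link{generateSection}}.
#' Defaults: portal tracts render as dark lumen discs (radius 25 um)
#' wrapped in a dense collagen annulus; central veins as larger dark discs
#' (radius 40 um) without a dense ring; lipid vacuoles are log-normal
#' (median diameter 12 um, truncated to 5--40 um); hepatocyte sites sit on
#' a jittered hexagonal lattice at one site per 450 um^2 (area-equivalent
#' cell diameter 24 um); confounding vessels get a sparse collagen ring
#' and one crack per section opens onto the tissue edge; additive Gaussian
#' noise (sigma 5 of 255) on both channels plus bright salt specks outside
#' the tissue on SHG exercise the noise-removal steps.
#'
#' @param ... overrides of the defaults listed above.
#' @return Named list of options.
#' @export
sectionOptions <- function(...) {
  o <- list(
    ptRadiusUm = 25, cvRadiusUm = 40,
    ringWidthUm = 5, ptRingCoverage = 0.85, vesselRingCoverage = 0.35,
    vacuoleMedianUm = 12, vacuoleSdlog = 0.35,
    vacuoleMinUm = 5, vacuoleMaxUm = 40,
    cellAreaUm2 = 450, siteJitterUm = 2, siteClearanceUm = 1.5,
    gapUm = 2.7,
    tissueMarginUm = 30, minSepUm = 80, bandUm = 100,
    vesselsPerMm2 = 3, vesselRadiusUm = c(10, 18),
    nCracks = 1, crackWidthUm = 8, crackLengthUm = c(150, 300),
    fibrilSizeUm = 3,
    noiseSd = 5, saltCount = 600,
    tpefTissue = 180, tpefTexture = 12, tpefCavity = 25, tpefBackground = 8,
    shgBackground = 8, shgCollagen = 180, shgCollagenSd = 20, shgSalt = 220)
  dots <- list(...)
  bad <- setdiff(names(dots), names(o))
  if (length(bad)) stop("unknown section options: ", paste(bad, collapse = ", "))
  o[names(dots)] <- dots
  o
}

#' Plant non-overlapping circular landmarks
#'
#' Rejection-samples \code{ptCount} portal-tract and \code{cvCount}
#' central-vein landmark centers uniformly over a square field of
#' \code{areaMm2}, keeping centers at least \code{minSepUm} apart and away
#' from the field edge. Deterministic given the seed.
#'
#' @param areaMm2 field area in mm^2 (square field).
#' @param ptCount,cvCount landmark counts per class.
#' @param minSepUm minimum center-to-center separation in microns.
#' @param seed RNG seed.
#' @param ptRadiusUm,cvRadiusUm lumen radii in microns.
#' @param edgeMarginUm minimum center distance from the field edge
#'   (default: radius + 12 um, keeping the collagen annulus inside).
#' @param maxAttempts rejection-sampling attempts per landmark before a
#'   placement-infeasible error.
#' @return data.frame with columns class, x_um, y_um, radius_um.
#' @export
plantLandmarks <- function(areaMm2, ptCount, cvCount, minSepUm, seed = 1,
                           ptRadiusUm = 25, cvRadiusUm = 40,
                           edgeMarginUm = NULL, maxAttempts = 2000) {
  stopifnot(areaMm2 > 0, ptCount >= 0, cvCount >= 0, minSepUm > 0)
  side <- sqrt(areaMm2) * 1000
  cls <- c(rep("PT", ptCount), rep("CV", cvCount))
  rad <- c(rep(ptRadiusUm, ptCount), rep(cvRadiusUm, cvCount))
  n <- length(cls)
  if (n == 0L)
    return(data.frame(class = character(), x_um = numeric(),
                      y_um = numeric(), radius_um = numeric()))
  withSeed(seed, {
    xs <- ys <- numeric(0)
    for (k in seq_len(n)) {
      marg <- if (is.null(edgeMarginUm)) rad[k] + 12 else edgeMarginUm
      if (side - 2 * marg <= 0)
        stop("landmark placement infeasible: field smaller than margins")
      ok <- FALSE
      for (a in seq_len(maxAttempts)) {
        x <- stats::runif(1, marg, side - marg)
        y <- stats::runif(1, marg, side - marg)
        if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= minSepUm^2) {
          xs <- c(xs, x); ys <- c(ys, y); ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(paste0("landmark placement infeasible: could not place ",
                            "landmark %d of %d at %g um separation"),
                     k, n, minSepUm))
    }
    data.frame(class = cls, x_um = xs, y_um = ys, radius_um = rad)
  })
}

# Rejection-sample extra (non-landmark) structure centers against existing
# centers. Returns data.frame(x_um, y_um, radius_um); silently returns fewer
# if placement stalls (confounders, not a contract).
.placeExtra <- function(n, side, marginLo, marginHi, radii, minSepUm,
                        exX, exY, maxAttempts = 500) {
  xs <- ys <- rs <- numeric(0)
  for (k in seq_len(n)) {
    for (a in seq_len(maxAttempts)) {
      x <- stats::runif(1, marginLo, marginHi)
      y <- stats::runif(1, marginLo, marginHi)
      allX <- c(exX, xs); allY <- c(exY, ys)
      if (!length(allX) || min((allX - x)^2 + (allY - y)^2) >= minSepUm^2) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, radii[k])
        break
      }
    }
  }
  data.frame(x_um = xs, y_um = ys, radius_um = rs)
}

#' Generate a synthetic two-channel liver section
#'
#' Renders a calibrated SHG/TPEF image pair emulating a liver section under
#' one condition profile, together with the full ground truth for
#' parameter-recovery testing. The TPEF channel shows bright hepatocyte
#' cytoplasm with dark hollows for every planted structure (PT/CV lumens,
#' vessels, a crack opening onto the tissue edge, lipid vacuoles); lipid
#' vacuoles occupy a Bernoulli fraction of hepatocyte lattice sites equal
#' to the profile's steatotic fraction. The SHG channel renders collagen:
#' a dense annulus around each portal tract, a sparse ring around vessels
#' (and none around central veins), plus zonal fibril speckle whose total
#' areal fraction matches the profile's collagen total, allocated over the
#' true zone map (same 100 um band rule as the analysis) by the profile's
#' zone weights. Landmark counts are Poisson with the profile's densities
#' unless explicit \code{landmarks} are supplied.
#'
#' @param profile a \linkS4class{ConditionProfile}.
#' @param widthMm,heightMm field size in millimetres.
#' @param pixelSizeUm microns per pixel; must not exceed the smallest
#'   structure (the minimum vacuole diameter).
#' @param seed RNG seed; identical inputs give bit-identical output.
#' @param landmarks optional data.frame (class, x_um, y_um, radius_um)
#'   overriding Poisson landmark placement.
#' @param opts rendering options from \code{\link{sectionOptions}}.
#' @return \code{list(image = ChannelImage, truth = GroundTruth)}.
#' @export
generateSection <- function(profile, widthMm = 1, heightMm = 1,
                            pixelSizeUm = 1, seed = 1, landmarks = NULL,
                            opts = sectionOptions()) {
  if (widthMm <= 0 || heightMm <= 0) stop("section dimensions must be positive")
  if (pixelSizeUm <= 0) stop("pixel size must be positive")
  if (pixelSizeUm > opts$vacuoleMinUm)
    stop("pixel size larger than the smallest structure (minimum vacuole)")
  ps <- pixelSizeUm
  nr <- as.integer(round(widthMm * 1000 / ps))
  nc <- as.integer(round(heightMm * 1000 / ps))
  areaMm2 <- widthMm * heightMm

  withSeed(seed, {
    ## tissue geometry -----------------------------------------------------
    tissue <- matrix(TRUE, nr, nc)
    mpx <- as.integer(round(opts$tissueMarginUm / ps))
    if (mpx > 0L) {
      tissue[c(seq_len(mpx), nr - seq_len(mpx) + 1L), ] <- FALSE
      tissue[, c(seq_len(mpx), nc - seq_len(mpx) + 1L)] <- FALSE
    }
    sideX <- nr * ps; sideY <- nc * ps
    margin <- mpx * ps

    ## landmarks ------------------------------------------------------------
    if (is.null(landmarks)) {
      ptN <- stats::rpois(1, ptFociDensity(profile) * areaMm2)
      cvN <- stats::rpois(1, cvFociDensity(profile) * areaMm2)
      lmSeed <- stats::runif(1)  # keep stream position deterministic
      landmarks <- tryCatch(
        plantLandmarks(areaMm2, ptN, cvN, opts$minSepUm,
                       seed = as.integer(lmSeed * 1e8),
                       ptRadiusUm = opts$ptRadiusUm,
                       cvRadiusUm = opts$cvRadiusUm,
                       edgeMarginUm = margin + opts$cvRadiusUm + 12),
        error = function(e)
          plantLandmarks(areaMm2, max(0L, ptN - 2L), max(0L, cvN - 1L),
                         opts$minSepUm, seed = as.integer(lmSeed * 1e8),
                         ptRadiusUm = opts$ptRadiusUm,
                         cvRadiusUm = opts$cvRadiusUm,
                         edgeMarginUm = margin + opts$cvRadiusUm + 12))
    }
    landmarks <- as.data.frame(landmarks)

    ptMask <- matrix(FALSE, nr, nc)
    cvMask <- matrix(FALSE, nr, nc)
    if (nrow(landmarks)) {
      for (i in seq_len(nrow(landmarks))) {
        cx <- umToPx(landmarks$x_um[i], ps)
        cy <- umToPx(landmarks$y_um[i], ps)
        rpx <- landmarks$radius_um[i] / ps
        if (landmarks$class[i] == "PT") ptMask <- stampDisc(ptMask, cx, cy, rpx)
        else cvMask <- stampDisc(cvMask, cx, cy, rpx)
      }
    }

    ## confounders: vessels and a crack --------------------------------------
    nVes <- stats::rpois(1, opts$vesselsPerMm2 * areaMm2)
    vesselMask <- matrix(FALSE, nr, nc)
    vessels <- data.frame(x_um = numeric(), y_um = numeric(),
                          radius_um = numeric())
    if (nVes > 0L) {
      vr <- stats::runif(nVes, opts$vesselRadiusUm[1], opts$vesselRadiusUm[2])
      vessels <- .placeExtra(nVes, min(sideX, sideY),
                             margin + max(vr) + 12,
                             min(sideX, sideY) - margin - max(vr) - 12,
                             vr, opts$minSepUm,
                             landmarks$x_um, landmarks$y_um)
      for (i in seq_len(nrow(vessels)))
        vesselMask <- stampDisc(vesselMask, umToPx(vessels$x_um[i], ps),
                                umToPx(vessels$y_um[i], ps),
                                vessels$radius_um[i] / ps)
    }
    crackMask <- matrix(FALSE, nr, nc)
    for (k in seq_len(opts$nCracks)) {
      edge <- sample.int(4L, 1L)
      u <- stats::runif(1, 0.25, 0.75)
      start <- switch(edge,
                      c(margin, margin + u * (sideY - 2 * margin)),
                      c(sideX - margin, margin + u * (sideY - 2 * margin)),
                      c(margin + u * (sideX - 2 * margin), margin),
                      c(margin + u * (sideX - 2 * margin), sideY - margin))
      inward <- switch(edge, 0, pi, pi / 2, -pi / 2)
      ang <- inward + stats::runif(1, -0.6, 0.6)
      len <- stats::runif(1, opts$crackLengthUm[1], opts$crackLengthUm[2])
      tt <- seq(0, len, by = ps / 2)
      wpx <- opts$crackWidthUm / 2 / ps
      for (t in tt)
        crackMask <- stampDisc(crackMask,
                               umToPx(start[1] + t * cos(ang), ps),
                               umToPx(start[2] + t * sin(ang), ps), wpx)
    }
    # keep a bright gap between the crack and other structures so they
    # stay separate objects under 8-connected labeling
    otherStruct <- ptMask | cvMask | vesselMask
    if (any(crackMask) && any(otherStruct))
      crackMask <- crackMask & (distToSet(otherStruct, ps) > opts$gapUm)
    crackMask <- crackMask & tissue
    struct <- ptMask | cvMask | vesselMask | crackMask

    ## true zone map (shared band geometry) ----------------------------------
    zmTrue <- zoneMapCore(tissue, ptMask & tissue, cvMask & tissue, ps,
                          opts$bandUm, landmarks)
    zl <- zoneLabels(zmTrue)

    ## hepatocyte lattice and lipid vacuoles ---------------------------------
    s <- sqrt(opts$cellAreaUm2 / (sqrt(3) / 2))   # hex spacing, um
    dy <- s * sqrt(3) / 2
    jrow <- seq(0, sideX + s, by = dy)
    # clearance from structural cavities and from the tissue boundary, so
    # vacuoles never merge with either
    dStruct <- distToSet(struct | !tissue, ps)
    siteR <- siteC <- integer(0)
    for (j in seq_along(jrow)) {
      xr <- jrow[j]
      off <- if (j %% 2 == 0) s / 2 else 0
      yy <- seq(off, sideY + s, by = s)
      xx <- rep(xr, length(yy))
      xx <- xx + stats::rnorm(length(xx), 0, opts$siteJitterUm)
      yy <- yy + stats::rnorm(length(yy), 0, opts$siteJitterUm)
      rI <- as.integer(round(umToPx(xx, ps)))
      cI <- as.integer(round(umToPx(yy, ps)))
      keep <- rI >= 1L & rI <= nr & cI >= 1L & cI <= nc
      rI <- rI[keep]; cI <- cI[keep]
      keep2 <- tissue[cbind(rI, cI)] & dStruct[cbind(rI, cI)] > opts$siteClearanceUm
      siteR <- c(siteR, rI[keep2]); siteC <- c(siteC, cI[keep2])
    }
    nSites <- length(siteR)
    sf <- steatoticFraction(profile)
    vacMask <- matrix(FALSE, nr, nc)
    vacDiam <- numeric(0)
    if (nSites > 0L && sf > 0) {
      isVac <- stats::runif(nSites) < sf
      nVac <- sum(isVac)
      if (nVac > 0L) {
        d <- stats::rlnorm(nVac, log(opts$vacuoleMedianUm), opts$vacuoleSdlog)
        for (rep in 1:20) {
          bad <- d < opts$vacuoleMinUm | d > opts$vacuoleMaxUm
          if (!any(bad)) break
          d[bad] <- stats::rlnorm(sum(bad), log(opts$vacuoleMedianUm),
                                  opts$vacuoleSdlog)
        }
        d <- pmin(pmax(d, opts$vacuoleMinUm), opts$vacuoleMaxUm)
        vr <- siteR[isVac]; vc <- siteC[isVac]
        # a steatotic site boxed in against a structure or the tissue edge
        # is nudged up the clearance gradient (still within its own cell
        # footprint) so its vacuole renders with a clean bright gap and the
        # one-vacuole-one-cavity mapping stays exact
        gap <- opts$gapUm
        needClear <- opts$vacuoleMinUm / 2 + gap
        for (i in seq_len(nVac)) {
          steps <- 0L
          while (dStruct[vr[i], vc[i]] < needClear && steps < 10L) {
            nb <- expand.grid(r = vr[i] + (-1:1), c = vc[i] + (-1:1))
            nb <- nb[nb$r >= 1 & nb$r <= nr & nb$c >= 1 & nb$c <= nc, ]
            j <- which.max(dStruct[cbind(nb$r, nb$c)])
            if (dStruct[nb$r[j], nb$c[j]] <= dStruct[vr[i], vc[i]]) break
            vr[i] <- nb$r[j]; vc[i] <- nb$c[j]
            steps <- steps + 1L
          }
        }
        clear <- dStruct[cbind(vr, vc)]
        # cap radii so neighboring vacuoles stay disjoint under 8-connected
        # labeling (count recovery: one planted vacuole, one detected cavity)
        nnHalf <- rep(Inf, nVac)
        if (nVac > 1L) {
          dm <- as.matrix(stats::dist(cbind(vr, vc) * ps))
          diag(dm) <- Inf
          nnHalf <- apply(dm, 1, min) / 2 - gap / 2
        }
        rads <- pmax(opts$vacuoleMinUm / 2,
                     pmin(d / 2, clear - gap, nnHalf))
        for (i in seq_len(nVac))
          vacMask <- stampDisc(vacMask, vr[i], vc[i], rads[i] / ps)
        vacDiam <- 2 * rads
      }
    } else {
      nVac <- 0L
    }
    nVac <- if (exists("isVac", inherits = FALSE)) sum(isVac) else 0L
    vacMask <- vacMask & tissue & !struct

    ## collagen truth ---------------------------------------------------------
    collagen <- matrix(FALSE, nr, nc)
    ringBand <- function(maskIn, coverage) {
      d <- distToSet(maskIn, ps)
      ring <- d > 0 & d <= opts$ringWidthUm & tissue & !struct & !vacMask
      ring[ring] <- stats::runif(sum(ring)) < coverage
      ring
    }
    if (any(ptMask)) collagen <- collagen | ringBand(ptMask, opts$ptRingCoverage)
    if (any(vesselMask))
      collagen <- collagen | ringBand(vesselMask, opts$vesselRingCoverage)

    total <- collagenTotal(profile)
    w <- collagenZoneWeights(profile)
    tissuePx <- sum(tissue)
    fibPx <- max(1L, as.integer(round(opts$fibrilSizeUm / ps)))
    blockPx <- fibPx^2
    if (!is.na(total) && total > 0) {
      stampFibrils <- function(collagen, zoneCode, nf) {
        elig <- tissue & !struct & !vacMask & !collagen & zl == zoneCode
        zelig <- which(elig)
        if (!length(zelig) || nf < 1L) return(collagen)
        centers <- zelig[sample.int(length(zelig), min(nf, length(zelig)))]
        half <- (fibPx - 1L) %/% 2L
        fib <- matrix(FALSE, nr, nc)
        cR <- (centers - 1L) %% nr + 1L
        cC <- (centers - 1L) %/% nr + 1L
        for (i in seq_along(centers)) {
          r0 <- max(1L, cR[i] - half); r1 <- min(nr, cR[i] - half + fibPx - 1L)
          c0 <- max(1L, cC[i] - half); c1 <- min(nc, cC[i] - half + fibPx - 1L)
          fib[r0:r1, c0:c1] <- TRUE
        }
        collagen | (fib & elig)
      }
      # allocate by zone weights, then top up: block overlap and zone-edge
      # clipping lose area, so re-stamp until the planted total matches the
      # profile target
      for (pass in 1:5) {
        remaining <- total * tissuePx - sum(collagen)
        if (remaining < blockPx) break
        # renormalize weights over zones that can actually host fibrils
        # (lumen-zone pixels are structural; sections may lack PT or CV)
        hosts <- vapply(names(.ZONE)[-1], function(zn)
          w[[zn]] > 0 && any(tissue & !struct & !vacMask & !collagen &
                               zl == .ZONE[[zn]]), logical(1))
        if (!any(hosts)) break
        wz <- w[hosts] / sum(w[hosts])
        for (zn in names(wz))
          collagen <- stampFibrils(collagen, .ZONE[[zn]],
                                   as.integer(round(remaining * wz[[zn]] /
                                                      blockPx)))
      }
    }

    ## render TPEF ------------------------------------------------------------
    tp <- matrix(opts$tpefBackground, nr, nc)
    tp[tissue] <- opts$tpefTissue +
      stats::rnorm(sum(tissue), 0, opts$tpefTexture)
    tp[struct | vacMask] <- opts$tpefCavity
    tp <- tp + stats::rnorm(nr * nc, 0, opts$noiseSd)
    tp <- quantize8(tp)

    ## render SHG -------------------------------------------------------------
    sh <- matrix(opts$shgBackground, nr, nc)
    sh[collagen] <- opts$shgCollagen +
      stats::rnorm(sum(collagen), 0, opts$shgCollagenSd)
    bgIdx <- which(!tissue)
    nsalt <- min(opts$saltCount, length(bgIdx))
    if (nsalt > 0L)
      sh[bgIdx[sample.int(length(bgIdx), nsalt)]] <- opts$shgSalt
    sh <- sh + stats::rnorm(nr * nc, 0, opts$noiseSd)
    sh <- quantize8(sh)

    ## ground truth -----------------------------------------------------------
    zoneCnt <- tabulate(zl[zl > 0L], 5L)
    collCnt <- vapply(1:5, function(z) sum(collagen & zl == z), numeric(1))
    zonalDensity <- stats::setNames(
      ifelse(zoneCnt > 0, collCnt / zoneCnt, NA_real_), names(.ZONE)[-1])
    truth <- new("GroundTruth",
                 landmarks = landmarks,
                 vacuoleMask = vacMask, collagenMask = collagen,
                 zoneMapTrue = zl,
                 params = list(
                   ptCount = sum(landmarks$class == "PT"),
                   cvCount = sum(landmarks$class == "CV"),
                   nVessels = nrow(vessels), vessels = vessels,
                   nCracks = opts$nCracks,
                   nSites = nSites, nVacuoles = nVac,
                   steatoticFraction = if (nSites > 0) nVac / nSites else 0,
                   vacuoleDiametersUm = vacDiam,
                   targetCollagenFraction = total,
                   realizedCollagenFraction = sum(collagen) / tissuePx,
                   zonalCollagenDensity = zonalDensity,
                   tissueAreaMm2 = tissuePx * ps^2 / 1e6,
                   seed = seed))
    list(image = ChannelImage(sh, tp, ps), truth = truth)
  })
}

#' Representative day-4 PHx+Gln section (fixture recipe)
#'
#' Renders the package's bundled representative section for the
#' glutamine-supplemented hepatectomy arm at day 4: a 1 mm x 1 mm
#' full-tissue field with exactly 5 portal tracts and 2 central veins
#' planted at >= 150 um separation under a fixed seed, matching the
#' representative foci densities (5 PT and 2 CV per mm^2). The recipe
#' parameters are also stored as JSON under
#' \code{system.file("extdata", "representative_d4.json", package = "hepzone")}.
#'
#' @param seed fixed recipe seed.
#' @return \code{list(image, truth)} as \code{\link{generateSection}}.
#' @export
representativeSection <- function(seed = 4L) {
  prof <- getProfile("PHx+Gln", 4)
  lm <- plantLandmarks(1, 5, 2, minSepUm = 150, seed = seed)
  generateSection(prof, 1, 1, 1, seed = seed + 1000L, landmarks = lm,
                  opts = sectionOptions(tissueMarginUm = 0, saltCount = 0))
}
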