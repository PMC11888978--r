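# Zone-wise collagen, steatosis, and foci-density readouts.

#' Quantify collagen by acinar zone
#'
#' Exact pixel-count collagen quantification over the five-zone map: the
#' share of total collagen falling in each zone, the within-zone areal
#' density (collagen pixels / zone pixels), and the total collagen areal
#' fraction of tissue.
#'
#' @param collagen logical collagen mask.
#' @param zoneMap a \linkS4class{ZoneMap} with matching dimensions.
#' @return A \linkS4class{ZoneCollagenProfile}; with an empty collagen
#'   mask all shares are zero and \code{defined} is FALSE.
#' @export
collagenByZone <- function(collagen, zoneMap) {
  zl <- zoneLabels(zoneMap)
  if (!identical(dim(collagen), dim(zl)))
    stop("collagen mask and zone map dimensions differ")
  zones <- names(.ZONE)[-1]
  collCnt <- vapply(1:5, function(z) sum(collagen & zl == z), numeric(1))
  zoneCnt <- tabulate(zl[zl > 0L], 5L)
  total <- sum(collCnt)
  defined <- total > 0
  shares <- stats::setNames(if (defined) collCnt / total else rep(0, 5), zones)
  densities <- stats::setNames(
    ifelse(zoneCnt > 0, collCnt / zoneCnt, NA_real_), zones)
  tissuePx <- sum(zoneCnt)
  new("ZoneCollagenProfile", shares = shares, densities = densities,
      totalFraction = if (tissuePx > 0) total / tissuePx else 0,
      defined = defined)
}

#' Group ratio of collagen deposition
#'
#' Ratio of group means of the total collagen areal fraction (or of one
#' zone's areal density), the form in which group contrasts of ECM
#' collagen are reported.
#'
#' @param groupA,groupB lists of \linkS4class{ZoneCollagenProfile}.
#' @param zone \code{"total"} or one of \code{"PT","PP","TS","PC","CV"}.
#' @return Scalar ratio mean(A)/mean(B).
#' @export
collagenRatio <- function(groupA, groupB, zone = "total") {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  f <- function(p) {
    stopifnot(is(p, "ZoneCollagenProfile"))
    if (zone == "total") p@totalFraction else p@densities[[zone]]
  }
  a <- mean(vapply(groupA, f, numeric(1)))
  b <- mean(vapply(groupB, f, numeric(1)))
  if (!is.finite(b) || b == 0) stop("zero denominator group mean")
  a / b
}

#' Steatotic-hepatocyte fraction
#'
#' Steatotic hepatocytes are counted as vacuole-class cavity objects (one
#' vacuole, one steatotic hepatocyte; vacuoles merged by connectivity
#' count once). The total hepatocyte denominator is an area quotient:
#' hepatocyte-occupiable tissue (the section support minus non-vacuole
#' cavity pixels; a steatotic cell's own vacuole still occupies its cell
#' footprint) divided by the nominal single-cell area.
#'
#' @param cavities a classified \linkS4class{CavitySet}.
#' @param support logical section-support mask.
#' @param pixelSizeUm microns per pixel.
#' @param cellAreaUm2 nominal hepatocyte area (default 450 um^2, an
#'   area-equivalent cell diameter of 24 um).
#' @return A \linkS4class{SteatosisResult} with the fraction clipped to
#'   [0, 1] and vacuole size statistics.
#' @export
steatosis <- function(cavities, support, pixelSizeUm, cellAreaUm2 = 450) {
  if (cellAreaUm2 <= 0) stop("nominal cell area must be positive")
  tab <- cavityTable(cavities)
  if (nrow(tab) && !"class" %in% names(tab))
    stop("classify cavities before quantifying steatosis")
  px2 <- pixelSizeUm^2
  l <- cavityLabels(cavities)
  n <- max(0L, l)
  vacIds <- if (nrow(tab)) tab$id[tab$class == "vacuole"] else integer(0)
  otherIds <- if (nrow(tab)) setdiff(tab$id, vacIds) else integer(0)
  sz <- if (n > 0L) tabulate(l[l > 0L], n) else integer(0)
  otherPx <- if (length(otherIds)) sum(sz[otherIds]) else 0
  occupiable <- (sum(support) - otherPx) * px2
  totalHep <- occupiable / cellAreaUm2
  nVac <- length(vacIds)
  frac <- if (totalHep > 0) min(1, nVac / totalHep) else 0
  dia <- if (nVac) tab$equiv_diameter_um[tab$class == "vacuole"] else numeric(0)
  new("SteatosisResult", fraction = frac, nVacuoles = as.integer(nVac),
      totalHepatocytes = totalHep,
      medianDiameterUm = if (nVac) stats::median(dia) else NA_real_,
      iqrDiameterUm = if (nVac)
        unname(diff(stats::quantile(dia, c(0.25, 0.75)))) else NA_real_)
}

#' Portal-tract and central-vein foci density
#'
#' Counts of PT-class and CV-class objects per square millimetre of
#' tissue, the structural-remodeling readout.
#'
#' @param x a classified \linkS4class{CavitySet}, or a data.frame with a
#'   \code{class} column (e.g. a planted landmark list).
#' @param tissueAreaMm2 tissue area in mm^2 (must be positive).
#' @return A \linkS4class{FociDensity}.
#' @export
fociDensity <- function(x, tissueAreaMm2) {
  if (!is.numeric(tissueAreaMm2) || tissueAreaMm2 <= 0)
    stop("tissue area must be positive")
  tab <- if (is(x, "CavitySet")) cavityTable(x) else as.data.frame(x)
  if (nrow(tab) && !"class" %in% names(tab))
    stop("objects must carry a class column")
  nPt <- sum(tab$class == "PT")
  nCv <- sum(tab$class == "CV")
  new("FociDensity", ptPerMm2 = nPt / tissueAreaMm2,
      cvPerMm2 = nCv / tissueAreaMm2, tissueAreaMm2 = tissueAreaMm2)
}
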