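#' @import methods
NULL

#' Calibrated two-channel SHG/TPEF section image
#'
#' Container for a registered pair of rasters from second harmonic
#' generation (SHG, fibrillar collagen) and two-photon excitation
#' fluorescence (TPEF, parenchymal autofluorescence) imaging of a liver
#' section, with the microns-per-pixel calibration. Intensities are stored
#' as 8-bit levels (0--255); pixel centers sit at \code{(i - 0.5) *
#' pixelSize} microns, row-major.
#'
#' @slot shg numeric matrix, SHG channel (collagen signal).
#' @slot tpef numeric matrix, TPEF channel (tissue autofluorescence).
#' @slot pixelSize positive scalar, microns per pixel.
#' @export
setClass("ChannelImage",
  representation(shg = "matrix", tpef = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@shg), dim(object@tpef)))
      msg <- c(msg, "SHG and TPEF rasters must have identical dimensions")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive finite scalar")
    rng <- range(object@shg, object@tpef)
    if (rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "intensities must lie in [0, 255]")
    if (is.null(msg)) TRUE else msg
  })

#' @param shg,tpef numeric matrices with identical dimensions (8-bit levels).
#' @param pixelSizeUm microns per pixel.
#' @rdname ChannelImage-class
#' @export
ChannelImage <- function(shg, tpef, pixelSizeUm) {
  new("ChannelImage", shg = quantize8(shg) * 1, tpef = quantize8(tpef) * 1,
      pixelSize = as.numeric(pixelSizeUm))
}

#' Group-by-day condition profile
#'
#' Ground-truth parameter set for one experimental condition (surgery/
#' supplementation group at a post-operative day): steatotic hepatocyte
#' fraction, portal-tract and central-vein foci densities, total collagen
#' areal fraction with its zonal allocation weights, and the longitudinal
#' endpoint means (mean, SEM, n) used by the cohort simulator.
#'
#' Collagen is parameterized as a total areal fraction plus zonal share
#' weights rather than absolute per-zone densities: group contrasts are
#' reported as ratios of totals, which this parameterization keeps invariant
#' to the realized landmark geometry. The per-zone areal densities actually
#' planted in a section are recorded in its \linkS4class{GroundTruth}.
#'
#' @slot group character, one of \code{"sham+Gln"}, \code{"sham-Gln"},
#'   \code{"PHx+Gln"}, \code{"PHx-Gln"}.
#' @slot day integer post-operative day, 0--6.
#' @slot steatoticFraction proportion of hepatocytes bearing a lipid
#'   vacuole, in [0, 1].
#' @slot ptFociDensity,cvFociDensity expected foci per square millimetre.
#' @slot collagenTotal total collagen areal fraction of tissue, in [0, 1].
#' @slot collagenZoneWeights named non-negative weights over
#'   \code{c("PT","PP","TS","PC","CV")} summing to 1.
#' @slot endpointMeans data.frame with columns endpoint, mean, sem, n
#'   (NA mean = endpoint not defined for this condition).
#' @export
setClass("ConditionProfile",
  representation(group = "character", day = "integer",
                 steatoticFraction = "numeric",
                 ptFociDensity = "numeric", cvFociDensity = "numeric",
                 collagenTotal = "numeric", collagenZoneWeights = "numeric",
                 endpointMeans = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!object@group %in% c("sham+Gln", "sham-Gln", "PHx+Gln", "PHx-Gln"))
      msg <- c(msg, "unknown group")
    if (object@day < 0L || object@day > 6L)
      msg <- c(msg, "day must be in 0..6")
    if (is.na(object@steatoticFraction) || object@steatoticFraction < 0 ||
        object@steatoticFraction > 1)
      msg <- c(msg, "steatoticFraction must be in [0, 1]")
    if (object@ptFociDensity < 0 || object@cvFociDensity < 0)
      msg <- c(msg, "foci densities must be non-negative")
    if (!is.na(object@collagenTotal) &&
        (object@collagenTotal < 0 || object@collagenTotal > 1))
      msg <- c(msg, "collagenTotal must be in [0, 1]")
    w <- object@collagenZoneWeights
    if (length(w) != 5L || !setequal(names(w), c("PT", "PP", "TS", "PC", "CV")))
      msg <- c(msg, "collagenZoneWeights must be named over the five zones")
    else if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, "collagenZoneWeights must be non-negative and sum to 1")
    em <- object@endpointMeans
    if (!all(c("endpoint", "mean", "sem", "n") %in% names(em)))
      msg <- c(msg, "endpointMeans needs columns endpoint, mean, sem, n")
    else if (any(!is.na(em$n) & em$n < 1))
      msg <- c(msg, "endpoint n must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Generator ground truth for one synthetic section
#'
#' Everything the synthetic section generator planted, for parameter-recovery
#' testing: the landmark list (class, center, radius), the lipid-vacuole and
#' collagen masks, the true five-zone label raster (built with the same
#' 100 micron band rule the analysis uses), and the realized parameters.
#'
#' @slot landmarks data.frame with columns class ("PT"/"CV"), x_um, y_um,
#'   radius_um.
#' @slot vacuoleMask,collagenMask logical matrices, image dimensions.
#' @slot zoneMapTrue integer matrix of zone codes (see \code{\link{zoneCodes}}).
#' @slot params list of realized values (counts, steatotic fraction,
#'   per-zone collagen densities, ...).
#' @export
setClass("GroundTruth",
  representation(landmarks = "data.frame", vacuoleMask = "matrix",
                 collagenMask = "matrix", zoneMapTrue = "matrix",
                 params = "list"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@vacuoleMask), dim(object@collagenMask)) ||
        !identical(dim(object@vacuoleMask), dim(object@zoneMapTrue)))
      msg <- c(msg, "ground-truth masks must share dimensions")
    lm <- object@landmarks
    if (nrow(lm) && !all(c("class", "x_um", "y_um", "radius_um") %in% names(lm)))
      msg <- c(msg, "landmarks need columns class, x_um, y_um, radius_um")
    p <- object@params
    if (!is.null(p$ptCount) && nrow(lm) &&
        p$ptCount != sum(lm$class == "PT"))
      msg <- c(msg, "realized PT count must equal number of PT landmarks")
    if (!is.null(p$cvCount) && nrow(lm) &&
        p$cvCount != sum(lm$class == "CV"))
      msg <- c(msg, "realized CV count must equal number of CV landmarks")
    if (is.null(msg)) TRUE else msg
  })

#' Tissue and collagen segmentation masks
#'
#' Otsu-derived masks for one section: the TPEF tissue foreground (small
#' holes filled, small components removed), the SHG collagen mask restricted
#' to tissue with sub-fibril noise removed, and the section support (tissue
#' closure with enclosed cavities filled) on which zonation and cavity
#' detection operate.
#'
#' @slot tissue,collagen,support logical matrices.
#' @slot thresholds named numeric, 8-bit Otsu levels for (tpef, shg).
#' @slot pixelSize microns per pixel.
#' @export
setClass("TissueMasks",
  representation(tissue = "matrix", collagen = "matrix", support = "matrix",
                 thresholds = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@tissue), dim(object@collagen)))
      msg <- c(msg, "masks must share dimensions")
    if (any(object@collagen & !object@tissue))
      msg <- c(msg, "collagen mask must be a subset of the tissue mask")
    if (is.null(msg)) TRUE else msg
  })

#' Five-zone acinar label map
#'
#' Per-pixel partition of the section support into portal tract (PT),
#' periportal (PP), transitional (TS), pericentral (PC) and central vein
#' (CV) zones, with non-tissue pixels labeled background. PP/PC are the
#' bands within \code{bandUm} (Euclidean distance from the landmark object
#' boundary) of any PT/CV; overlaps go to the nearer landmark class with
#' exact ties periportal.
#'
#' @slot labels integer matrix of zone codes (see \code{\link{zoneCodes}}).
#' @slot pixelSize microns per pixel.
#' @slot bandUm band width in microns (default analysis uses 100).
#' @slot landmarks data.frame recording landmark provenance.
#' @export
setClass("ZoneMap",
  representation(labels = "matrix", pixelSize = "numeric", bandUm = "numeric",
                 landmarks = "data.frame"),
  validity = function(object) {
    if (!all(object@labels %in% 0:5))
      "zone labels must be integer codes 0..5" else TRUE
  })

#' Detected tissue cavities with morphological features
#'
#' Result of cavity ("hollow") detection on the TPEF channel: a feature
#' table (one row per cavity) and the matching integer label raster. After
#' classification the table gains a \code{class} column over
#' \{PT, CV, vessel_duct, crack, vacuole\}.
#'
#' @slot table data.frame of per-object features: id, centroid_x_um,
#'   centroid_y_um, area_um2, equiv_diameter_um, circularity, solidity,
#'   collagen_ring_fraction, border_flag (and class once classified).
#' @slot labels integer matrix; 0 = not a cavity, k = cavity id k.
#' @slot pixelSize microns per pixel.
#' @export
setClass("CavitySet",
  representation(table = "data.frame", labels = "matrix",
                 pixelSize = "numeric"),
  validity = function(object) {
    n <- max(0L, object@labels)
    if (nrow(object@table) != n)
      "cavity table rows must match label raster ids" else TRUE
  })

#' Decision tree for cavity classification
#'
#' Binary decision tree over cavity features assigning one of the classes
#' PT, CV, vessel_duct, crack, vacuole. Either the inspectable rule-based
#' default (\code{\link{defaultClassTree}}) or a CART fit trained on labeled
#' objects (\code{\link{fitTree}}).
#'
#' @slot kind "rules" or "rpart".
#' @slot root nested node list for rule trees: \code{list(feature,
#'   threshold, left, right)} with left taken when value < threshold;
#'   leaves are \code{list(leaf = class)}.
#' @slot fit the rpart fit for trained trees (NULL otherwise).
#' @slot classes character vector of reachable class labels.
#' @export
setClass("ObjectClassTree",
  representation(kind = "character", root = "list", fit = "ANY",
                 classes = "character"),
  validity = function(object) {
    if (!object@kind %in% c("rules", "rpart")) "kind must be rules or rpart"
    else TRUE
  })

#' Grid of square analysis tiles
#'
#' Non-overlapping square tiles (default 200 x 200 microns) covering a
#' section; partial edge tiles are discarded.
#'
#' @slot sidePx tile side in pixels.
#' @slot nTileRow,nTileCol tile grid dimensions.
#' @slot pixelSize microns per pixel.
#' @slot tileUm nominal tile side in microns.
#' @export
setClass("TileGrid",
  representation(sidePx = "integer", nTileRow = "integer", nTileCol = "integer",
                 pixelSize = "numeric", tileUm = "numeric"))

#' Selected regions of interest
#'
#' A set of pairwise-disjoint 5 x 5-tile windows (1 mm x 1 mm at the default
#' tile size), selected greedily by tissue coverage; per-slide statistics
#' are reported as means over these ROIs.
#'
#' @slot windows data.frame: tileRow, tileCol, row0, col0, sidePx,
#'   tissueFraction.
#' @slot tileUm tile side in microns.
#' @slot tilesPerSide tiles per ROI side (5).
#' @slot complete FALSE when fewer qualifying windows existed than requested.
#' @export
setClass("RoiSet",
  representation(windows = "data.frame", tileUm = "numeric",
                 tilesPerSide = "integer", complete = "logical"))

#' Zone-wise collagen quantification
#'
#' @slot shares named numeric: fraction of total collagen pixels in each
#'   zone (sums to 1 when any collagen exists).
#' @slot densities named numeric: collagen pixels / zone pixels per zone.
#' @slot totalFraction collagen pixels / tissue pixels.
#' @slot defined FALSE when the collagen mask was empty (shares undefined).
#' @export
setClass("ZoneCollagenProfile",
  representation(shares = "numeric", densities = "numeric",
                 totalFraction = "numeric", defined = "logical"))

#' Steatosis quantification result
#'
#' @slot fraction steatotic hepatocytes / total hepatocytes, in [0, 1].
#' @slot nVacuoles number of vacuole-class objects.
#' @slot totalHepatocytes estimated hepatocyte count (area quotient).
#' @slot medianDiameterUm,iqrDiameterUm vacuole size statistics (microns).
#' @export
setClass("SteatosisResult",
  representation(fraction = "numeric", nVacuoles = "integer",
                 totalHepatocytes = "numeric", medianDiameterUm = "numeric",
                 iqrDiameterUm = "numeric"))

#' Portal-tract / central-vein foci density
#'
#' @slot ptPerMm2,cvPerMm2 foci counts per square millimetre of tissue.
#' @slot tissueAreaMm2 tissue area used as the denominator.
#' @export
setClass("FociDensity",
  representation(ptPerMm2 = "numeric", cvPerMm2 = "numeric",
                 tissueAreaMm2 = "numeric"))
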