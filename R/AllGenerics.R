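# Accessors and show methods.

#' @describeIn ChannelImage-class SHG (collagen) channel raster.
#' @param x,object a \code{ChannelImage}.
#' @export
setGeneric("shgChannel", function(x) standardGeneric("shgChannel"))
#' @rdname ChannelImage-class
#' @export
setMethod("shgChannel", "ChannelImage", function(x) x@shg)

#' @describeIn ChannelImage-class TPEF (parenchyma) channel raster.
#' @export
setGeneric("tpefChannel", function(x) standardGeneric("tpefChannel"))
#' @rdname ChannelImage-class
#' @export
setMethod("tpefChannel", "ChannelImage", function(x) x@tpef)

#' @describeIn ChannelImage-class microns per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname ChannelImage-class
#' @export
setMethod("pixelSize", "ChannelImage", function(x) x@pixelSize)
#' @rdname ZoneMap-class
#' @export
setMethod("pixelSize", "ZoneMap", function(x) x@pixelSize)
#' @rdname CavitySet-class
#' @export
setMethod("pixelSize", "CavitySet", function(x) x@pixelSize)

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@shg)
  cat(sprintf("ChannelImage: %d x %d px at %.4g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize / 1000, d[2] * object@pixelSize / 1000))
  cat("  channels: SHG (collagen), TPEF (parenchyma), 8-bit\n")
})

#' @describeIn ConditionProfile-class steatotic hepatocyte fraction.
#' @param x,object a \code{ConditionProfile}.
#' @export
setGeneric("steatoticFraction", function(x) standardGeneric("steatoticFraction"))
#' @rdname ConditionProfile-class
#' @export
setMethod("steatoticFraction", "ConditionProfile", function(x) x@steatoticFraction)

#' @describeIn ConditionProfile-class expected portal-tract foci per mm^2.
#' @export
setGeneric("ptFociDensity", function(x) standardGeneric("ptFociDensity"))
#' @rdname ConditionProfile-class
#' @export
setMethod("ptFociDensity", "ConditionProfile", function(x) x@ptFociDensity)

#' @describeIn ConditionProfile-class expected central-vein foci per mm^2.
#' @export
setGeneric("cvFociDensity", function(x) standardGeneric("cvFociDensity"))
#' @rdname ConditionProfile-class
#' @export
setMethod("cvFociDensity", "ConditionProfile", function(x) x@cvFociDensity)

#' @describeIn ConditionProfile-class total collagen areal fraction of tissue.
#' @export
setGeneric("collagenTotal", function(x) standardGeneric("collagenTotal"))
#' @rdname ConditionProfile-class
#' @export
setMethod("collagenTotal", "ConditionProfile", function(x) x@collagenTotal)

#' @describeIn ConditionProfile-class zonal collagen allocation weights.
#' @export
setGeneric("collagenZoneWeights", function(x) standardGeneric("collagenZoneWeights"))
#' @rdname ConditionProfile-class
#' @export
setMethod("collagenZoneWeights", "ConditionProfile", function(x) x@collagenZoneWeights)

#' @describeIn ConditionProfile-class endpoint means table (endpoint, mean, sem, n).
#' @export
setGeneric("endpointMeans", function(x) standardGeneric("endpointMeans"))
#' @rdname ConditionProfile-class
#' @export
setMethod("endpointMeans", "ConditionProfile", function(x) x@endpointMeans)

setMethod("show", "ConditionProfile", function(object) {
  cat(sprintf("ConditionProfile %s day %d\n", object@group, object@day))
  cat(sprintf("  steatotic fraction: %.3f | PT foci: %.1f /mm^2 | CV foci: %.1f /mm^2\n",
              object@steatoticFraction, object@ptFociDensity, object@cvFociDensity))
  cat(sprintf("  collagen total: %s of tissue\n",
              ifelse(is.na(object@collagenTotal), "NA",
                     sprintf("%.2f%%", 100 * object@collagenTotal))))
  em <- object@endpointMeans
  em <- em[!is.na(em$mean), , drop = FALSE]
  if (nrow(em))
    cat("  endpoints:", paste(sprintf("%s=%.3g+/-%.2g", em$endpoint, em$mean,
                                      em$sem), collapse = ", "), "\n")
})

#' @describeIn ZoneMap-class integer zone label raster.
#' @param x,object a \code{ZoneMap}.
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))
#' @rdname ZoneMap-class
#' @export
setMethod("zoneLabels", "ZoneMap", function(x) x@labels)

#' @describeIn ZoneMap-class zone areas in square microns (named, five zones).
#' @export
setGeneric("zoneAreas", function(x) standardGeneric("zoneAreas"))
#' @rdname ZoneMap-class
#' @export
setMethod("zoneAreas", "ZoneMap", function(x) {
  px2 <- x@pixelSize^2
  cnt <- tabulate(x@labels[x@labels > 0L], 5L)
  stats::setNames(cnt * px2, names(.ZONE)[-1])
})

setMethod("show", "ZoneMap", function(object) {
  a <- zoneAreas(object) / 1e6
  cat(sprintf("ZoneMap: %d x %d px, %g um band\n", nrow(object@labels),
              ncol(object@labels), object@bandUm))
  cat("  zone areas (mm^2):",
      paste(sprintf("%s=%.3g", names(a), a), collapse = " "), "\n")
})

#' @describeIn CavitySet-class per-cavity feature table.
#' @param x,object a \code{CavitySet}.
#' @export
setGeneric("cavityTable", function(x) standardGeneric("cavityTable"))
#' @rdname CavitySet-class
#' @export
setMethod("cavityTable", "CavitySet", function(x) x@table)

#' @describeIn CavitySet-class integer cavity label raster.
#' @export
setGeneric("cavityLabels", function(x) standardGeneric("cavityLabels"))
#' @rdname CavitySet-class
#' @export
setMethod("cavityLabels", "CavitySet", function(x) x@labels)

setMethod("show", "CavitySet", function(object) {
  cat(sprintf("CavitySet: %d cavities\n", nrow(object@table)))
  if ("class" %in% names(object@table)) {
    tb <- table(object@table$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
})

setMethod("show", "ObjectClassTree", function(object) {
  cat(sprintf("ObjectClassTree (%s): classes %s\n", object@kind,
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "TissueMasks", function(object) {
  cat(sprintf("TissueMasks: tissue %.3g mm^2, collagen %.3g%% of tissue (Otsu t=%s)\n",
              sum(object@tissue) * object@pixelSize^2 / 1e6,
              100 * sum(object@collagen) / max(1, sum(object@tissue)),
              paste(object@thresholds, collapse = "/")))
})

setMethod("show", "GroundTruth", function(object) {
  p <- object@params
  cat(sprintf("GroundTruth: %d PT + %d CV landmarks, %s vacuoles, steatotic fraction %.3f\n",
              sum(object@landmarks$class == "PT"),
              sum(object@landmarks$class == "CV"),
              ifelse(is.null(p$nVacuoles), "?", p$nVacuoles),
              ifelse(is.null(p$steatoticFraction), NA, p$steatoticFraction)))
})

setMethod("show", "ZoneCollagenProfile", function(object) {
  cat(sprintf("ZoneCollagenProfile: total %.3g%% of tissue%s\n",
              100 * object@totalFraction,
              if (object@defined) "" else " (no collagen; shares undefined)"))
  cat("  shares:", paste(sprintf("%s=%.3f", names(object@shares),
                                 object@shares), collapse = " "), "\n")
})

setMethod("show", "SteatosisResult", function(object) {
  cat(sprintf("SteatosisResult: %.1f%% steatotic (%d vacuoles / %.0f hepatocytes)\n",
              100 * object@fraction, object@nVacuoles, object@totalHepatocytes))
})

setMethod("show", "FociDensity", function(object) {
  cat(sprintf("FociDensity: PT %.2f /mm^2, CV %.2f /mm^2 over %.3g mm^2\n",
              object@ptPerMm2, object@cvPerMm2, object@tissueAreaMm2))
})
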