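# End-to-end analysis of one section.

#' Analyze a two-channel section end to end
#'
#' Runs the full quantification path on a calibrated SHG/TPEF image:
#' Otsu tissue and collagen masks with SHG noise removal, cavity detection
#' and decision-tree classification, five-zone acinar map from the
#' detected PT/CV objects, and the zone-wise collagen, steatosis and foci
#' readouts.
#'
#' @param image a \linkS4class{ChannelImage}.
#' @param tree cavity classifier (default \code{\link{defaultClassTree}()}).
#' @param bandUm PP/PC band width in microns.
#' @param cellAreaUm2 nominal hepatocyte area for the steatosis denominator.
#' @param maxHoleUm2,minTissueUm2,minFibrilUm2,minCavityUm2,ringUm
#'   segmentation parameters (see \code{\link{tissueMask}},
#'   \code{\link{collagenMask}}, \code{\link{detectCavities}}).
#' @return List with components \code{masks} (\linkS4class{TissueMasks}),
#'   \code{cavities} (classified \linkS4class{CavitySet}), \code{zoneMap},
#'   \code{collagen} (\linkS4class{ZoneCollagenProfile}), \code{steatosis},
#'   \code{foci}, and \code{tissueAreaMm2}.
#' @export
analyzeSection <- function(image, tree = defaultClassTree(), bandUm = 100,
                           cellAreaUm2 = 450, maxHoleUm2 = 400,
                           minTissueUm2 = 10000, minFibrilUm2 = 5,
                           minCavityUm2 = 15, ringUm = 5) {
  ps <- pixelSize(image)
  tis <- tissueMask(tpefChannel(image), ps, maxHoleUm2, minTissueUm2)
  sup <- sectionSupport(tis, ps)
  col <- collagenMask(shgChannel(image), tis, ps, minFibrilUm2)
  cav <- detectCavities(tpefChannel(image), tis, col, ps,
                        minCavityUm2, ringUm, support = sup)
  cls <- classifyCavities(cav, tree)
  zm <- buildZoneMap(sup, cls, ps, bandUm)
  zc <- collagenByZone(col, zm)
  st <- steatosis(cls, sup, ps, cellAreaUm2)
  areaMm2 <- sum(sup) * ps^2 / 1e6
  fd <- fociDensity(cls, areaMm2)
  masks <- new("TissueMasks",
               tissue = tis & TRUE, collagen = col & TRUE, support = sup,
               thresholds = c(tpef = attr(tis, "threshold"),
                              shg = attr(col, "threshold")),
               pixelSize = ps)
  list(masks = masks, cavities = cls, zoneMap = zm, collagen = zc,
       steatosis = st, foci = fd, tissueAreaMm2 = areaMm2)
}

#' One-row summary of a section analysis
#'
#' Flattens an \code{\link{analyzeSection}} result into the per-slide CSV
#' layout: zone collagen shares and densities, total collagen fraction,
#' steatotic fraction, and PT/CV foci densities.
#'
#' @param analysis result of \code{\link{analyzeSection}}.
#' @param id optional slide/ROI identifier.
#' @return A one-row data.frame.
#' @export
sectionSummary <- function(analysis, id = NA_character_) {
  zc <- analysis$collagen
  sh <- stats::setNames(as.list(zc@shares), paste0("share_", names(zc@shares)))
  de <- stats::setNames(as.list(zc@densities),
                        paste0("density_", names(zc@densities)))
  data.frame(id = id,
             tissue_area_mm2 = analysis$tissueAreaMm2,
             total_collagen_fraction = zc@totalFraction,
             as.data.frame(sh), as.data.frame(de),
             steatotic_fraction = analysis$steatosis@fraction,
             n_vacuoles = analysis$steatosis@nVacuoles,
             pt_per_mm2 = analysis$foci@ptPerMm2,
             cv_per_mm2 = analysis$foci@cvPerMm2,
             row.names = NULL)
}
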