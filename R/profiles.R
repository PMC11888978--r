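# Built-in condition profiles: group x day parameter sets transcribed from
# the reported means +/- SEM of the four-arm hepatectomy/glutamine study
# (sham +/- Gln, 70% partial hepatectomy +/- Gln, days 0-6).

.GROUPS <- c("sham+Gln", "sham-Gln", "PHx+Gln", "PHx-Gln")
.ENDPOINTS <- c("rlw_bw_pct", "ast_UL", "alt_UL", "albumin", "pcna_pct")

# One row per reported (group, day) cell. Means/SEMs are the printed
# values; NA marks endpoints not reported for that cell. Albumin was
# reported only as "comparable between groups": a constant 3.5 +/- 0.1 g/dL
# is used for all arms. Collagen totals are areal fractions of tissue
# chosen so the group ratios match the reported total-collagen ratios
# (1.2x at D2, 4.9x at D4); PT foci at unreported days sit at the 2.5/mm^2
# baseline. Group size n is 6 throughout.
.profileRows <- function() {
  r <- function(group, day, steat, pt, cv, coll,
                rlw = c(NA, NA), ast = c(NA, NA), alt = c(NA, NA),
                alb = c(3.5, 0.1), pcna = c(NA, NA)) {
    list(group = group, day = day, steat = steat, pt = pt, cv = cv,
         coll = coll, rlw = rlw, ast = ast, alt = alt, alb = alb,
         pcna = pcna)
  }
  list(
    r("sham+Gln", 0L, 0,     2.5, 2, 0.008, rlw = c(4.3, 0.2)),
    r("sham-Gln", 0L, 0,     2.5, 2, 0.008, rlw = c(4.1, 0.4)),
    r("sham+Gln", 2L, 0,     2.5, 2, 0.008, rlw = c(4.3, 0.2)),
    r("sham-Gln", 2L, 0,     2.5, 2, 0.008, rlw = c(4.1, 0.4)),
    r("sham+Gln", 6L, 0,     2.5, 2, 0.008, rlw = c(4.3, 0.2)),
    r("sham-Gln", 6L, 0,     2.5, 2, 0.008, rlw = c(4.7, 0.1)),
    r("PHx+Gln", 1L, 0.103,  2.5, 2, 0.010,
      ast = c(11393, 367), alt = c(9478, 564), pcna = c(9.6, 1.5)),
    r("PHx-Gln", 1L, 0.044,  2.5, 2, 0.010,
      ast = c(7600, 873), alt = c(5704, 588), pcna = c(9.1, 3.9)),
    r("PHx+Gln", 2L, 0.333,  7.7, 2, 0.012,
      rlw = c(3.0, 0.2), pcna = c(34.3, 4.8)),
    r("PHx-Gln", 2L, 0.162,  3.2, 2, 0.010,
      rlw = c(2.0, 0.1), pcna = c(15.5, 1.4)),
    r("PHx+Gln", 4L, 0.057,  5.0, 2, 0.0392,
      rlw = c(3.7, 0.4), pcna = c(24.2, 3.3)),
    r("PHx-Gln", 4L, 0.011,  2.5, 2, 0.008,
      rlw = c(2.7, 0.3), pcna = c(13.6, 0.8))
  )
}

.DEFAULT_ZONE_WEIGHTS <- c(PT = 0.05, PP = 0.50, TS = 0.30, PC = 0.10,
                           CV = 0.05)

#' Construct a condition profile
#'
#' @param group one of \code{"sham+Gln"}, \code{"sham-Gln"},
#'   \code{"PHx+Gln"}, \code{"PHx-Gln"}.
#' @param day integer post-operative day (0--6).
#' @param steatoticFraction proportion of hepatocytes bearing a vacuole.
#' @param ptFociDensity,cvFociDensity expected foci per mm^2.
#' @param collagenTotal total collagen areal fraction of tissue.
#' @param collagenZoneWeights named zonal allocation weights (sum 1).
#' @param endpointMeans data.frame (endpoint, mean, sem, n).
#' @return A \linkS4class{ConditionProfile}.
#' @export
conditionProfile <- function(group, day, steatoticFraction = 0,
                             ptFociDensity = 2.5, cvFociDensity = 2,
                             collagenTotal = 0.008,
                             collagenZoneWeights = .DEFAULT_ZONE_WEIGHTS,
                             endpointMeans = NULL) {
  if (is.null(endpointMeans))
    endpointMeans <- data.frame(endpoint = .ENDPOINTS, mean = NA_real_,
                                sem = NA_real_, n = 6)
  new("ConditionProfile", group = group, day = as.integer(day),
      steatoticFraction = steatoticFraction,
      ptFociDensity = ptFociDensity, cvFociDensity = cvFociDensity,
      collagenTotal = collagenTotal,
      collagenZoneWeights = collagenZoneWeights[c("PT", "PP", "TS", "PC", "CV")],
      endpointMeans = endpointMeans)
}

#' Built-in group-by-day condition profiles
#'
#' One \linkS4class{ConditionProfile} per reported (group, day) combination,
#' with the printed means and SEMs: remnant liver weight / body weight,
#' serum AST/ALT, albumin, PCNA-positive hepatocyte percentage, steatotic
#' hepatocyte fraction, PT/CV foci densities and total collagen (as
#' group-ratio-matched areal fractions).
#'
#' @return Named list of \linkS4class{ConditionProfile} objects; names are
#'   \code{"<group>:D<day>"}.
#' @examples
#' p <- getProfile("PHx+Gln", 2)
#' steatoticFraction(p)  # 0.333
#' @export
builtinProfiles <- function() {
  rows <- .profileRows()
  out <- lapply(rows, function(x) {
    em <- data.frame(endpoint = .ENDPOINTS,
                     mean = c(x$rlw[1], x$ast[1], x$alt[1], x$alb[1], x$pcna[1]),
                     sem = c(x$rlw[2], x$ast[2], x$alt[2], x$alb[2], x$pcna[2]),
                     n = 6)
    conditionProfile(x$group, x$day, x$steat, x$pt, x$cv, x$coll,
                     endpointMeans = em)
  })
  names(out) <- vapply(rows, function(x) sprintf("%s:D%d", x$group, x$day), "")
  out
}

#' @rdname builtinProfiles
#' @param group group name.
#' @param day post-operative day.
#' @param profiles profile list to look in.
#' @export
getProfile <- function(group, day, profiles = builtinProfiles()) {
  key <- sprintf("%s:D%d", group, as.integer(day))
  if (!key %in% names(profiles))
    stop(sprintf("no profile for %s", key))
  profiles[[key]]
}

#' @rdname builtinProfiles
#' @export
conditionTable <- function(profiles = builtinProfiles()) {
  do.call(rbind, lapply(profiles, function(p) {
    em <- endpointMeans(p)
    wide <- stats::setNames(em$mean, em$endpoint)
    data.frame(group = p@group, day = p@day,
               steatotic_fraction = p@steatoticFraction,
               pt_foci_density = p@ptFociDensity,
               cv_foci_density = p@cvFociDensity,
               collagen_total = p@collagenTotal,
               t(wide), row.names = NULL)
  }))
}
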