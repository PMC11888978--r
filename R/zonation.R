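# Cavity classification (decision tree) and five-zone acinar map.

.CAVITY_CLASSES <- c("PT", "CV", "vessel_duct", "crack", "vacuole")
.TREE_FEATURES <- c("area_um2", "equiv_diameter_um", "circularity",
                    "solidity", "collagen_ring_fraction", "border_flag")

#' Default rule-based cavity classification tree
#'
#' Inspectable binary decision tree encoding how the cavity classes differ
#' in morphology and surrounding collagen, used when no training data are
#' available: border-contact objects are cracks; large lumens without a
#' collagen ring are central veins; lumens wrapped in collagen
#' (ring fraction >= 0.5, area 300--20000 um^2) are portal tracts; small
#' round hollows (circularity >= 0.6, diameter 5--40 um) without
#' surrounding collagen are lipid vacuoles; everything else is a vessel or
#' duct lumen.
#'
#' @return An \linkS4class{ObjectClassTree} of kind \code{"rules"}.
#' @export
defaultClassTree <- function() {
  leaf <- function(lab) list(leaf = lab)
  node <- function(f, t, lo, hi)
    list(feature = f, threshold = t, left = lo, right = hi)  # left: value < t
  vac4 <- node("collagen_ring_fraction", 0.2, leaf("vacuole"), leaf("vessel_duct"))
  vac3 <- node("equiv_diameter_um", 40, vac4, leaf("vessel_duct"))
  vac2 <- node("equiv_diameter_um", 5, leaf("vessel_duct"), vac3)
  vac  <- node("circularity", 0.6, leaf("vessel_duct"), vac2)
  pt3  <- node("area_um2", 20000, leaf("PT"), vac)
  pt2  <- node("area_um2", 300, vac, pt3)
  ptn  <- node("collagen_ring_fraction", 0.5, vac, pt2)
  cv2  <- node("collagen_ring_fraction", 0.2, leaf("CV"), ptn)
  cvn  <- node("area_um2", 2000, ptn, cv2)
  root <- node("border_flag", 0.5, cvn, leaf("crack"))
  new("ObjectClassTree", kind = "rules", root = root, fit = NULL,
      classes = .CAVITY_CLASSES)
}

.predictRules <- function(root, row, id = "?") {
  nd <- root
  while (is.null(nd$leaf)) {
    v <- row[[nd$feature]]
    if (is.null(v) || is.na(v))
      stop(sprintf("cavity %s: missing feature '%s'", id, nd$feature))
    nd <- if (as.numeric(v) < nd$threshold) nd$left else nd$right
  }
  nd$leaf
}

#' Classify detected cavities
#'
#' Assigns each cavity exactly one class in \{PT, CV, vessel_duct, crack,
#' vacuole\} using a decision tree over its morphological features and
#' surrounding collagen. Border-flagged objects are never classed as
#' vacuoles (a trained tree's vacuole call on a border object is demoted to
#' crack).
#'
#' @param cavities a \linkS4class{CavitySet}.
#' @param tree an \linkS4class{ObjectClassTree};
#'   default \code{\link{defaultClassTree}()}.
#' @return The \code{CavitySet} with a \code{class} column added.
#' @export
classifyCavities <- function(cavities, tree = defaultClassTree()) {
  tab <- cavities@table
  if (nrow(tab) == 0L) {
    tab$class <- character(0)
    cavities@table <- tab
    return(cavities)
  }
  need <- .TREE_FEATURES
  for (f in need) {
    bad <- which(is.na(tab[[f]]))
    if (length(bad))
      stop(sprintf("cavity %d: missing feature '%s'", tab$id[bad[1]], f))
  }
  cls <- if (tree@kind == "rules") {
    vapply(seq_len(nrow(tab)), function(i)
      .predictRules(tree@root, tab[i, , drop = FALSE], tab$id[i]),
      character(1))
  } else {
    nd <- tab[, need, drop = FALSE]
    nd$border_flag <- as.numeric(nd$border_flag)
    as.character(predict(tree@fit, newdata = nd, type = "class"))
  }
  cls[tab$border_flag & cls == "vacuole"] <- "crack"
  tab$class <- cls
  cavities@table <- tab
  cavities
}

#' Fit a CART cavity classifier from labeled objects
#'
#' Greedy binary recursive partitioning (Gini impurity, via \pkg{rpart}) on
#' labeled cavity feature vectors, e.g. objects from synthetic sections
#' matched to their ground truth.
#'
#' @param objects data.frame with a \code{class} column plus the feature
#'   columns of \code{\link{detectCavities}}.
#' @param maxDepth maximum tree depth.
#' @param seed RNG seed (splits are deterministic given data order; the
#'   seed fixes any surrogate tie handling).
#' @return An \linkS4class{ObjectClassTree} of kind \code{"rpart"}; a
#'   single-class input yields a trivial one-leaf rule tree with a warning.
#' @export
fitTree <- function(objects, maxDepth = 4, seed = 1) {
  stopifnot("class" %in% names(objects))
  cls <- unique(objects$class)
  if (length(cls) < 2L) {
    warning("single-class input: returning a one-leaf tree")
    return(new("ObjectClassTree", kind = "rules",
               root = list(leaf = cls), fit = NULL, classes = cls))
  }
  feats <- intersect(.TREE_FEATURES, names(objects))
  d <- objects[, c("class", feats)]
  d$border_flag <- as.numeric(d$border_flag)
  d$class <- factor(d$class)
  fit <- withSeed(seed,
    rpart::rpart(class ~ ., data = d, method = "class",
                 control = rpart::rpart.control(maxdepth = maxDepth,
                                                minsplit = 2, cp = 0,
                                                xval = 0)))
  new("ObjectClassTree", kind = "rpart", root = list(), fit = fit,
      classes = levels(d$class))
}

#' Serialize / deserialize a rule tree as JSON
#'
#' @param tree an \linkS4class{ObjectClassTree} of kind \code{"rules"}.
#' @param path file path.
#' @return \code{treeToJSON} writes and returns the path invisibly;
#'   \code{treeFromJSON} returns the tree.
#' @export
treeToJSON <- function(tree, path) {
  if (tree@kind != "rules")
    stop("only rule trees have a JSON serialization")
  jsonlite::write_json(list(kind = "rules", classes = tree@classes,
                            root = tree@root),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname treeToJSON
#' @export
treeFromJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(nd) {
    if (!is.null(nd$leaf)) return(list(leaf = nd$leaf))
    list(feature = nd$feature, threshold = as.numeric(nd$threshold),
         left = fix(nd$left), right = fix(nd$right))
  }
  new("ObjectClassTree", kind = "rules", root = fix(x$root), fit = NULL,
      classes = unlist(x$classes))
}

# Core zone assignment shared by the generator (ground truth) and the
# analysis: single source of truth for the band geometry.
zoneMapCore <- function(mask, ptMask, cvMask, pixelSizeUm, bandUm,
                        landmarks = data.frame()) {
  z <- matrix(.ZONE[["TS"]], nrow(mask), ncol(mask))
  z[!mask] <- .ZONE[["background"]]
  if (!any(ptMask) && !any(cvMask)) {
    warning("no PT/CV landmarks: entire tissue labeled transitional")
  } else {
    dpt <- distToSet(ptMask, pixelSizeUm)
    dcv <- distToSet(cvMask, pixelSizeUm)
    nearP <- dpt <= bandUm
    nearC <- dcv <= bandUm
    pp <- mask & nearP & (!nearC | dpt <= dcv)   # exact ties periportal
    pc <- mask & nearC & !pp
    z[pc] <- .ZONE[["PC"]]
    z[pp] <- .ZONE[["PP"]]
    z[mask & cvMask] <- .ZONE[["CV"]]
    z[mask & ptMask] <- .ZONE[["PT"]]
  }
  storage.mode(z) <- "integer"
  new("ZoneMap", labels = z, pixelSize = pixelSizeUm, bandUm = bandUm,
      landmarks = landmarks)
}

#' Build the five-zone acinar map from landmarks
#'
#' Partitions the tissue support into portal tract (PT), periportal (PP),
#' transitional (TS), pericentral (PC) and central vein (CV) zones. PT/CV
#' pixels are the landmark object pixels themselves; PP (PC) is the tissue
#' within \code{bandUm} Euclidean distance of any PT (CV) object boundary;
#' a pixel within band of both is assigned to the nearer landmark class,
#' with exact ties periportal; all remaining tissue is transitional.
#'
#' @param mask logical tissue-support raster (see
#'   \code{\link{sectionSupport}}); zones partition exactly this mask.
#' @param landmarks either a classified \linkS4class{CavitySet} (its
#'   PT-/CV-class objects become the landmarks) or a data.frame with
#'   columns class ("PT"/"CV"), x_um, y_um, radius_um describing circular
#'   landmarks.
#' @param pixelSizeUm microns per pixel.
#' @param bandUm band width in microns (default 100).
#' @return A \linkS4class{ZoneMap}. With no landmarks the whole tissue is
#'   labeled transitional, with a warning.
#' @export
buildZoneMap <- function(mask, landmarks, pixelSizeUm, bandUm = 100) {
  nr <- nrow(mask); nc <- ncol(mask)
  ptMask <- matrix(FALSE, nr, nc)
  cvMask <- matrix(FALSE, nr, nc)
  if (is(landmarks, "CavitySet")) {
    tab <- landmarks@table
    if (!"class" %in% names(tab))
      stop("classify cavities before building the zone map")
    l <- landmarks@labels
    ptIds <- tab$id[tab$class == "PT"]
    cvIds <- tab$id[tab$class == "CV"]
    if (length(ptIds)) ptMask <- matrix(l %in% ptIds, nr, nc)
    if (length(cvIds)) cvMask <- matrix(l %in% cvIds, nr, nc)
    prov <- tab[tab$class %in% c("PT", "CV"),
                c("id", "class", "centroid_x_um", "centroid_y_um")]
  } else {
    lm <- as.data.frame(landmarks)
    if (nrow(lm)) {
      if (!all(lm$class %in% c("PT", "CV")))
        stop("landmark classes must be PT or CV")
      for (i in seq_len(nrow(lm))) {
        cx <- umToPx(lm$x_um[i], pixelSizeUm)
        cy <- umToPx(lm$y_um[i], pixelSizeUm)
        rpx <- lm$radius_um[i] / pixelSizeUm
        if (lm$class[i] == "PT") ptMask <- stampDisc(ptMask, cx, cy, rpx)
        else cvMask <- stampDisc(cvMask, cx, cy, rpx)
      }
    }
    prov <- lm
  }
  ptMask <- ptMask & mask
  cvMask <- cvMask & mask
  zoneMapCore(mask, ptMask, cvMask, pixelSizeUm, bandUm, prov)
}
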