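#' @include AllClasses.R distances.R
NULL

#' All vertex angles through landmark triples
#'
#' For every unordered triple of landmarks, the three vertex angles (law of
#' cosines), giving 3 * C(26,3) = 7800 angles for the default battery. The
#' three interior angles of each triple sum to 180 degrees. Triples
#' containing coincident landmarks yield NA.
#'
#' @param lms a \linkS4class{LandmarkSet}.
#' @return named numeric vector of angles in degrees, in [0, 180]; names are
#'   \code{"a-b-c@v"} where v is the vertex landmark.
#' @export
angleMeasurements <- function(lms) {
  x <- coords(lms)
  nms <- rownames(x)
  p <- nrow(x)
  D <- as.matrix(stats::dist(x))
  tri <- t(utils::combn(p, 3L))
  a <- D[tri[, c(2L, 3L)]]  # side opposite vertex 1
  b <- D[tri[, c(1L, 3L)]]  # opposite vertex 2
  cc <- D[tri[, c(1L, 2L)]] # opposite vertex 3
  degen <- a == 0 | b == 0 | cc == 0   # coincident points: whole triple NA
  ang <- function(opp, s1, s2) {
    r <- (s1^2 + s2^2 - opp^2) / (2 * s1 * s2)
    out <- acos(pmin(pmax(r, -1), 1)) * 180 / pi
    out[degen] <- NA_real_
    out
  }
  A1 <- ang(a, b, cc); A2 <- ang(b, a, cc); A3 <- ang(cc, a, b)
  lab <- paste(nms[tri[, 1L]], nms[tri[, 2L]], nms[tri[, 3L]], sep = "-")
  out <- c(rbind(A1, A2, A3))
  names(out) <- c(rbind(paste0(lab, "@", nms[tri[, 1L]]),
                        paste0(lab, "@", nms[tri[, 2L]]),
                        paste0(lab, "@", nms[tri[, 3L]])))
  out
}

#' Heron triangle areas of all landmark triples
#'
#' Area of every C(26,3) = 2600 landmark triangle by Heron's formula
#' A = sqrt(s(s-a)(s-b)(s-c)) with s the semiperimeter; a negative radicand
#' (collinear triples, up to rounding) is clamped to zero.
#'
#' @param lms a \linkS4class{LandmarkSet}.
#' @return named numeric vector of areas (mm^2).
#' @export
triangleAreas <- function(lms) {
  x <- coords(lms)
  nms <- rownames(x)
  D <- as.matrix(stats::dist(x))
  tri <- t(utils::combn(nrow(x), 3L))
  a <- D[tri[, c(2L, 3L)]]; b <- D[tri[, c(1L, 3L)]]; cc <- D[tri[, c(1L, 2L)]]
  s <- (a + b + cc) / 2
  out <- sqrt(pmax(s * (s - a) * (s - b) * (s - cc), 0))
  names(out) <- paste(nms[tri[, 1L]], nms[tri[, 2L]], nms[tri[, 3L]],
                      sep = "-")
  out
}

#' Default battery of 32 proportion indices
#'
#' Farkas-style facial ratios, each defined by two Euclidean distances and
#' reported as the smaller expressed as a percentage of the larger. The
#' exact published index sets vary; this battery is a documented default
#' covering face, orbit, nose, mouth and profile proportions.
#'
#' @return data.frame with columns name, a1, a2 (first distance pair),
#'   b1, b2 (second distance pair).
#' @export
defaultIndexBattery <- function() {
  m <- matrix(c(
    "facial",               "nasion", "gnathion", "zygion_L", "zygion_R",
    "upper_face",           "nasion", "stomion", "zygion_L", "zygion_R",
    "lower_upper_face",     "subnasale", "gnathion", "nasion", "gnathion",
    "mandibulo_facial",     "gonion_L", "gonion_R", "zygion_L", "zygion_R",
    "mandibulo_upper_face", "gonion_L", "gonion_R", "nasion", "stomion",
    "chin_face_height",     "sublabiale", "gnathion", "nasion", "gnathion",
    "lower_face_width",     "subnasale", "gnathion", "zygion_L", "zygion_R",
    "forehead_face",        "glabella", "nasion", "nasion", "gnathion",
    "intercanthal_biocular","endocanthion_L", "endocanthion_R", "exocanthion_L", "exocanthion_R",
    "intercanthal_face",    "endocanthion_L", "endocanthion_R", "zygion_L", "zygion_R",
    "biocular_face",        "exocanthion_L", "exocanthion_R", "zygion_L", "zygion_R",
    "orbital_L",            "endocanthion_L", "exocanthion_L", "endocanthion_L", "endocanthion_R",
    "orbital_R",            "endocanthion_R", "exocanthion_R", "endocanthion_L", "endocanthion_R",
    "nasal",                "alare_L", "alare_R", "nasion", "subnasale",
    "nasal_tip",            "pronasale", "subnasale", "nasion", "subnasale",
    "nasal_bridge",         "nasion", "pronasale", "nasion", "subnasale",
    "nose_face_height",     "nasion", "subnasale", "nasion", "gnathion",
    "nose_face_width",      "alare_L", "alare_R", "zygion_L", "zygion_R",
    "nose_mouth_width",     "alare_L", "alare_R", "cheilion_L", "cheilion_R",
    "alar_base",            "subalare_L", "subalare_R", "alare_L", "alare_R",
    "mouth_face_width",     "cheilion_L", "cheilion_R", "zygion_L", "zygion_R",
    "mouth_jaw_width",      "cheilion_L", "cheilion_R", "gonion_L", "gonion_R",
    "upper_lip_face",       "subnasale", "stomion", "subnasale", "gnathion",
    "lower_lip_face",       "stomion", "sublabiale", "subnasale", "gnathion",
    "vermilion",            "labiale_superius", "stomion", "stomion", "labiale_inferius",
    "lip_chin",             "stomion", "gnathion", "subnasale", "gnathion",
    "chin",                 "sublabiale", "gnathion", "subnasale", "gnathion",
    "cutaneous_upper_lip",  "subnasale", "labiale_superius", "subnasale", "stomion",
    "tragal_face_width",    "tragion_L", "tragion_R", "zygion_L", "zygion_R",
    "face_depth",           "tragion_L", "gnathion", "nasion", "gnathion",
    "profile_L",            "tragion_L", "pronasale", "tragion_L", "tragion_R",
    "profile_R",            "tragion_R", "pronasale", "tragion_L", "tragion_R"),
    ncol = 5L, byrow = TRUE)
  data.frame(name = m[, 1L], a1 = m[, 2L], a2 = m[, 3L], b1 = m[, 4L],
             b2 = m[, 5L], stringsAsFactors = FALSE)
}

#' Proportion indices from Euclidean distances
#'
#' Each index is the smaller of its two distances expressed as a percentage
#' of the larger, so values lie in (0, 100].
#'
#' @param distances named pairwise distances from
#'   \code{\link{euclideanDistances}}.
#' @param battery index definitions (see \code{\link{defaultIndexBattery}}).
#' @return named numeric vector of indices (percent).
#' @export
proportionIndices <- function(distances, battery = defaultIndexBattery()) {
  look <- function(a, b) {
    v <- distances[paste(a, b, sep = "-")]
    v2 <- distances[paste(b, a, sep = "-")]
    v[is.na(v)] <- v2[is.na(v)]
    unname(v)
  }
  d1 <- look(battery$a1, battery$a2)
  d2 <- look(battery$b1, battery$b2)
  if (anyNA(d1) || anyNA(d2))
    stop("index battery references a distance pair that was not computed")
  if (any(pmax(d1, d2) == 0))
    stop("zero denominator distance in index: ",
         paste(battery$name[pmax(d1, d2) == 0], collapse = ", "))
  out <- pmin(d1, d2) / pmax(d1, d2) * 100
  names(out) <- battery$name
  out
}

#' Convex hull of a 3D point set: volume and surface area
#'
#' Facet-enumeration hull for small point sets (all supporting planes are
#' found by triple enumeration, coplanar facets merged via their planar
#' 2D hull). Intended for landmark subsets (tens of points), not meshes.
#'
#' @param points numeric matrix (n x 3).
#' @return list(volume, area) in mm^3 and mm^2; coplanar input yields
#'   volume 0 (with a warning) and the area of the flat polygon counted
#'   once per side is avoided: a degenerate hull reports polygon area * 2
#'   as its closed-surface area would be; here flat sets report the single
#'   polygon area and volume 0.
#' @export
convexHull3d <- function(points) {
  p <- unique(as.matrix(points))
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 distinct points")
  ctr <- colMeans(p)
  scale <- max(sqrt(rowSums(sweep(p, 2L, ctr)^2)), 1e-12)
  tol <- 1e-9 * scale
  # coplanarity of the full set
  sv <- svd(sweep(p, 2L, ctr))
  if (n < 4L || sv$d[3L] < 1e-9 * sv$d[1L]) {
    if (sv$d[2L] < 1e-9 * sv$d[1L]) stop("points are collinear: hull degenerate")
    basis <- sv$v[, 1:2]
    q <- sweep(p, 2L, ctr) %*% basis
    h <- grDevices::chull(q)
    xy <- q[h, , drop = FALSE]
    a <- abs(sum(xy[, 1L] * xy[c(2:nrow(xy), 1L), 2L] -
                 xy[c(2:nrow(xy), 1L), 1L] * xy[, 2L])) / 2
    warning("coplanar points: hull volume is 0")
    return(list(volume = 0, area = a))
  }
  planes <- list()
  keys <- character(0)
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    nrm <- .cross3(p[j, ] - p[i, ], p[k, ] - p[i, ])
    nl <- sqrt(sum(nrm^2))
    if (nl < tol * scale) next
    nrm <- nrm / nl
    s <- sweep(p, 2L, p[i, ]) %*% nrm
    if (all(s <= tol)) nrm <- -nrm
    else if (!all(s >= -tol)) next
    off <- sum(nrm * p[i, ])
    key <- paste(round(c(nrm, off / scale) * 1e6), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    planes[[length(planes) + 1L]] <- list(normal = nrm, pts = which(abs(s) <= tol))
  }
  vol <- 0; area <- 0
  for (pl in planes) {
    on <- p[pl$pts, , drop = FALSE]
    nrm <- pl$normal
    # outward orientation: normal away from centroid
    if (sum(nrm * (on[1L, ] - ctr)) < 0) nrm <- -nrm
    b1 <- on[2L, ] - on[1L, ]; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- .cross3(nrm, b1)
    q <- sweep(on, 2L, on[1L, ]) %*% cbind(b1, b2)
    h <- grDevices::chull(q)
    xy <- q[h, , drop = FALSE]
    a2 <- sum(xy[, 1L] * xy[c(2:nrow(xy), 1L), 2L] -
              xy[c(2:nrow(xy), 1L), 1L] * xy[, 2L]) / 2
    if (a2 < 0) { h <- rev(h); xy <- q[h, , drop = FALSE]; a2 <- -a2 }
    area <- area + a2
    # cone volume from the centroid: (1/3) * facet triangle area * height
    for (t in 2:(length(h) - 1L)) {
      tri <- rbind(on[h[1L], ], on[h[t], ], on[h[t + 1L], ])
      atri <- sqrt(sum(.cross3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])^2)) / 2
      height <- sum(nrm * (tri[1L, ] - ctr))
      vol <- vol + atri * height / 3
    }
  }
  list(volume = vol, area = area)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Default facial region definitions for hull volumes and areas
#'
#' Ten landmark subsets (nose, left/right cheek, chin, mouth, upper and
#' lower lip, eye span, jaw, midface) used for convex-hull volume and
#' surface-area phenotypes. Published region subsets vary; these are
#' documented defaults.
#'
#' @return named list of landmark-name vectors.
#' @export
defaultRegionDefinitions <- function() {
  list(
    nose = c("nasion", "pronasale", "subnasale", "alare_L", "alare_R",
             "subalare_L", "subalare_R"),
    cheek_L = c("zygion_L", "gonion_L", "alare_L", "exocanthion_L",
                "cheilion_L"),
    cheek_R = c("zygion_R", "gonion_R", "alare_R", "exocanthion_R",
                "cheilion_R"),
    chin = c("pogonion", "gnathion", "sublabiale", "gonion_L", "gonion_R"),
    mouth = c("cheilion_L", "cheilion_R", "labiale_superius",
              "labiale_inferius", "stomion"),
    upper_lip = c("subnasale", "labiale_superius", "cheilion_L", "cheilion_R",
                  "stomion"),
    lower_lip = c("labiale_inferius", "sublabiale", "cheilion_L",
                  "cheilion_R", "stomion"),
    eye_span = c("endocanthion_L", "endocanthion_R", "exocanthion_L",
                 "exocanthion_R", "nasion", "glabella"),
    jaw = c("gonion_L", "gonion_R", "gnathion", "pogonion", "tragion_L",
            "tragion_R"),
    midface = c("nasion", "zygion_L", "zygion_R", "subnasale", "pronasale"))
}

#' Convex-hull volume and surface area of facial regions
#'
#' For each region (a landmark subset), the volume and surface area of the
#' convex hull of its landmarks. Regions need at least 4 non-coplanar
#' points for a volume (coplanar sets report volume 0 with a warning) and
#' 3 for an area.
#'
#' @param lms a \linkS4class{LandmarkSet}.
#' @param regions named list of landmark-name subsets
#'   (default \code{\link{defaultRegionDefinitions}}).
#' @return data.frame: region, volume (mm^3), surface_area (mm^2).
#' @export
regionVolumeSurface <- function(lms, regions = defaultRegionDefinitions()) {
  x <- coords(lms)
  out <- lapply(names(regions), function(rn) {
    sub <- regions[[rn]]
    missing <- setdiff(sub, rownames(x))
    if (length(missing))
      stop("region ", rn, " references unknown landmark(s): ",
           paste(missing, collapse = ", "))
    h <- convexHull3d(x[sub, , drop = FALSE])
    data.frame(region = rn, volume = h$volume, surface_area = h$area)
  })
  do.call(rbind, out)
}
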