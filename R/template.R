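#' @include AllClasses.R dictionary.R
NULL

# Analytic feature positions (mm) of the 26 landmarks on the template
# parametric surface; x is lateral (left negative), y vertical (up positive).
.template_landmark_xy <- function() {
  m <- rbind(
    glabella         = c(0, 38), nasion = c(0, 30), pronasale = c(0, 0),
    subnasale        = c(0, -12),
    labiale_superius = c(0, -26), stomion = c(0, -32),
    labiale_inferius = c(0, -38), sublabiale = c(0, -46),
    pogonion         = c(0, -58), gnathion = c(0, -80),
    endocanthion_L   = c(-16, 25), endocanthion_R = c(16, 25),
    exocanthion_L    = c(-38, 25), exocanthion_R = c(38, 25),
    zygion_L         = c(-62, 8), zygion_R = c(62, 8),
    alare_L          = c(-14, -6), alare_R = c(14, -6),
    subalare_L       = c(-9, -13), subalare_R = c(9, -13),
    cheilion_L       = c(-24, -32), cheilion_R = c(24, -32),
    gonion_L         = c(-52, -52), gonion_R = c(52, -52),
    tragion_L        = c(-66, 25), tragion_R = c(66, 25))
  colnames(m) <- c("x", "y")
  m
}

# Face depth (mm) at lateral/vertical position: half-ellipsoid dome plus a
# nose ridge, eye depressions, a mouth groove and a chin bulge. Even in x,
# so the surface is bilaterally symmetric by construction.
.template_depth <- function(x, y) {
  u <- x / 70; v <- y / 90
  z <- 50 * sqrt(pmax(1.02 - u^2 - v^2, 0))
  z <- z + 16 * exp(-(x / 10)^2 - (y / 18)^2)                      # nose ridge
  z <- z - 6 * exp(-((x - 27) / 12)^2 - ((y - 25) / 8)^2)          # right eye
  z <- z - 6 * exp(-((x + 27) / 12)^2 - ((y - 25) / 8)^2)          # left eye
  z <- z - 3 * exp(-(x / 18)^2 - ((y + 32) / 4)^2)                 # mouth
  z <- z + 5 * exp(-(x / 15)^2 - ((y + 58) / 12)^2)                # chin
  z
}

#' Build the procedural face template
#'
#' Constructs a face-like parametric surface patch — a half-ellipsoid head
#' (140 mm wide, 180 mm tall, 50 mm deep) with a nose ridge, eye
#' depressions, a mouth groove and a chin bulge — triangulated over a
#' regular grid masked to an ellipse, and places the 26 landmarks of the
#' default dictionary at their named feature vertices. The grid is symmetric
#' in x, so paired landmarks mirror exactly across the sagittal plane.
#'
#' @param resolution grid points across the face; the default (61) yields
#'   roughly 2,900 vertices (configured band 2,000-4,000). Must be odd (one
#'   column on the midline) and large enough that all 26 landmarks land on
#'   distinct vertices.
#' @return a \linkS4class{FaceTemplate}.
#' @examples
#' tpl <- buildTemplate()
#' tpl
#' @export
buildTemplate <- function(resolution = 61L) {
  resolution <- as.integer(resolution)
  if (resolution %% 2L == 0L) resolution <- resolution + 1L
  xs <- seq(-70, 70, length.out = resolution)
  ys <- seq(-90, 90, length.out = resolution)
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x / 70)^2 + (g$y / 90)^2 <= 1
  idx <- matrix(NA_integer_, resolution, resolution)  # [ix, iy] -> vertex id
  idx[keep] <- seq_len(sum(keep))
  v <- cbind(x = g$x[keep], y = g$y[keep],
             z = .template_depth(g$x[keep], g$y[keep]))
  f <- list()
  for (iy in seq_len(resolution - 1L)) {
    a <- idx[-resolution, iy]; b <- idx[-1L, iy]
    c2 <- idx[-resolution, iy + 1L]; d2 <- idx[-1L, iy + 1L]
    ok1 <- !is.na(a) & !is.na(b) & !is.na(c2)
    ok2 <- !is.na(b) & !is.na(d2) & !is.na(c2)
    f[[length(f) + 1L]] <- cbind(a[ok1], b[ok1], c2[ok1])
    f[[length(f) + 1L]] <- cbind(b[ok2], d2[ok2], c2[ok2])
  }
  f <- do.call(rbind, f)
  # drop vertices not referenced by any face (ellipse-boundary orphans)
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3L)
  if (nrow(v) < 500L)
    stop("resolution too coarse: only ", nrow(v), " vertices (need >= 500)")
  mesh <- SurfaceMesh(v, f)
  dict <- defaultLandmarkDictionary()
  lmxy <- .template_landmark_xy()[landmarkNames(dict), , drop = FALSE]
  lmidx <- integer(nrow(lmxy)); names(lmidx) <- rownames(lmxy)
  for (nm in rownames(lmxy)) {
    side <- dict@side[match(nm, dict@names)]
    if (side == "R") {
      # mirror the already-snapped left partner so pairs are exactly symmetric
      lnm <- dict@pair[match(nm, dict@names)]
      lv <- v[lmidx[[lnm]], ]
      d2 <- (v[, 1L] + lv[1L])^2 + (v[, 2L] - lv[2L])^2
    } else {
      d2 <- (v[, 1L] - lmxy[nm, "x"])^2 + (v[, 2L] - lmxy[nm, "y"])^2
    }
    lmidx[[nm]] <- which.min(d2)
  }
  if (anyDuplicated(lmidx))
    stop("resolution too coarse to place 26 distinct landmarks")
  new("FaceTemplate", mesh = mesh, landmarkIndex = lmidx, dictionary = dict,
      resolution = as.numeric(resolution))
}

#' Template landmark coordinates
#'
#' @param template a \linkS4class{FaceTemplate}.
#' @return a \linkS4class{LandmarkSet} at the template's landmark vertices.
#' @export
templateLandmarks <- function(template) {
  stopifnot(is(template, "FaceTemplate"))
  m <- template@mesh@vertices[template@landmarkIndex, , drop = FALSE]
  rownames(m) <- names(template@landmarkIndex)
  LandmarkSet(m, individual = "template", replicate = NA_character_)
}
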