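#' @include AllClasses.R align.R distances.R curvature.R phenotypes.R segmentation.R
NULL

#' Extract the landmark-based facial phenotype library
#'
#' Runs the landmark pipeline for a whole population: averages the two
#' landmarking replicates, aligns all individuals by GPA (no scaling), and
#' computes ten phenotype families per individual — the 78 aligned point
#' coordinates, 26 mean and 26 Gaussian landmark curvatures, 325 Euclidean,
#' 325 Manhattan and 325 geodesic distances, 32 proportion indices, 7800
#' angles, 2600 triangle areas, and convex-hull volumes and surface areas
#' of 10 facial regions. Rotation-dependent families (points, Manhattan)
#' use the GPA consensus frame; surface families (curvature, geodesics)
#' use each individual's mesh.
#'
#' @param population a \linkS4class{FacePopulation}.
#' @param indexBattery proportion-index definitions
#'   (default \code{\link{defaultIndexBattery}}).
#' @param regions hull region definitions
#'   (default \code{\link{defaultRegionDefinitions}}).
#' @param curvatureRadius quadric-fit radius (mm, default 10).
#' @param geodesics,curvatures set FALSE to skip the mesh-based families
#'   (e.g. for landmark-only populations).
#' @param alignment optional precomputed \linkS4class{ProcrustesAlignment}.
#' @return a \linkS4class{FacePhenotypes}.
#' @export
extractPhenotypes <- function(population,
                              indexBattery = defaultIndexBattery(),
                              regions = defaultRegionDefinitions(),
                              curvatureRadius = 10,
                              geodesics = length(population@meshes) > 0,
                              curvatures = length(population@meshes) > 0,
                              alignment = NULL) {
  stopifnot(is(population, "FacePopulation"))
  avg <- mapply(averageReplicates, population@landmarksA,
                population@landmarksB, SIMPLIFY = FALSE)
  if (is.null(alignment)) alignment <- gpa(avg)
  n <- length(avg)
  lmn <- rownames(coords(avg[[1L]]))
  rows <- vector("list", n)
  cat_tpl <- NULL
  for (i in seq_len(n)) {
    al <- LandmarkSet(alignment@aligned[, , i],
                      individual = avg[[i]]@individual)
    pts <- as.vector(coords(al))
    names(pts) <- paste0("Point_", rep(lmn, 3L), "_",
                         rep(c("x", "y", "z"), each = length(lmn)))
    euc <- euclideanDistances(al); names(euc) <- paste0("Euc_", names(euc))
    man <- manhattanDistances(al); names(man) <- paste0("Man_", names(man))
    idxv <- proportionIndices(stats::setNames(euc, sub("^Euc_", "", names(euc))),
                              indexBattery)
    names(idxv) <- paste0("Index_", names(idxv))
    ang <- angleMeasurements(al); names(ang) <- paste0("Ang_", names(ang))
    tri <- triangleAreas(al); names(tri) <- paste0("Tri_", names(tri))
    hull <- regionVolumeSurface(al, regions)
    vol <- stats::setNames(hull$volume, paste0("Vol_", hull$region))
    sar <- stats::setNames(hull$surface_area, paste0("Surf_", hull$region))
    vals <- c(pts, euc, man, idxv, ang, tri, vol, sar)
    cats <- c(rep("Point", length(pts)), rep("Euclidean", length(euc)),
              rep("Manhattan", length(man)), rep("Index", length(idxv)),
              rep("Angle", length(ang)), rep("Triangle_area", length(tri)),
              rep("Volume", length(vol)), rep("Surface_area", length(sar)))
    if (curvatures || geodesics) {
      mesh <- population@meshes[[i]]
      if (curvatures) {
        cv <- landmarkCurvatures(mesh, avg[[i]], radius = curvatureRadius)
        mc <- stats::setNames(cv$MC, paste0("MeanCur_", cv$landmark))
        gc_ <- stats::setNames(cv$GC, paste0("GauCur_", cv$landmark))
        vals <- c(vals, mc, gc_)
        cats <- c(cats, rep("Curvature", length(mc) + length(gc_)))
      }
      if (geodesics) {
        geo <- geodesicDistances(mesh, avg[[i]])
        names(geo) <- paste0("Geod_", names(geo))
        vals <- c(vals, geo)
        cats <- c(cats, rep("Geodesic", length(geo)))
      }
    }
    rows[[i]] <- vals
    if (is.null(cat_tpl)) cat_tpl <- cats
  }
  M <- do.call(rbind, rows)
  rownames(M) <- vapply(avg, function(s) s@individual, "")
  units <- c(Point = "mm", Curvature = "1/mm", Euclidean = "mm",
             Manhattan = "mm", Geodesic = "mm", Index = "%",
             Angle = "deg", Triangle_area = "mm^2", Volume = "mm^3",
             Surface_area = "mm^2")[cat_tpl]
  units[cat_tpl == "Curvature" & startsWith(colnames(M), "GauCur_")] <- "1/mm^2"
  FacePhenotypes(M, category = cat_tpl, units = unname(units),
                 sampleData = as.data.frame(population@sampleData))
}

#' Extract the segmentation-based facial phenotype library
#'
#' Runs the computer-aided (global-to-local) pipeline: dense displacement
#' fields in the consensus frame, RV-coefficient vertex similarity,
#' hierarchical spectral segmentation (127 segments at 7 levels), and per
#' segment the parallel-analysis principal-component scores, the surface
#' area on each individual's mesh, and Moran's I of the z coordinate, mean
#' curvature and Gaussian curvature over the segment's (x, y) locations.
#'
#' @param population a \linkS4class{FacePopulation} with meshes in template
#'   correspondence.
#' @param hierarchy optional precomputed \linkS4class{SegmentHierarchy}.
#' @param levels,minSize segmentation depth and guard (defaults 7, 10).
#' @param nNull parallel-analysis permutations (default 100).
#' @param seed RNG seed for the parallel-analysis null.
#' @param moran compute the three Moran's I families (default TRUE).
#' @param curvatureRadius per-vertex quadric radius for the curvature
#'   attributes (mm, default 8).
#' @param moranK neighbours for the spatial weights (default 8).
#' @return list(phenotypes = \linkS4class{FacePhenotypes},
#'   hierarchy = \linkS4class{SegmentHierarchy}, fields = array).
#' @export
segmentPhenotypes <- function(population, hierarchy = NULL, levels = 7L,
                              minSize = 10L, nNull = 100L, seed = 1L,
                              moran = TRUE, curvatureRadius = 8,
                              moranK = 8L) {
  fields <- displacementField(population)
  if (is.null(hierarchy)) {
    sim <- vertexSimilarity(fields)
    hierarchy <- hierarchicalSegmentation(sim, levels = levels,
                                          minSize = minSize)
  }
  tpl <- population@template
  n <- dim(fields)[3L]
  ids <- dimnames(fields)[[3L]]
  segids <- hierarchy@table$id
  vals <- list(); cats <- character(0)
  # principal components per segment (parallel analysis retention)
  for (sid in segids) {
    mem <- segmentMembers(hierarchy, sid)
    pc <- segmentPCA(fields, mem, nNull = nNull, seed = seed + sid)
    if (pc$nRetained > 0L) {
      sc <- pc$scores
      colnames(sc) <- sprintf("Module_%d_PC%d", sid, seq_len(ncol(sc)))
      vals[[length(vals) + 1L]] <- sc
      cats <- c(cats, rep("Module_PCs", ncol(sc)))
    }
  }
  # per-individual segment surface areas
  areas <- t(vapply(seq_len(n), function(i)
    segmentSurfaceAreas(population@meshes[[i]], hierarchy),
    numeric(length(segids))))
  colnames(areas) <- sprintf("Module_%d_area", segids)
  rownames(areas) <- ids
  vals[[length(vals) + 1L]] <- areas
  cats <- c(cats, rep("Module_surf_area", ncol(areas)))
  if (moran) {
    tv <- vertices(tpl)
    Ws <- lapply(segids, function(sid) {
      mem <- segmentMembers(hierarchy, sid)
      if (length(mem) >= 5L) spatialWeights(tv[mem, 1:2, drop = FALSE],
                                            k = moranK) else NULL
    })
    names(Ws) <- as.character(segids)
    nb <- meshNeighborhoods(tpl@mesh, curvatureRadius)
    mz <- mm <- mg <- matrix(NA_real_, n, length(segids),
                             dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      mesh <- population@meshes[[i]]
      cv <- vertexCurvatures(mesh, nb)
      zc <- mesh@vertices[, 3L]
      for (s in seq_along(segids)) {
        W <- Ws[[s]]
        if (is.null(W)) next
        mem <- segmentMembers(hierarchy, segids[s])
        mz[i, s] <- moranI(zc[mem], W)
        mcv <- cv$MC[mem]; gcv <- cv$GC[mem]
        if (stats::var(mcv, na.rm = TRUE) > 0 && !anyNA(mcv))
          mm[i, s] <- moranI(mcv, W)
        if (stats::var(gcv, na.rm = TRUE) > 0 && !anyNA(gcv))
          mg[i, s] <- moranI(gcv, W)
      }
    }
    colnames(mz) <- sprintf("Module_%d_mor_z", segids)
    colnames(mm) <- sprintf("Module_%d_mor_mea", segids)
    colnames(mg) <- sprintf("Module_%d_mor_gau", segids)
    vals <- c(vals, list(mz, mm, mg))
    cats <- c(cats, rep("Module_mor_z", ncol(mz)),
              rep("Module_mor_mea", ncol(mm)),
              rep("Module_mor_gau", ncol(mg)))
  }
  M <- do.call(cbind, vals)
  units <- rep("score", ncol(M))
  units[cats == "Module_surf_area"] <- "mm^2"
  units[startsWith(cats, "Module_mor")] <- "I"
  ph <- FacePhenotypes(M, category = cats, units = units,
                       sampleData = as.data.frame(population@sampleData))
  list(phenotypes = ph, hierarchy = hierarchy, fields = fields)
}

#' Combine phenotype containers over the same individuals
#'
#' Row-binds (phenotype-wise) two or more \linkS4class{FacePhenotypes}
#' objects sharing the same individuals, e.g. the landmark and segmentation
#' libraries.
#'
#' @param ... \linkS4class{FacePhenotypes} objects.
#' @return a \linkS4class{FacePhenotypes}.
#' @export
bindPhenotypes <- function(...) {
  xs <- list(...)
  out <- do.call(rbind, xs)
  new("FacePhenotypes", out)
}
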