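#' @include AllClasses.R dictionary.R
NULL

#' Read a triangle mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (1-based indices on disk) and PLY in ascii or
#' binary little-endian form. Faces must be triangles; quads or dangling
#' vertex references raise a format error naming the offending element.
#'
#' @param path path to a .obj or .ply file.
#' @return a \linkS4class{SurfaceMesh} (1-based indices internally).
#' @seealso \code{\link{writeMesh}}
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = .read_obj(path),
    ply = .read_ply(path),
    stop("unsupported mesh format: .", ext, " (expected .obj or .ply)"))
  validObject(mesh)
  mesh
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3L,
              byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f ", "", fl)), "[[:space:]]+")
  nvert <- lengths(ftok)
  if (any(nvert != 3L))
    stop(sprintf("non-triangular face at f-record %d (%d vertices)",
                 which(nvert != 3L)[1L], nvert[nvert != 3L][1L]))
  # OBJ allows v/vt/vn triplets; the vertex index is the first field
  idx <- vapply(ftok, function(tk) as.integer(sub("/.*$", "", tk)), integer(3L))
  f <- t(idx)
  if (any(f < 1L) || any(f > nrow(v)))
    stop(sprintf("face %d references vertex %d of a %d-vertex file",
                 which(apply(f, 1L, function(r) any(r < 1L | r > nrow(v))))[1L],
                 f[f < 1L | f > nrow(v)][1L], nrow(v)))
  SurfaceMesh(v, f)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("truncated PLY header")
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE))
  fmt <- strsplit(fmt, " ")[[1L]][1L]
  el <- grep("^element ", hdr)
  elems <- do.call(rbind, lapply(strsplit(hdr[el], " "), function(x)
    data.frame(name = x[2L], count = as.integer(x[3L]))))
  props <- lapply(seq_along(el), function(i) {
    to <- if (i < length(el)) el[i + 1L] - 1L else length(hdr) - 1L
    grep("^property ", hdr[el[i]:to], value = TRUE)
  })
  names(props) <- elems$name
  if (!all(c("vertex", "face") %in% elems$name))
    stop("PLY file must declare vertex and face elements")
  nv <- elems$count[elems$name == "vertex"]
  nf <- elems$count[elems$name == "face"]
  vprop <- sub("^property ", "", props$vertex)
  vtypes <- vapply(strsplit(vprop, " "), `[`, "", 1L)
  vnames <- vapply(strsplit(vprop, " "), `[`, "", 2L)
  if (fmt == "ascii") {
    body <- readLines(con)
    vdat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                   nrow = nv, byrow = TRUE)
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
    cnt <- vapply(ftok, function(x) as.integer(x[1L]), 1L)
    if (any(cnt != 3L))
      stop(sprintf("non-triangular face at record %d", which(cnt != 3L)[1L]))
    f <- t(vapply(ftok, function(x) as.integer(x[2:4]), integer(3L))) + 1L
  } else if (fmt == "binary_little_endian") {
    sz <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
            ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
            int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L, double = 8L,
            float64 = 8L)
    vdat <- matrix(NA_real_, nv, length(vtypes))
    for (i in seq_len(nv)) for (j in seq_along(vtypes)) {
      tp <- vtypes[j]
      vdat[i, j] <- if (tp %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", 1L, size = sz[[tp]], endian = "little")
      else readBin(con, "integer", 1L, size = sz[[tp]], endian = "little")
    }
    fprop <- strsplit(sub("^property list ", "", props$face[1L]), " ")[[1L]]
    csz <- sz[[fprop[1L]]]; isz <- sz[[fprop[2L]]]
    f <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1L, size = csz, endian = "little",
                     signed = csz > 1L)
      if (cnt != 3L) stop(sprintf("non-triangular face at record %d", i))
      f[i, ] <- readBin(con, "integer", 3L, size = isz, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z properties")
  if (any(f < 1L) || any(f > nv))
    stop(sprintf("face references vertex %d of a %d-vertex file",
                 max(f) - 1L, nv))
  SurfaceMesh(vdat[, xyz, drop = FALSE], f)
}

#' Write a triangle mesh to OBJ or ascii PLY
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output path; format chosen by extension (.obj or .ply).
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  stopifnot(is(mesh, "SurfaceMesh"))
  v <- mesh@vertices; f <- mesh@faces
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
               con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' Read a landmark CSV
#'
#' Expects a comma-separated file with header \code{name,x,y,z} and
#' optionally a \code{replicate} column; coordinates are in mm. Rows are
#' reordered to dictionary order; missing, unknown or duplicated landmark
#' names raise an error listing the names.
#'
#' @param path path to the CSV.
#' @param dictionary a \linkS4class{LandmarkDictionary}.
#' @param individual individual id; default: file name without extension.
#' @param replicate replicate id; default: the \code{replicate} column if
#'   present, else a trailing \code{_rep<k>} in the file name, else NA.
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path, dictionary = defaultLandmarkDictionary(),
                          individual = NULL, replicate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns name,x,y,z (got: ",
         paste(names(d), collapse = ","), ")")
  for (cc in c("x", "y", "z"))
    if (!is.numeric(d[[cc]]))
      stop("non-numeric ", cc, " coordinate in ", path)
  base <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(replicate)) {
    replicate <- if ("replicate" %in% names(d)) as.character(d$replicate[1L])
    else if (grepl("_rep[0-9]+$", base)) sub("^.*_rep([0-9]+)$", "\\1", base)
    else NA_character_
  }
  if (is.null(individual))
    individual <- sub("_rep[0-9]+$", "", base)
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$name
  LandmarkSet(m, individual = individual, replicate = replicate,
              dictionary = dictionary)
}

#' Write a landmark CSV
#'
#' @param lms a \linkS4class{LandmarkSet}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLandmarks <- function(lms, path) {
  stopifnot(is(lms, "LandmarkSet"))
  d <- data.frame(name = rownames(lms@coords), lms@coords,
                  replicate = lms@replicate, row.names = NULL)
  if (all(is.na(d$replicate))) d$replicate <- NULL
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.meta_path <- function(path) sub("(\\.[^.]*)?$", ".meta.tsv",
                                 sub("\\.tsv$", "", path))

#' Write a phenotype matrix as TSV with a metadata sidecar
#'
#' Writes individuals as rows and phenotypes as columns (plus leading id,
#' region, sex, age columns) with literal \code{NA} tokens for missing
#' values, and a sidecar \code{<path minus .tsv>.meta.tsv} listing phenotype
#' id, category and units. \code{readPhenotypes} restores an identical
#' object.
#'
#' @param x a \linkS4class{FacePhenotypes}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePhenotypes <- function(x, path) {
  stopifnot(is(x, "FacePhenotypes"))
  vals <- t(SummarizedExperiment::assay(x))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  lead <- data.frame(id = colnames(x))
  for (cc in c("region", "sex", "age"))
    if (cc %in% names(cd)) lead[[cc]] <- cd[[cc]]
  out <- cbind(lead, as.data.frame(vals, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  meta <- data.frame(phenotype = rownames(x), category = rd$category,
                     units = rd$units)
  utils::write.table(meta, .meta_path(path), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phenotype TSV written by \code{writePhenotypes}
#'
#' @param path the TSV path (sidecar found automatically).
#' @return a \linkS4class{FacePhenotypes}.
#' @export
readPhenotypes <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(.meta_path(path), stringsAsFactors = FALSE)
  lead <- intersect(c("id", "region", "sex", "age"), names(d))
  vals <- as.matrix(d[, setdiff(names(d), lead), drop = FALSE])
  rownames(vals) <- d$id
  if (!identical(colnames(vals), as.character(meta$phenotype)))
    stop("phenotype columns do not match metadata sidecar")
  FacePhenotypes(vals, category = meta$category, units = meta$units,
                 sampleData = d[, setdiff(lead, "id"), drop = FALSE])
}

#' Construct a FacePhenotypes container
#'
#' @param values numeric matrix, individuals x phenotypes (rownames ids,
#'   colnames phenotype ids).
#' @param category per-phenotype category tag; one of
#'   \code{PHENOTYPE_CATEGORIES}.
#' @param units per-phenotype units string.
#' @param sampleData optional data.frame of per-individual covariates
#'   (region, sex, age).
#' @return a \linkS4class{FacePhenotypes} (phenotypes x individuals inside).
#' @export
FacePhenotypes <- function(values, category, units = NA_character_,
                           sampleData = NULL) {
  values <- as.matrix(values)
  category <- rep_len(category, ncol(values))
  units <- rep_len(units, ncol(values))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = rownames(values))
        else S4Vectors::DataFrame(sampleData, row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(phenotypes = t(values)),
    rowData = S4Vectors::DataFrame(category = category, units = units,
                                   row.names = colnames(values)),
    colData = cd)
  new("FacePhenotypes", se)
}

#' Extract the individuals-by-phenotypes value matrix
#'
#' @param x a \linkS4class{FacePhenotypes}.
#' @return numeric matrix, individuals x phenotypes.
#' @export
phenotypeValues <- function(x) t(SummarizedExperiment::assay(x))

#' Per-phenotype category tags
#'
#' @param x a \linkS4class{FacePhenotypes}.
#' @return character vector of category tags, named by phenotype.
#' @export
phenotypeCategories <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$category, rownames(x))
}
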