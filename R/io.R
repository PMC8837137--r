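infer_mesh_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("ply", "stl", "obj")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop(sprintf("cannot infer mesh format from extension '%s'", ext))
  ext
}

#' Read a triangulated mesh (PLY, STL or OBJ)
#'
#' Coordinates are assumed to be millimetres (a warning notes the assumption
#' for formats without unit metadata, i.e. all of them). STL files store
#' faces independently; identical vertex coordinates are merged on read so
#' topology checks are meaningful.
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"` or `"obj"`; inferred from the extension by
#'   default.
#' @param frame frame label to attach.
#' @return A [triangle_mesh()] with a `validation` attribute
#'   (see [validate_mesh()]).
#' @export
read_mesh <- function(path, format = NULL, frame = "world") {
  format <- infer_mesh_format(path, format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  mesh <- switch(format, ply = read_ply(path, frame), stl = read_stl(path, frame),
                 obj = read_obj(path, frame))
  attr(mesh, "validation") <- validate_mesh(mesh)
  mesh
}

#' Write a triangulated mesh (PLY, STL or OBJ)
#'
#' Binary little-endian PLY (lossless doubles) is the canonical interchange;
#' STL (binary or ASCII) is provided for interoperability despite its
#' single-precision loss.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format inferred from the extension unless given.
#' @param format `"ply"`, `"stl"` or `"obj"`.
#' @param binary binary (default) or ASCII encoding, for PLY/STL.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- infer_mesh_format(path, format)
  switch(format,
         ply = write_ply(mesh, path, binary),
         stl = write_stl(mesh, path, binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment units mm",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      paste(c(3L, f), collapse = " ")), con)
  }
}

read_ply <- function(path, frame) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY parse error: truncated header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 200L) stop("PLY parse error: header too long")
  }
  if (hdr[1] != "ply") stop("PLY parse error: missing 'ply' magic")
  fmt <- grep("^format ", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  if (is.na(nv) || is.na(nf)) stop("PLY parse error: missing element counts")
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  dbl <- grepl("double", vprops[1])
  if (binary) {
    verts <- matrix(readBin(con, "double", nv * 3L, size = if (dbl) 8L else 4L,
                            endian = "little"), ncol = 3, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1L))
      if (length(cnt) == 0L) stop("PLY parse error: truncated face data")
      if (cnt != 3L) stop("PLY parse error: only triangle faces supported")
      faces[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    }
  } else {
    txt <- readLines(con)
    if (length(txt) < nv + nf) stop("PLY parse error: truncated body")
    verts <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(nv)]), "\\s+"))),
                    ncol = 3, byrow = TRUE)
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(s) as.integer(s[2:4]), integer(3)))
  }
  triangle_mesh(verts, faces + 1L, frame = frame)
}

write_stl <- function(mesh, path, binary = TRUE) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  n <- face_normals(mesh)
  nf <- nrow(mesh$faces)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    tri <- cbind(n, a, b, c)
    for (i in seq_len(nf)) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    fmt <- function(v) paste(format(v, digits = 9, scientific = TRUE, trim = TRUE),
                             collapse = " ")
    for (i in seq_len(nf)) {
      writeLines(c(sprintf("  facet normal %s", fmt(n[i, ])),
                   "    outer loop",
                   sprintf("      vertex %s", fmt(a[i, ])),
                   sprintf("      vertex %s", fmt(b[i, ])),
                   sprintf("      vertex %s", fmt(c[i, ])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
}

merge_duplicate_vertices <- function(tri_coords, frame) {
  # tri_coords: (3*nf) x 3, rows grouped per face
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3])
  uid <- match(key, key)
  keep <- !duplicated(uid)
  verts <- tri_coords[keep, , drop = FALSE]
  remap <- match(uid, which(keep))
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, frame = frame)
}

read_stl <- function(path, frame) {
  size <- file.size(path)
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (!is_ascii && size >= 84) {
    nf <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (size != 84 + 50 * nf) stop("STL parse error: truncated binary file")
    tri <- matrix(NA_real_, 3L * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12L, size = 4, endian = "little")
      readBin(con, "raw", 2L)
      tri[3 * i - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    return(merge_duplicate_vertices(tri, frame))
  }
  close(con); on.exit()
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("STL parse error: malformed ASCII facet list")
  tri <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                         function(s) s[2:4]))),
                ncol = 3, byrow = TRUE)
  merge_duplicate_vertices(tri, frame)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(v)
    paste("v", paste(format(v, digits = 17, trim = TRUE), collapse = " "))), con)
  writeLines(apply(mesh$faces, 1, function(f)
    paste("f", paste(f, collapse = " "))), con)
}

read_obj <- function(path, frame) {
  txt <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", txt, value = TRUE)), "\\s+")
  fl <- strsplit(trimws(grep("^f\\s", txt, value = TRUE)), "\\s+")
  if (length(vl) == 0L || length(fl) == 0L)
    stop("OBJ parse error: no vertices or faces found")
  verts <- t(vapply(vl, function(s) as.numeric(s[2:4]), numeric(3)))
  faces <- t(vapply(fl, function(s)
    as.integer(sub("/.*$", "", s[2:4])), integer(3)))
  triangle_mesh(verts, faces, frame = frame)
}

#' Read a labeled point set (CSV or JSON)
#'
#' CSV dialect: header `label,x,y,z`, coordinates in mm. JSON dialect: an
#' object with `frame` and `points` (records with `label`, `x`, `y`, `z`).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"json"`; inferred from the extension.
#' @param frame frame label (CSV carries none).
#' @return A [point_set()].
#' @export
read_points <- function(path, dialect = NULL, frame = "world") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(dialect))
    dialect <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(path)
    pts <- obj$points
    if (is.null(pts) || nrow(pts) == 0L) stop("empty point set in JSON input")
    return(point_set(cbind(pts$x, pts$y, pts$z),
                     frame = if (!is.null(obj$frame)) obj$frame else frame,
                     labels = pts$label))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty point-set file")
  need <- c("label", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  for (cn in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate at data row %d", cn, bad[1]))
    df[[cn]] <- v
  }
  point_set(cbind(df$x, df$y, df$z), frame = frame, labels = as.character(df$label))
}

#' Write a labeled point set (CSV or JSON)
#'
#' @param points a [point_set()].
#' @param path output path; dialect inferred from the extension.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, dialect = NULL) {
  stopifnot(inherits(points, "point_set"))
  if (is.null(dialect))
    dialect <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  m <- ps_coords(points)
  labels <- attr(points, "labels")
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(m)))
  df <- data.frame(label = labels, x = m[, 1], y = m[, 2], z = m[, 3])
  if (dialect == "json") {
    jsonlite::write_json(list(frame = attr(points, "frame"), points = df),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read/write a rigid transform as JSON
#'
#' JSON dialect: `rotation` (9 entries, row-major), `translation` (3), and
#' `scale`.
#'
#' @param t a [rigid_transform()].
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [rigid_transform()].
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(rotation = as.numeric(t(t$rotation)),
                            translation = t$translation, scale = t$scale,
                            frame = t$frame),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation,
                  if (is.null(obj$scale)) 1 else obj$scale,
                  frame = obj$frame)
}

#' Write a binary occupancy mask as NIfTI-1
#'
#' The affine encodes the grid's voxel-center origin convention: world
#' position of voxel (i,j,k) center = `origin + spacing * (i,j,k)`.
#'
#' @param volume integer/logical array matching `grid$dims`.
#' @param grid an [image_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(volume, grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  if (!identical(dim(volume), as.integer(grid$dims)))
    stop("volume dimensions do not match the grid")
  img <- RNifti::asNifti(array(as.integer(volume != 0), dim = grid$dims))
  RNifti::pixdim(img) <- grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI binary mask back into a volume and grid
#'
#' @param path NIfTI file written by [write_mask()] (axis-aligned affine).
#' @return List with `volume` (integer array) and `grid` ([image_grid()]).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vol <- array(as.integer(img), dim = dim(img))
  grid <- image_grid(aff[1:3, 4], diag(aff[1:3, 1:3]), dim(vol))
  list(volume = vol, grid = grid)
}

#' Read/write a contour stack (JSON or CSV)
#'
#' JSON carries the degree/closed/plane metadata directly; the CSV dialect
#' stores per-slice records `slice_index, z_mm, point_index, x_mm, y_mm`
#' plus constant `degree`, `closed` and `plane` columns.
#'
#' @param stack a [contour_stack()].
#' @param path file path.
#' @return `write_contour_stack` returns `path` invisibly;
#'   `read_contour_stack` returns a [contour_stack()].
#' @export
write_contour_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  dialect <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  rows <- do.call(rbind, lapply(seq_along(stack$contours), function(i) {
    cp <- stack$contours[[i]]$control_points
    data.frame(slice_index = i, z_mm = stack$slice_positions[i],
               point_index = seq_len(nrow(cp)), x_mm = cp[, 1], y_mm = cp[, 2])
  }))
  if (dialect == "json") {
    jsonlite::write_json(list(plane = stack$plane, frame = stack$frame,
                              degree = stack$contours[[1]]$degree,
                              closed = stack$contours[[1]]$closed,
                              records = rows),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    rows$degree <- stack$contours[[1]]$degree
    rows$closed <- stack$contours[[1]]$closed
    rows$plane <- stack$plane
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_contour_stack
#' @export
read_contour_stack <- function(path) {
  dialect <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(path)
    rows <- obj$records
    degree <- obj$degree; closed <- obj$closed; plane <- obj$plane
    frame <- if (!is.null(obj$frame)) obj$frame else "world"
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
    degree <- rows$degree[1]; closed <- as.logical(rows$closed[1])
    plane <- rows$plane[1]; frame <- "world"
  }
  sl <- split(rows, rows$slice_index)
  ord <- order(as.integer(names(sl)))
  contours <- lapply(sl[ord], function(d)
    bspline_contour(cbind(d$x_mm, d$y_mm)[order(d$point_index), , drop = FALSE],
                    degree = degree, closed = closed))
  zs <- vapply(sl[ord], function(d) d$z_mm[1], 0)
  contour_stack(unname(contours), unname(zs), plane = plane, frame = frame)
}
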