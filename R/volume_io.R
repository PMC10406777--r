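# File I/O: volumes (NIfTI via RNifti, MetaImage), tetrahedral meshes
# (VTK legacy ASCII), surface meshes (ASCII PLY) and the model container
# (JSON with full-precision numbers). All readers enforce the package's
# identity-orientation convention and 0-based voxel-center world mapping.

file_ext_of <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii\\.gz$", lp)) return("nii.gz")
  sub(".*\\.", "", lp)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha`, `.mhd`). Intensities are returned unmodified (no rescaling).
#' Files with a non-identity orientation matrix are rejected: the package's
#' world convention is `origin + index * spacing` with 0-based indices at
#' voxel centers.
#'
#' @param path path to an existing image file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  ext <- file_ext_of(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("I/O error reading NIfTI file '",
                                             path, "': ", conditionMessage(e)))
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop("expected a 3D volume, got ", length(dim(a)), "D data in ", path)
    xf <- RNifti::xform(img)
    rot <- xf[1:3, 1:3]
    sp <- RNifti::pixdim(img)[1:3]
    if (max(abs(rot - diag(sp))) > 1e-4 * max(sp))
      stop("non-identity orientation matrix in ", path,
           "; only identity direction cosines are supported")
    volume_image(a, spacing = sp, origin = xf[1:3, 4])
  } else if (ext %in% c("mha", "mhd")) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format '.", ext, "' (use .nii, .nii.gz, .mha or .mhd)")
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Data are written as 64-bit floats so round-trips are bit-exact
#' (NaN included). The identity orientation plus spacing and origin are
#' stored in the format's native header fields.
#'
#' @param img a [volume_image()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  if (!dir.exists(dirname(path)))
    stop("I/O error: parent directory does not exist: ", dirname(path))
  ext <- file_ext_of(path)
  if (ext %in% c("nii", "nii.gz")) {
    a <- img$data
    storage.mode(a) <- "double"
    attr(a, "pixdim") <- img$spacing
    ni <- RNifti::asNifti(a, datatype = "double")
    m <- diag(c(img$spacing, 1))
    m[1:3, 4] <- img$origin
    RNifti::qform(ni) <- structure(m, code = 2L)
    RNifti::sform(ni) <- structure(m, code = 2L)
    ok <- tryCatch({ RNifti::writeNifti(ni, path); TRUE },
                   error = function(e) stop("I/O error writing NIfTI file '",
                                            path, "': ", conditionMessage(e)))
    invisible(ok)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(img, path)
  } else {
    stop("unsupported volume format '.", ext, "'")
  }
}

# ---- MetaImage (.mha local-data / .mhd + .raw) ----

metaimage_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),
  MET_SHORT  = list(what = "integer", size = 2L),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L)
)

read_metaimage <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header is ASCII up to and including the ElementDataFile line
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  hdr_lines <- character(0)
  prev <- 0L
  for (pos in nl) {
    line <- rawToChar(raw_all[(prev + 1L):(pos - 1L)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    prev <- pos
    if (grepl("^\\s*ElementDataFile", line)) { hdr_end <- pos; break }
  }
  if (is.na(hdr_end)) stop("I/O error: malformed MetaImage header in ", path)
  kv <- strsplit(hdr_lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  h <- stats::setNames(vals, keys)
  if (!is.na(h["CompressedData"]) && toupper(h["CompressedData"]) == "TRUE")
    stop("I/O error: compressed MetaImage data is not supported (", path, ")")
  ndims <- as.integer(h["NDims"])
  if (is.na(ndims) || ndims != 3L)
    stop("expected a 3D volume, got ", ndims, "D data in ", path)
  dm <- as.integer(strsplit(h["DimSize"], "\\s+")[[1]])
  sp <- if (!is.na(h["ElementSpacing"]))
    as.numeric(strsplit(h["ElementSpacing"], "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.na(h["Offset"]))
    as.numeric(strsplit(h["Offset"], "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.na(h["TransformMatrix"])) {
    tm <- as.numeric(strsplit(h["TransformMatrix"], "\\s+")[[1]])
    if (max(abs(tm - as.vector(diag(3)))) > 1e-9)
      stop("non-identity orientation matrix in ", path,
           "; only identity direction cosines are supported")
  }
  tt <- metaimage_types[[h["ElementType"]]]
  if (is.null(tt)) stop("I/O error: unsupported MetaImage ElementType ",
                        h["ElementType"], " in ", path)
  n <- prod(dm)
  df <- h["ElementDataFile"]
  if (toupper(df) == "LOCAL") {
    data_raw <- raw_all[(hdr_end + 1L):length(raw_all)]
  } else {
    data_raw <- readBin(file.path(dirname(path), df), "raw",
                        n = n * tt$size)
  }
  signed <- if (is.null(tt$signed)) TRUE else tt$signed
  vals_num <- readBin(data_raw, tt$what, n = n, size = tt$size,
                      signed = signed, endian = "little")
  volume_image(array(as.numeric(vals_num), dim = dm), spacing = sp, origin = org)
}

write_metaimage <- function(img, path) {
  ext <- file_ext_of(path)
  local_data <- ext == "mha"
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(img$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(img$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(img$data), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name)
  )
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error opening '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(img$data), con, size = 8L, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(as.numeric(img$data), rawcon, size = 8L, endian = "little")
  }
  invisible(TRUE)
}

# ---- meshes ----

#' Read a mesh file
#'
#' Tetrahedral meshes are read from VTK legacy ASCII unstructured grids
#' (cell type 10 only); triangular surfaces from ASCII PLY. Vertex order is
#' preserved: across-population correspondence is positional.
#'
#' @param path `.vtk` (tetrahedral) or `.ply` (surface) file.
#' @return A [tet_mesh()] or `surface_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  ext <- file_ext_of(path)
  switch(ext,
         vtk = read_vtk_tet(path),
         ply = read_ply_surface(path),
         stop("unsupported mesh format '.", ext, "' (use .vtk or .ply)"))
}

#' Write a mesh file
#'
#' @param mesh a [tet_mesh()] (written as VTK legacy ASCII) or a
#'   `surface_mesh` (written as ASCII PLY).
#' @param path output path; extension must match the mesh kind.
#' @export
write_mesh <- function(mesh, path) {
  ext <- file_ext_of(path)
  if (inherits(mesh, "tet_mesh")) {
    if (ext != "vtk") stop("tetrahedral meshes are written as .vtk")
    write_vtk_tet(mesh, path)
  } else if (inherits(mesh, "surface_mesh")) {
    if (ext != "ply") stop("surface meshes are written as .ply")
    write_ply_surface(mesh, path)
  } else stop("mesh must be a tet_mesh or surface_mesh")
}

read_vtk_tet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- scan(text = paste(lines[-(1:2)], collapse = "\n"), what = "character",
               quiet = TRUE)
  eat <- function(i, n) toks[i:(i + n - 1L)]
  ip <- which(toupper(toks) == "POINTS")
  if (length(ip) != 1L) stop("format error: no POINTS section in ", path)
  nv <- as.integer(toks[ip + 1L])
  verts <- matrix(as.numeric(eat(ip + 3L, 3L * nv)), ncol = 3L, byrow = TRUE)
  ic <- which(toupper(toks) == "CELLS")
  if (length(ic) != 1L) stop("format error: no CELLS section in ", path)
  nc <- as.integer(toks[ic + 1L])
  sz <- as.integer(toks[ic + 2L])
  cell_ints <- as.integer(eat(ic + 3L, sz))
  it <- which(toupper(toks) == "CELL_TYPES")
  if (length(it) != 1L) stop("format error: no CELL_TYPES section in ", path)
  types <- as.integer(eat(it + 2L, nc))
  if (any(types != 10L))
    stop("format error: non-tetrahedral cells (VTK types ",
         paste(unique(types[types != 10L]), collapse = ","), ") in ", path)
  if (sz != 5L * nc)
    stop("format error: tetrahedral CELLS section has wrong size in ", path)
  conn <- matrix(cell_ints, ncol = 5L, byrow = TRUE)
  if (any(conn[, 1L] != 4L))
    stop("format error: cells are not 4-vertex tetrahedra in ", path)
  tet_mesh(verts, conn[, 2:5, drop = FALSE] + 1L)
}

write_vtk_tet <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral mesh written by ssimaug",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1L,
                   function(v) paste(sprintf("%.17g", v), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(apply(mesh$tets - 1L, 1L,
                   function(t) paste(c(4L, t), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  invisible(TRUE)
}

#' Triangular surface mesh
#'
#' @param vertices V x 3 numeric matrix of world mm coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

read_ply_surface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (tolower(trimws(lines[1])) != "ply" ||
      !grepl("ascii", tolower(lines[2])))
    stop("format error: not an ASCII PLY file: ", path)
  hend <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(hend)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv)) stop("format error: PLY without vertex element: ", path)
  if (is.na(nf)) nf <- 0L
  body <- lines[(hend + 1L):length(lines)]
  vtoks <- scan(text = paste(body[seq_len(nv)], collapse = "\n"), quiet = TRUE)
  verts <- matrix(vtoks, ncol = length(vtoks) / nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    frows <- lapply(body[nv + seq_len(nf)], function(l)
      as.integer(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(vapply(frows, `[`, 0L, 1L) != 3L))
      stop("format error: PLY faces must be triangles: ", path)
    faces <- do.call(rbind, lapply(frows, function(r) r[2:4])) + 1L
  }
  surface_mesh(verts, faces)
}

write_ply_surface <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1L,
                   function(v) paste(sprintf("%.17g", v), collapse = " ")), con)
  if (nf > 0L)
    writeLines(apply(mesh$faces - 1L, 1L,
                     function(f) paste(c(3L, f), collapse = " ")), con)
  invisible(TRUE)
}

# ---- model container (JSON, full IEEE precision) ----

num_to_str <- function(x) sprintf("%.17g", as.numeric(x))

array_entry <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (is.integer(x)) list(dim = as.integer(d), kind = "int",
                          values = as.integer(x))
  else list(dim = as.integer(d), kind = "double", values = num_to_str(x))
}

entry_to_array <- function(e) {
  vals <- if (identical(e$kind, "int")) as.integer(e$values)
          else as.numeric(e$values)
  d <- as.integer(e$dim)
  if (length(d) == 1L) vals else array(vals, dim = d)
}

#' Save an SSIM model container to disk
#'
#' The container is a single JSON file holding named numeric arrays plus a
#' manifest (degree, mode counts, variance fraction, mesh topology sizes).
#' Doubles are stored with 17 significant digits, so write/read round-trips
#' are bit-exact.
#'
#' @param model an `ssim_model` from [build_ssim()].
#' @param path output path (conventionally `.json`).
#' @export
save_ssim_model <- function(model, path) {
  stopifnot(inherits(model, "ssim_model"))
  ok <- vapply(list(model$shape_model$mean, model$shape_model$modes,
                    model$shape_model$eigenvalues, model$intensity_model$mean,
                    model$intensity_model$modes, model$intensity_model$eigenvalues),
               function(a) all(is.finite(a)), TRUE)
  if (!all(ok)) stop("model fields must be finite")
  n_align <- length(model$alignment)
  rot <- t(vapply(model$alignment, function(a) as.numeric(a$R), numeric(9)))
  tra <- t(vapply(model$alignment, function(a) as.numeric(a$t), numeric(3)))
  obj <- list(
    format = "ssimaug-model-1",
    manifest = list(
      degree = model$degree,
      variance_fraction = model$shape_model$variance_fraction,
      shape_modes = ncol(model$shape_model$modes),
      intensity_modes = ncol(model$intensity_model$modes),
      n_vertices = model$n_vertices,
      n_tets = nrow(model$tets),
      m_coefficients = count_coefficients(model$degree),
      n_training = n_align
    ),
    arrays = list(
      shape_mean = array_entry(model$shape_model$mean),
      shape_modes = array_entry(model$shape_model$modes),
      shape_eigenvalues = array_entry(model$shape_model$eigenvalues),
      intensity_mean = array_entry(model$intensity_model$mean),
      intensity_modes = array_entry(model$intensity_model$modes),
      intensity_eigenvalues = array_entry(model$intensity_model$eigenvalues),
      tets = array_entry(model$tets),
      alignment_rotations = array_entry(rot),
      alignment_translations = array_entry(tra)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SSIM model container
#'
#' Arrays are checked against the manifest (mode counts, feature lengths);
#' any inconsistency raises an integrity error.
#'
#' @param path file written by [save_ssim_model()].
#' @return an `ssim_model`.
#' @export
load_ssim_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ssimaug-model-1"))
    stop("integrity error: unrecognized model container format")
  man <- obj$manifest
  a <- lapply(obj$arrays, entry_to_array)
  V <- as.integer(man$n_vertices); Tt <- as.integer(man$n_tets)
  m <- count_coefficients(as.integer(man$degree))
  if (m != as.integer(man$m_coefficients))
    stop("integrity error: manifest coefficient count inconsistent with degree")
  chk <- function(cond, what) if (!cond)
    stop("integrity error: ", what, " inconsistent with manifest")
  chk(length(a$shape_mean) == 3L * V, "shape mean length")
  chk(all(dim(a$shape_modes) == c(3L * V, man$shape_modes)), "shape mode matrix")
  chk(length(a$shape_eigenvalues) == man$shape_modes, "shape eigenvalues")
  chk(length(a$intensity_mean) == Tt * m, "intensity mean length")
  chk(all(dim(a$intensity_modes) == c(Tt * m, man$intensity_modes)),
      "intensity mode matrix")
  chk(length(a$intensity_eigenvalues) == man$intensity_modes,
      "intensity eigenvalues")
  chk(all(dim(a$tets) == c(Tt, 4L)), "tet connectivity")
  align <- lapply(seq_len(as.integer(man$n_training)), function(i)
    list(R = matrix(a$alignment_rotations[i, ], 3, 3),
         t = a$alignment_translations[i, ]))
  structure(list(
    shape_model = pdm(a$shape_mean, a$shape_modes, a$shape_eigenvalues,
                      man$variance_fraction, "shape"),
    intensity_model = pdm(a$intensity_mean, a$intensity_modes,
                          a$intensity_eigenvalues, man$variance_fraction,
                          "intensity"),
    tets = a$tets,
    degree = as.integer(man$degree),
    n_vertices = V,
    alignment = align
  ), class = "ssim_model")
}
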