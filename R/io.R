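utils::globalVariables(c("dof", "value", "bound", "mu", "sigma",
                         "ci95_low", "ci95_high"))

#' Read a 3D volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) through RNifti, or MetaImage
#' (`.mhd` + raw / `.mha`, uncompressed) through a built-in reader.
#' Only axis-aligned geometries are supported: spacing is taken from the
#' header, the origin is the world position of the first voxel center.
#'
#' @param path file path.
#' @return [mmri_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: file not found: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- paste0(ext, ".gz")
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    sp <- attr(img, "pixdim")[1:3]
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    # RNifti xforms are RAS with possible axis flips; this package writes
    # (and expects) plain positive-diagonal affines
    dg <- diag(xf[1:3, 1:3])
    origin <- ifelse(dg < 0, origin + (dim(arr) - 1) * dg, origin)
    mmri_volume(arr, abs(sp), origin)
  } else if (ext %in% c("mhd", "mha")) {
    read_metaimage(path)
  } else {
    stop(sprintf("format error: unsupported volume format: %s", path))
  }
}

#' Write a volume as NIfTI-1
#'
#' @param vol [mmri_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mmri_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_metaimage <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  hdr <- list()
  data_start <- NULL
  for (i in seq_along(lines)) {
    kv <- regmatches(lines[i], regexec("^([A-Za-z]+) *= *(.*)$", lines[i]))[[1]]
    if (length(kv) == 3) hdr[[kv[2]]] <- trimws(kv[3])
    if (identical(hdr[["ElementDataFile"]], "LOCAL")) { data_start <- i; break }
    if (!is.null(hdr[["ElementDataFile"]]) &&
        !identical(hdr[["ElementDataFile"]], "LOCAL")) break
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("format error: corrupt MetaImage header: %s", path))
  }
  if (hdr$NDims != "3") stop("format error: only 3D MetaImage supported")
  dims <- as.integer(strsplit(hdr$DimSize, " +")[[1]])
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, " +")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, " +")[[1]]) else c(0, 0, 0)
  type <- switch(hdr$ElementType,
                 MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                 MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                 MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                 MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                 MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE),
                 stop(sprintf("format error: unsupported MetaImage element type %s",
                              hdr$ElementType)))
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    con <- file(path, "rb")
    on.exit(close(con))
    # skip the header lines (ASCII) up to and including ElementDataFile
    hdr_bytes <- sum(nchar(lines[seq_len(data_start)], type = "bytes") + 1L)
    readBin(con, "raw", hdr_bytes)
    raw_data <- readBin(con, type$what, n, size = type$size,
                        signed = type$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) {
      stop(sprintf("format error: MetaImage data file missing: %s", raw_path))
    }
    con <- file(raw_path, "rb")
    on.exit(close(con))
    raw_data <- readBin(con, type$what, n, size = type$size,
                        signed = type$signed, endian = "little")
  }
  if (length(raw_data) != n) stop("format error: truncated MetaImage data")
  mmri_volume(array(as.numeric(raw_data), dim = dims), sp, org)
}

#' Read a surface mesh (STL or PLY)
#'
#' Binary and ASCII STL (identical vertices are merged to restore
#' connectivity) and ASCII PLY with triangular faces; PLY per-vertex scalar
#' properties beyond x/y/z are returned in the `scalars` attribute.
#'
#' @param path file path.
#' @return [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") read_stl(path)
  else if (ext == "ply") read_ply(path)
  else stop(sprintf("format error: unsupported mesh format: %s", path))
}

#' Write a surface mesh (STL or PLY)
#'
#' @param mesh [surface_mesh].
#' @param path output path; format chosen by extension (`.stl` binary,
#'   `.ply` ASCII).
#' @param scalars named list of per-vertex numeric vectors written as PLY
#'   vertex properties (ignored for STL).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, scalars = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") write_stl(mesh, path)
  else if (ext == "ply") write_ply(mesh, path, scalars)
  else stop(sprintf("format error: unsupported mesh format: %s", path))
  invisible(path)
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "mmri binary STL; mm; voxel-center convention"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  td <- triangle_data(mesh)
  nrm <- td$normal / pmax(sqrt(rowSums(td$normal^2)), 1e-30)
  v <- mesh$vertices; f <- mesh$faces
  # 12 floats + uint16 per facet
  block <- matrix(0, 12, nf)
  block[1:3, ] <- t(nrm)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", 80)
  if (sz >= 84) {
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(nf) && sz == 84 + 50 * nf &&
        !grepl("^solid", rawToChar(head_raw[1:5]))) {
      return(parse_stl_binary(con, nf))
    }
  }
  close(con); on.exit(NULL)
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", txt[1])) {
    stop(sprintf("format error: not an STL file: %s", path))
  }
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (is.null(coords) || nrow(coords) %% 3 != 0) {
    stop("format error: corrupt ASCII STL")
  }
  stl_from_soup(coords)
}

parse_stl_binary <- function(con, nf) {
  coords <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    coords[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  stl_from_soup(coords)
}

# merge exactly coincident vertices of a triangle soup
stl_from_soup <- function(coords) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  props <- c("property float x", "property float y", "property float z")
  cols <- mesh$vertices
  if (!is.null(scalars)) {
    for (nm in names(scalars)) {
      stopifnot(length(scalars[[nm]]) == nv)
      props <- c(props, sprintf("property float %s", nm))
      cols <- cbind(cols, scalars[[nm]])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment mmri surface; mm; %s", euler_convention_tag()),
               sprintf("element vertex %d", nv), props,
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(cols, 1, function(r)
    paste(sprintf("%.8g", r), collapse = " ")), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3 || txt[1] != "ply") {
    stop(sprintf("format error: not a PLY file: %s", path))
  }
  if (!grepl("ascii", txt[2])) stop("format error: only ASCII PLY supported")
  endh <- match("end_header", txt)
  hdr <- txt[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vstart <- which(grepl("^element vertex", hdr))
  vend <- which(grepl("^element face", hdr))
  pnames <- sub("^property +\\S+ +", "",
                grep("^property (float|double)", hdr[vstart:vend], value = TRUE))
  vlines <- txt[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  colnames(vm) <- pnames
  flines <- txt[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(p) {
    p <- as.integer(p)
    if (p[1] != 3L) stop("format error: non-triangulated PLY face")
    p[2:4] + 1L
  }))
  mesh <- surface_mesh(vm[, c("x", "y", "z"), drop = FALSE], fm)
  extra <- setdiff(pnames, c("x", "y", "z"))
  if (length(extra)) {
    attr(mesh, "scalars") <- lapply(stats::setNames(extra, extra),
                                    function(nm) vm[, nm])
  }
  mesh
}

#' Landmark and transform JSON I/O
#'
#' Landmarks are stored as `{name: [x, y, z], ...}` (mm); transforms as
#' produced by [transform_to_list] (row-major rotation, translation, Euler
#' convention tag and optional frame metadata).
#'
#' @param path file path.
#' @param landmarks named Nx3 matrix.
#' @param x [rigid_transform].
#' @param frame optional [anatomical_frame] metadata.
#' @return see the individual functions.
#' @export
read_landmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, lst)
  if (is.null(m) || ncol(m) != 3) stop(sprintf("format error: bad landmark file %s", path))
  rownames(m) <- names(lst)
  m
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  lst <- stats::setNames(lapply(seq_len(nrow(landmarks)), function(i)
    as.numeric(landmarks[i, ])), rownames(landmarks))
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname read_landmarks
#' @export
write_transform <- function(x, path, frame = NULL) {
  jsonlite::write_json(transform_to_list(x, frame), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname read_landmarks
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
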