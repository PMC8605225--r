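#' @useDynLib concord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.concord_error <- function(class, msg) {
  stop(structure(
    class = c(class, "concord_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Read a binary structure mask from a volumetric image file
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and, read-only, NRRD (`.nrrd`).
#' Any non-zero voxel value is treated as occupied, so label maps and
#' probability maps load as binary masks. Spacing (mm) is taken from file
#' metadata and must be present and positive; the physical origin is taken
#' from the NIfTI transform translation (or NRRD `space origin`). Axes are
#' interpreted as voxel axes in file order.
#'
#' @param path Path to the image file.
#' @param expected_grid Optional `grid_spec`; if given, the file's grid must
#'   match it within `1e-4` mm (spacing, origin) and exactly (dims), else an
#'   error of class `concord_grid_mismatch` is raised.
#' @param patient_id,rater_id,structure Metadata attached to the returned
#'   mask.
#' @param superior_axis Superior axis of the returned grid (default 3).
#' @return A [structure_mask()].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path, expected_grid = NULL,
                      patient_id = NA_character_, rater_id = NA_character_,
                      structure = NA_character_, superior_axis = 3L) {
  if (!file.exists(path)) {
    .concord_error("concord_file_not_found", paste0("file not found: ", path))
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- .read_nifti_volume(path)
  } else if (grepl("\\.nrrd$", lower)) {
    vol <- .read_nrrd_volume(path)
  } else {
    .concord_error("concord_unsupported_format",
                   paste0("unsupported volumetric format: ", path))
  }
  grid <- grid_spec(vol$dims, vol$spacing, vol$origin,
                    superior_axis = superior_axis)
  if (!is.null(expected_grid) && !grids_equal(grid, expected_grid)) {
    .concord_error(
      "concord_grid_mismatch",
      sprintf("grid of %s does not match the expected grid (tol 1e-4 mm)",
              path))
  }
  structure_mask(vol$data != 0, grid, patient_id = patient_id,
                 rater_id = rater_id, structure = structure)
}

.read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    .concord_error("concord_unsupported_format",
                   paste0("expected a 3D volume: ", path))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (anyNA(sp) || any(!is.finite(sp)) || any(sp <= 0)) {
    .concord_error("concord_missing_spacing",
                   paste0("missing spacing metadata in ", path))
  }
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  list(data = array(as.numeric(img), dim = dim(img)),
       dims = dim(img), spacing = as.numeric(sp), origin = origin)
}

# Minimal NRRD reader: attached-header files, raw or gzip encoding,
# little-endian scalar types. Enough for mask interchange with other tools.
.read_nrrd_volume <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw_all == as.raw(10L))
  # header ends at the first blank line (LF LF, possibly with CR)
  hdr_end <- NA_integer_
  prev <- 0L
  for (pos in nl) {
    seg <- pos - prev - 1L
    if (seg == 0L || (seg == 1L && raw_all[prev + 1L] == as.raw(13L))) {
      hdr_end <- pos
      break
    }
    prev <- pos
  }
  if (is.na(hdr_end)) {
    .concord_error("concord_unsupported_format",
                   paste0("malformed NRRD header in ", path))
  }
  hdr_lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr_lines[1])) {
    .concord_error("concord_unsupported_format",
                   paste0("not an NRRD file: ", path))
  }
  fields <- list()
  for (ln in hdr_lines[-1]) {
    if (grepl("^\\s*#", ln) || !grepl(":", ln)) next
    key <- tolower(trimws(sub(":.*$", "", ln)))
    val <- trimws(sub("^[^:]*:=?", "", ln))
    fields[[key]] <- val
  }
  dims <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(dims) != 3L) {
    .concord_error("concord_unsupported_format",
                   paste0("only 3D NRRD volumes are supported: ", path))
  }
  spacing <- .nrrd_spacing(fields)
  if (is.null(spacing)) {
    .concord_error("concord_missing_spacing",
                   paste0("missing spacing metadata in ", path))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  }
  type <- tolower(fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (!enc %in% c("raw")) {
    .concord_error("concord_unsupported_format",
                   paste0("unsupported NRRD encoding '", enc, "' in ", path))
  }
  spec <- switch(type,
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    "char" = , "int8" = , "signed char" = list(what = "integer", size = 1, signed = TRUE),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "uint16" = , "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4, signed = TRUE),
    "uint" = , "uint32" = , "unsigned int" = list(what = "integer", size = 4, signed = FALSE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    .concord_error("concord_unsupported_format",
                   paste0("unsupported NRRD type '", type, "' in ", path))
  )
  endian <- if (!is.null(fields[["endian"]]) &&
                tolower(fields[["endian"]]) == "big") "big" else "little"
  vals <- readBin(payload, what = spec$what, n = prod(dims),
                  size = spec$size, signed = spec$signed, endian = endian)
  if (length(vals) < prod(dims)) {
    .concord_error("concord_unsupported_format",
                   paste0("truncated NRRD data in ", path))
  }
  list(data = array(as.numeric(vals), dim = dims), dims = dims,
       spacing = spacing, origin = origin)
}

.nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
    if (length(sp) == 3L && all(is.finite(sp)) && all(sp > 0)) return(sp)
    return(NULL)
  }
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) return(NULL)
    sp <- vapply(vecs, function(v) {
      comp <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(comp^2))
    }, numeric(1), USE.NAMES = FALSE)
    if (all(is.finite(sp)) && all(sp > 0)) return(sp)
  }
  NULL
}

#' Write a structure mask to a NIfTI file
#'
#' The round trip `read_mask(write_mask(m, path))` reproduces occupancy,
#' dims, spacing and origin exactly. Occupancy is stored as `uint8`
#' (0 = empty, 1 = occupied); spacing goes to `pixdim` and the origin into a
#' diagonal sform.
#'
#' @param mask A [structure_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!dir.exists(dirname(path))) {
    .concord_error("concord_unwritable_path",
                   paste0("parent directory does not exist: ", dirname(path)))
  }
  img <- RNifti::asNifti(array(as.integer(mask$occupancy),
                               dim = mask$grid$dims))
  RNifti::pixdim(img) <- mask$grid$spacing
  m <- diag(c(mask$grid$spacing, 1))
  m[1:3, 4] <- mask$grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Rasterize per-slice closed polygons into a binary mask
#'
#' Clinical contours are drawn as closed planar polygons on axial slices;
#' this converts them to a voxel mask. A voxel is occupied iff its center
#' lies inside an odd number of that slice's polygons (even-odd rule), so a
#' polygon nested inside another cuts a hole. Points exactly on an edge are
#' resolved by a fixed half-open convention (a crossing counts only for
#' edges spanning the test ordinate in the half-open sense, and only
#' strictly to the right of the point), so abutting polygons never
#' double-cover and counts are deterministic.
#'
#' @param polygons A data frame with columns `slice_z_mm`, `vertex_index`,
#'   `x_mm`, `y_mm` (and optionally `structure`). Vertices are ordered;
#'   a `vertex_index` that does not increase starts a new polygon. `x_mm`
#'   and `y_mm` are physical coordinates along the two in-plane axes (in
#'   axis order), `slice_z_mm` along the superior axis.
#' @param grid A `grid_spec`; each polygon's plane must coincide with a
#'   slice center within half a slice spacing.
#' @param patient_id,rater_id,structure Metadata for the returned mask.
#' @return A [structure_mask()].
#' @examples
#' g <- grid_spec(c(20, 20, 5), c(1, 1, 2))
#' sq <- data.frame(slice_z_mm = 4, vertex_index = 0:3,
#'                  x_mm = c(4.5, 14.5, 14.5, 4.5),
#'                  y_mm = c(4.5, 4.5, 14.5, 14.5))
#' voxel_count(rasterize_slice_polygons(sq, g))  # 100
#' @export
rasterize_slice_polygons <- function(polygons, grid,
                                     patient_id = NA_character_,
                                     rater_id = NA_character_,
                                     structure = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  req <- c("slice_z_mm", "vertex_index", "x_mm", "y_mm")
  if (!all(req %in% names(polygons))) {
    stop("polygons must have columns ", paste(req, collapse = ", "))
  }
  occ <- array(FALSE, grid$dims)
  if (nrow(polygons) == 0L) {
    return(structure_mask(occ, grid, patient_id, rater_id, structure))
  }
  ax <- grid$superior_axis
  inplane <- setdiff(1:3, ax)
  zc <- slice_centers(grid)
  dz <- grid$spacing[ax]

  # split rows into individual polygons: new polygon whenever vertex_index
  # does not increase, or the slice changes
  vi <- polygons$vertex_index
  newpoly <- c(TRUE, diff(vi) <= 0 | diff(polygons$slice_z_mm) != 0)
  poly_id <- cumsum(newpoly)

  # per-slice voxel-center coordinate vectors for the two in-plane axes
  u <- grid$origin[inplane[1]] +
    (seq_len(grid$dims[inplane[1]]) - 1) * grid$spacing[inplane[1]]
  v <- grid$origin[inplane[2]] +
    (seq_len(grid$dims[inplane[2]]) - 1) * grid$spacing[inplane[2]]

  for (pid in unique(poly_id)) {
    rows <- polygons[poly_id == pid, , drop = FALSE]
    if (nrow(rows) < 3L) stop("polygon with fewer than 3 vertices")
    z <- rows$slice_z_mm[1]
    k <- which(abs(zc - z) <= dz / 2 + 1e-9)
    if (length(k) == 0L) {
      stop(sprintf("polygon plane z = %g mm is not aligned with any slice", z))
    }
    k <- k[which.min(abs(zc[k] - z))]
    px <- rows$x_mm
    py <- rows$y_mm
    if (.polygon_self_intersects(px, py)) {
      stop(sprintf("self-intersecting polygon on slice z = %g mm", z))
    }
    inside <- .even_odd_inside(u, v, px, py)
    sl <- .get_slice(occ, ax, k)
    .set_slice(occ, ax, k) <- xor(sl, inside)
    # xor accumulates the even-odd rule across this slice's polygons
  }
  structure_mask(occ, grid, patient_id, rater_id, structure)
}

# Even-odd point-in-polygon over the full in-plane center lattice.
# A horizontal ray to the right; edges are half-open in y (y1 > py) != (y2 > py)
# and a crossing counts only when px is strictly left of the intersection.
.even_odd_inside <- function(u, v, px, py) {
  nu <- length(u); nv <- length(v)
  inside <- matrix(FALSE, nu, nv)
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    y1 <- py[j]; y2 <- py[i]; x1 <- px[j]; x2 <- px[i]
    if (y1 != y2) {
      spans <- (y1 > v) != (y2 > v)                    # length nv
      if (any(spans)) {
        xint <- x1 + (v - y1) * (x2 - x1) / (y2 - y1)  # length nv
        cross <- outer(u, xint, `<`)                   # nu x nv
        cross[, !spans] <- FALSE
        inside <- xor(inside, cross)
      }
    }
    j <- i
  }
  inside
}

# Simple O(n^2) proper-crossing test between non-adjacent edges.
.polygon_self_intersects <- function(px, py) {
  n <- length(px)
  if (n < 4L) return(FALSE)
  seg <- cbind(px, py, px[c(2:n, 1)], py[c(2:n, 1)])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    for (k in (i + 2L):n) {
      if (i == 1L && k == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[k, ]
      d1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Read slice polygons from CSV
#'
#' Expects columns `structure`, `slice_z_mm`, `vertex_index`, `x_mm`,
#' `y_mm` (`structure` optional).
#'
#' @param path CSV path.
#' @return Data frame suitable for [rasterize_slice_polygons()].
#' @export
read_slice_polygons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("slice_z_mm", "vertex_index", "x_mm", "y_mm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("polygon CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

.get_slice <- function(occ, ax, k) {
  switch(ax, occ[k, , ], occ[, k, ], occ[, , k])
}

`.set_slice<-` <- function(occ, ax, k, value) {
  switch(ax,
         occ[k, , ] <- value,
         occ[, k, ] <- value,
         occ[, , k] <- value)
  occ
}
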