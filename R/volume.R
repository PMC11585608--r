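#' Volumetric CT container
#'
#' A `ct_volume` holds a rank-3 grid of intensities indexed `(z, y, x)` --
#' axial slice first, matching the through-plane axis whose resolution the
#' model enhances -- together with per-axis voxel spacing and origin in mm.
#' Intensities are stored as doubles; `space` records whether values are in
#' Hounsfield units (`"hu"`) or normalized model space `[0, 1]` (`"unit"`).
#'
#' @param values numeric rank-3 array indexed `(z, y, x)`.
#' @param spacing numeric length-3, `(dz, dy, dx)` in mm, all positive.
#' @param origin numeric length-3, `(oz, oy, ox)` in mm.
#' @param space `"hu"` or `"unit"`.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(6, 8, 8)), spacing = c(5, 0.7, 0.7))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      space = c("hu", "unit")) {
  space <- match.arg(space)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a rank-3 array indexed (z, y, x)")
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (dz, dy, dx)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (oz, oy, ox)")
  if (dim(values)[1] < 1L) stop("volume must contain at least one slice")
  structure(
    list(values = array(as.double(values), dim(values)),
         spacing = as.double(spacing), origin = as.double(origin),
         space = space),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g mm, %s space\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$space))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

is_ct_volume <- function(x) inherits(x, "ct_volume")

# HU bounds of the normalization window
.hu_min <- -1024
.hu_max <- 2048
.hu_span <- .hu_max - .hu_min

#' Normalize HU intensities to model space
#'
#' Clamps intensities to the CT window `[-1024, 2048]` HU and maps them
#' linearly to `[0, 1]`: `out = (clamp(v, -1024, 2048) + 1024) / 3072`.
#' Out-of-range values are clamped rather than rejected.
#'
#' @param v a `ct_volume` in HU space.
#' @return A `ct_volume` with `space = "unit"` and values in `[0, 1]`.
#' @seealso [denormalize()]
#' @export
normalize_hu <- function(v) {
  stopifnot(is_ct_volume(v))
  if (v$space == "unit") return(v)
  out <- (pmin(pmax(v$values, .hu_min), .hu_max) - .hu_min) / .hu_span
  ct_volume(out, v$spacing, v$origin, space = "unit")
}

#' Map model-space intensities back to HU
#'
#' Inverse of [normalize_hu()] on its range: `out = v * 3072 - 1024`.
#' Values outside `[0, 1]` are a domain error.
#'
#' @param nv a `ct_volume` in unit space with values in `[0, 1]`.
#' @return A `ct_volume` in HU space.
#' @export
denormalize <- function(nv) {
  stopifnot(is_ct_volume(nv))
  rng <- range(nv$values)
  if (rng[1] < 0 || rng[2] > 1)
    stop(sprintf("denormalize: values outside [0, 1] (range %.4g..%.4g)",
                 rng[1], rng[2]))
  ct_volume(nv$values * .hu_span + .hu_min, nv$spacing, nv$origin,
            space = "hu")
}

# clamp an array of unit-space predictions into [0,1] before denormalizing
clamp_unit <- function(a) pmin(pmax(a, 0), 1)

#' Read a CT volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) through RNifti and uncompressed
#' MetaImage (`.mha`, `.mhd` + raw).  The header's slice axis becomes the
#' first (z) index of the returned array; spacing and origin are taken from
#' the header.
#'
#' @param path file path.
#' @return A `ct_volume` in HU space.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: cannot open '%s': no such file", path))
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mh[ad]))$", "\\1",
                     basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                      "read_volume: failed to read '%s': %s", path,
                      conditionMessage(e))))
    if (length(dim(img)) != 3L)
      stop(sprintf("read_volume: '%s' is not a 3-D image", path))
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop(sprintf("read_volume: '%s' has no valid voxel spacing", path))
    hdr <- RNifti::niftiHeader(img)
    origin_xyz <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    # NIfTI arrays are (x, y, z); reorder to (z, y, x)
    ct_volume(aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1)),
              spacing = rev(pd[1:3]), origin = rev(origin_xyz))
  } else if (ext %in% c(".mha", ".mhd")) {
    read_metaimage(path)
  } else {
    stop(sprintf("read_volume: unsupported file type '%s'", path))
  }
}

#' Write a CT volume to NIfTI or MetaImage
#'
#' The output format follows the file extension.  Values are stored as
#' 64-bit floats so a round-trip through [read_volume()] is bit-identical;
#' spacing and origin are stored in the header.
#'
#' @param v a `ct_volume`.
#' @param path destination path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_ct_volume(v))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("write_volume: directory '%s' does not exist", dir))
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mha))$", "\\1",
                     basename(path)))
  if (ext %in% c(".nii", ".nii.gz")) {
    arr <- aperm(v$values, c(3, 2, 1))  # back to (x, y, z)
    sp <- rev(v$spacing)
    org <- rev(v$origin)
    img <- RNifti::asNifti(arr, reference = list(
      pixdim = c(-1, sp, rep(0, 4)),
      qoffset_x = org[1], qoffset_y = org[2], qoffset_z = org[3],
      qform_code = 2L))
    RNifti::writeNifti(img, path)
  } else if (ext == ".mha") {
    write_metaimage(v, path)
  } else {
    stop(sprintf("write_volume: unsupported file type '%s'", path))
  }
  invisible(path)
}

# ---- MetaImage (.mha/.mhd) ------------------------------------------------
# Minimal uncompressed MetaImage support: 3-D, LOCAL or external raw data.

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("read_volume: '%s' has no ElementDataFile entry", path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$",
                                   line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("read_volume: malformed MetaImage header line '%s' in '%s'",
                   line, path))
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") { data_offset <- seek(con); break }
  }
  need <- function(key) {
    if (is.null(hdr[[key]]))
      stop(sprintf("read_volume: '%s' missing MetaImage field %s", path, key))
    hdr[[key]]
  }
  if (!is.null(hdr$CompressedData) &&
      toupper(hdr$CompressedData) == "TRUE")
    stop(sprintf("read_volume: compressed MetaImage '%s' is not supported",
                 path))
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dims) != 3L)
    stop(sprintf("read_volume: '%s' is not a 3-D image", path))
  spacing <- as.double(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.double(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- .met_types[[need("ElementType")]]
  if (is.null(ty))
    stop(sprintf("read_volume: unsupported ElementType %s in '%s'",
                 hdr$ElementType, path))
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("read_volume: raw data file '%s' not found", raw_path))
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, ty$what, n = n, size = ty$size,
                  signed = ty$signed, endian = "little")
  if (length(vals) < n)
    stop(sprintf("read_volume: '%s' is truncated (%d of %d voxels)",
                 path, length(vals), n))
  # MetaImage stores x fastest; reorder (x,y,z) -> (z,y,x)
  ct_volume(aperm(array(as.double(vals), dims), c(3, 2, 1)),
            spacing = rev(spacing), origin = rev(origin))
}

write_metaimage <- function(v, path) {
  dims <- rev(dim(v$values))  # (x, y, z)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(rev(v$spacing), collapse = " ")),
           paste("Offset =", paste(rev(v$origin), collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(aperm(v$values, c(3, 2, 1))), con, size = 8L,
           endian = "little")
  invisible(path)
}
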