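#' Raw CT volume with voxel spacing
#'
#' Container for a 3D grayscale volume in Hounsfield units together with its
#' voxel spacing. Axis order is canonical `(x, y, z)` with `z` the slice axis.
#'
#' @param intensities 3D numeric array of CT density (HU).
#' @param spacing numeric length-3 vector `(sx, sy, sz)` of voxel edge
#'   lengths in mm; all components must be strictly positive.
#' @param id optional identifier carried through to patches.
#' @return An object of class `raw_volume` with elements `intensities`,
#'   `spacing` and `id`.
#' @export
raw_volume <- function(intensities, spacing, id = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("volume ", if (is.null(id)) "" else paste0("'", id, "' "),
         "has missing or non-positive voxel spacing")
  if (any(dim(intensities) < 1L)) stop("all volume dimensions must be >= 1")
  structure(list(intensities = intensities, spacing = spacing, id = id),
            class = "raw_volume")
}

#' @export
print.raw_volume <- function(x, ...) {
  cat(sprintf("<raw_volume%s> %s voxels, spacing %s mm\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' 64^3 isotropic nodule patch
#'
#' The unit of classification: a 64 x 64 x 64 patch at 1 mm isotropic
#' spacing, with provenance (source volume id and the annotated center on
#' the original voxel grid).
#'
#' @param intensities 3D numeric array, exactly 64 x 64 x 64 (HU).
#' @param provenance list with optional `id` and `center` elements.
#' @return An object of class `volume_patch`.
#' @export
volume_patch <- function(intensities, provenance = list()) {
  if (!is.array(intensities) || !identical(dim(intensities), c(64L, 64L, 64L)))
    stop("a volume_patch must be exactly 64 x 64 x 64")
  structure(list(intensities = intensities, spacing = c(1, 1, 1),
                 provenance = provenance),
            class = "volume_patch")
}

#' @export
print.volume_patch <- function(x, ...) {
  cat(sprintf("<volume_patch%s> 64x64x64 @ 1 mm, HU range [%.0f, %.0f]\n",
              if (is.null(x$provenance$id)) "" else paste0(" ", x$provenance$id),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# Cell-centered 1D resampling geometry: input voxel i (0-based) spans
# [i*s, (i+1)*s) mm, its center sits at (i+1/2)*s. Output voxel j at 1 mm
# spacing has center (j+1/2) mm; its fractional input index is
# (j+1/2)/s - 1/2, clamped to [0, n-1] so interpolation never extrapolates.
.resample_axis <- function(n_in, spacing, n_out) {
  u <- (seq_len(n_out) - 0.5) / spacing - 0.5
  u <- pmin(pmax(u, 0), n_in - 1)
  i0 <- pmin(floor(u), n_in - 1)
  list(i0 = as.integer(i0) + 1L,              # 1-based lower index
       i1 = as.integer(pmin(i0 + 1, n_in - 1)) + 1L,
       f  = u - i0)
}

#' Resample a volume to 1 mm isotropic voxels
#'
#' Trilinear interpolation onto a 1 mm isotropic grid. The output shape along
#' axis i is `round(shape_i * spacing_i)`. Voxels are treated as
#' cell-centered and sample points are clamped at the faces, so interpolated
#' values never leave the input intensity range.
#'
#' @param volume a [raw_volume()].
#' @return A [raw_volume()] with `spacing = c(1, 1, 1)`.
#' @export
resample_isotropic <- function(volume) {
  stopifnot(inherits(volume, "raw_volume"))
  arr <- volume$intensities
  sp <- volume$spacing
  d <- dim(arr)
  if (all(sp == 1)) return(raw_volume(arr, c(1, 1, 1), id = volume$id))
  d_out <- pmax(as.integer(round(d * sp)), 1L)
  ax <- .resample_axis(d[1], sp[1], d_out[1])
  ay <- .resample_axis(d[2], sp[2], d_out[2])
  az <- .resample_axis(d[3], sp[3], d_out[3])
  out <- array(0, dim = d_out)
  # successive lerps a + f*(b - a): exact on constant data, and slab-wise
  # along z to bound memory on full CT grids
  bilin <- function(M) {
    t0 <- M[ax$i0, ay$i0, drop = FALSE]
    t0 <- t0 + ax$f * (M[ax$i1, ay$i0, drop = FALSE] - t0)
    t1 <- M[ax$i0, ay$i1, drop = FALSE]
    t1 <- t1 + ax$f * (M[ax$i1, ay$i1, drop = FALSE] - t1)
    t0 + sweep(t1 - t0, 2, ay$f, `*`)
  }
  for (k in seq_len(d_out[3])) {
    p0 <- bilin(arr[, , az$i0[k], drop = TRUE])
    if (az$f[k] > 0) {
      p1 <- bilin(arr[, , az$i1[k], drop = TRUE])
      out[, , k] <- p0 + az$f[k] * (p1 - p0)
    } else out[, , k] <- p0
  }
  # guard the CT intensity range against interpolation round-off
  out <- pmin(pmax(out, min(arr)), max(arr))
  raw_volume(out, c(1, 1, 1), id = volume$id)
}

#' Crop a centered 64^3 patch from an isotropic volume
#'
#' The voxel containing `center_mm` becomes patch voxel (32, 32, 32)
#' (0-based). Regions extending past the volume boundary are filled with the
#' padding value (default -1024 HU, air).
#'
#' @param volume a [raw_volume()] at 1 mm isotropic spacing.
#' @param center_mm numeric length-3 center in mm on the isotropic grid.
#' @param pad value for out-of-bounds voxels.
#' @param id provenance identifier.
#' @return A [volume_patch()].
#' @export
crop_centered <- function(volume, center_mm, pad = -1024, id = NULL) {
  stopifnot(inherits(volume, "raw_volume"))
  if (!all(volume$spacing == 1))
    stop("crop_centered requires a 1 mm isotropic volume; resample first")
  center_mm <- as.numeric(center_mm)
  d <- dim(volume$intensities)
  if (length(center_mm) != 3L || anyNA(center_mm) ||
      any(center_mm < 0) || any(center_mm >= d))
    stop("center (", paste(center_mm, collapse = ", "),
         ") lies outside the volume bounds ", paste(d, collapse = "x"))
  cvox <- pmin(floor(center_mm), d - 1)          # 0-based voxel containing center
  start <- as.integer(cvox) - 32L                # 0-based patch origin
  out <- array(pad, dim = c(64L, 64L, 64L))
  src_lo <- pmax(start, 0L); src_hi <- pmin(start + 63L, d - 1L)
  if (all(src_lo <= src_hi)) {
    dst <- lapply(1:3, function(i) (src_lo[i] - start[i] + 1L):(src_hi[i] - start[i] + 1L))
    src <- lapply(1:3, function(i) (src_lo[i] + 1L):(src_hi[i] + 1L))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      volume$intensities[src[[1]], src[[2]], src[[3]]]
  }
  volume_patch(out, provenance = list(id = id %||% volume$id, center = center_mm))
}

#' Read a volume from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`; spacing taken from the header) and a
#' raw little-endian double array (`.bin`) with a JSON sidecar
#' `<path>.json` holding `{"shape": [nx,ny,nz], "spacing": [sx,sy,sz]}`.
#'
#' @param path file path.
#' @param id identifier attached to the volume (defaults to the file name).
#' @return A [raw_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("volume file not readable: ", path)
  id <- id %||% basename(path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
    sp <- RNifti::pixdim(img)[1:3]
    return(raw_volume(unclass(arr), sp, id = id))
  }
  if (grepl("\\.bin$", path)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("missing JSON sidecar for raw volume: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$spacing)) stop("sidecar lacks \"spacing\": ", side)
    shp <- as.integer(meta$shape)
    vals <- readBin(path, what = "double", n = prod(shp), endian = "little")
    if (length(vals) != prod(shp)) stop("raw volume truncated: ", path)
    return(raw_volume(array(vals, dim = shp), as.numeric(meta$spacing), id = id))
  }
  stop("unrecognized volume format (expect .nii, .nii.gz or .bin): ", path)
}

#' Write a volume to disk in a format [read_volume()] can load
#'
#' @param volume a [raw_volume()] or [volume_patch()].
#' @param path destination ending in `.nii`, `.nii.gz` or `.bin`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$intensities
  sp <- volume$spacing
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.bin$", path)) {
    writeBin(as.numeric(arr), path, endian = "little")
    jsonlite::write_json(list(shape = dim(arr), spacing = sp),
                         paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else stop("unrecognized volume format: ", path)
  invisible(path)
}

#' Load a dataset manifest
#'
#' The manifest is a CSV with header `id,path,cx,cy,cz,label`. Centers
#' `(cx, cy, cz)` are 0-based voxel indices on the ORIGINAL grid; labels are
#' 0 (benign) or 1 (cancer).
#'
#' @param path manifest CSV path.
#' @return A `data.frame` of class `cadx_manifest` with an attribute
#'   `base_dir` (the manifest's directory, against which relative volume
#'   paths resolve).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "cx", "cy", "cz", "label")
  if (!all(need %in% names(df)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$label %in% c(0, 1))
      stop("manifest row ", i, ": label must be 0 or 1, got ", row$label)
    if (anyNA(as.numeric(row[c("cx", "cy", "cz")])))
      stop("manifest row ", i, ": malformed center coordinates")
  }
  df$label <- as.integer(df$label)
  attr(df, "base_dir") <- dirname(path)
  class(df) <- c("cadx_manifest", class(df))
  df
}

#' Load and preprocess a labelled patch dataset
#'
#' For every manifest record, reads the volume, resamples it to 1 mm
#' isotropic voxels, converts the annotated original-grid center to mm by
#' multiplying by the original spacing, and crops the centered 64^3 patch.
#'
#' @param manifest a path or the result of [load_manifest()].
#' @param pad padding value for out-of-bounds crop regions (HU).
#' @return A list of class `cadx_dataset` with `patches` (list of
#'   [volume_patch()]), `labels` (integer 0/1) and `ids`.
#' @export
load_dataset <- function(manifest, pad = -1024) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  base <- attr(manifest, "base_dir") %||% "."
  patches <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    p <- row$path
    if (!file.exists(p)) p <- file.path(base, row$path)
    vol <- read_volume(p, id = row$id)
    iso <- resample_isotropic(vol)
    center_mm <- as.numeric(row[c("cx", "cy", "cz")]) * vol$spacing
    patches[[i]] <- crop_centered(iso, center_mm, pad = pad, id = row$id)
  }
  cadx_dataset(patches, manifest$label, ids = manifest$id)
}

#' Bundle patches and labels into a dataset
#'
#' @param patches list of [volume_patch()].
#' @param labels integer 0/1 vector, one per patch.
#' @param ids optional identifiers.
#' @return An object of class `cadx_dataset`.
#' @export
cadx_dataset <- function(patches, labels, ids = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(patches) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(patches = patches, labels = labels,
                 ids = ids %||% as.character(seq_along(patches))),
            class = "cadx_dataset")
}

#' @export
print.cadx_dataset <- function(x, ...) {
  cat(sprintf("<cadx_dataset> %d patches (%d cancer / %d benign)\n",
              length(x$patches), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}
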