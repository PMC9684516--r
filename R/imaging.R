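#' Image volume container
#'
#' A 3D scalar grid with physical voxel spacing. Coordinates are physical
#' millimeters with the origin at the volume corner, so the center of voxel
#' `(i, j, k)` (1-based) lies at `((i - 0.5) * sx, (j - 0.5) * sy,
#' (k - 0.5) * sz)` relative to `origin_mm`.
#'
#' @param values numeric 3D array of intensities (arbitrary units).
#' @param spacing_mm length-3 positive numeric, voxel spacing in mm.
#' @param origin_mm length-3 numeric, corner position in mm.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' Binary region-of-interest mask
#'
#' A 0/1 grid aligned voxel-for-voxel with an [image_volume()].
#'
#' @param values logical/numeric 3D array; non-zero marks the ROI.
#' @param spacing_mm voxel spacing in mm (must match the paired volume).
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing_mm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- array(as.logical(values != 0), dim = dim(values))
  structure(list(values = v, spacing_mm = as.numeric(spacing_mm)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$values), collapse = "x"),
      " voxels, ", mask_voxel_count(x), " in ROI (",
      format(mask_volume_cc(x), digits = 4), " cc)\n", sep = "")
  invisible(x)
}

#' Number of ROI voxels
#' @param mask an [roi_mask()].
#' @export
mask_voxel_count <- function(mask) sum(mask$values)

#' Physical ROI volume in cubic centimeters
#' @param mask an [roi_mask()].
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$values) * prod(mask$spacing_mm) / 1000
}

check_alignment <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("mask is not aligned with the volume (different grid shapes)")
  if (max(abs(vol$spacing_mm - mask$spacing_mm)) > 1e-9)
    stop("mask is not aligned with the volume (different spacings)")
  invisible(TRUE)
}

## ---- NRRD I/O ------------------------------------------------------------
## Minimal NRRD reader/writer (no NRRD package exists in this stack). The
## writer emits NRRD0004 with `space directions` encoding the spacing and
## either raw little-endian or ascii data; the reader accepts that subset
## (plus the legacy `spacings` field) and refuses files without spacing
## metadata rather than silently assuming 1 mm.

#' Write a volume (or mask) to an NRRD file
#'
#' @param vol an [image_volume()] or [roi_mask()].
#' @param path output file path ending in `.nrrd`.
#' @param encoding `"raw"` (little-endian double) or `"ascii"` (text).
#' @export
write_volume <- function(vol, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  if (inherits(vol, "roi_mask"))
    vol <- image_volume(array(as.numeric(vol$values), dim(vol$values)),
                        vol$spacing_mm)
  if (!inherits(vol, "image_volume")) stop("`vol` must be an image_volume")
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unknown format for '", path, "': only .nrrd is supported")
  d <- dim(vol$values)
  s <- vol$spacing_mm
  o <- vol$origin_mm
  hdr <- c(
    "NRRD0004",
    "# deltarad volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            s[1], s[2], s[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(vol$values), digits = 17,
                            scientific = TRUE, trim = TRUE), collapse = "\n"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a volume from an NRRD file
#'
#' Errors (naming the file) if the file is not NRRD or lacks spacing
#' metadata; spacing is never silently defaulted.
#'
#' @param path path to a `.nrrd` file.
#' @param as_mask logical; return an [roi_mask()] instead of a volume.
#' @return an [image_volume()] (or [roi_mask()]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unknown format for '", path, "': only .nrrd is supported")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("'", path, "' is not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("'", path, "': truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("'", path, "': missing NRRD field '", k, "'")
    fields[[k]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("'", path, "': only 3D NRRD supported")
  if (!is.null(fields[["space directions"]])) {
    nums <- as.numeric(regmatches(fields[["space directions"]],
      gregexpr("-?[0-9.eE+]+", fields[["space directions"]]))[[1]])
    if (length(nums) != 9L) stop("'", path, "': bad space directions")
    m <- matrix(nums, 3, 3, byrow = TRUE)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-12))
      stop("'", path, "': oblique space directions not supported")
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    stop("'", path, "': no spacing metadata (space directions/spacings); ",
         "refusing to assume a default")
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(regmatches(fields[["space origin"]],
      gregexpr("-?[0-9.eE+]+", fields[["space origin"]]))[[1]])
  type <- need("type")
  enc <- need("encoding")
  n <- prod(sizes)
  if (enc == "raw") {
    endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
    sz <- switch(type, double = 8L, float = 4L, int = 4L, short = 2L,
                 uchar = 1L, stop("'", path, "': unsupported type ", type))
    what <- if (type %in% c("double", "float")) numeric() else integer()
    vals <- readBin(con, what, n = n, size = sz, endian = endian,
                    signed = !identical(type, "uchar"))
  } else if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[is.finite(vals) | !is.na(vals)]
  } else {
    stop("'", path, "': unsupported encoding '", enc, "'")
  }
  if (length(vals) < n) stop("'", path, "': truncated data section")
  arr <- array(as.numeric(vals[seq_len(n)]), dim = sizes)
  if (as_mask) roi_mask(arr, spacing)
  else image_volume(arr, spacing, origin)
}

## ---- resampling ----------------------------------------------------------

#' Resample a volume and its mask to isotropic spacing
#'
#' Intensities are interpolated trilinearly; the mask with nearest neighbor
#' (never smoothed, so the ROI cannot grow by partial-volume effects). The
#' output grid shares the input origin and covers `round(extent / target)`
#' voxels per axis.
#'
#' @param vol an [image_volume()].
#' @param mask an [roi_mask()] aligned with `vol`.
#' @param target_mm isotropic target spacing (default 1 mm).
#' @return list with elements `volume` and `mask`.
#' @export
resample_isotropic <- function(vol, mask, target_mm = 1.0) {
  check_alignment(vol, mask)
  if (!is.finite(target_mm) || target_mm <= 0)
    stop("degenerate target spacing")
  d <- dim(vol$values)
  extent <- d * vol$spacing_mm
  od <- pmax(1L, as.integer(round(extent / target_mm)))
  v <- resample_grid_cpp(as.numeric(vol$values), as.integer(d),
                         vol$spacing_mm, od, target_mm, 0L)
  m <- resample_grid_cpp(as.numeric(mask$values), as.integer(d),
                         vol$spacing_mm, od, target_mm, 1L)
  list(
    volume = image_volume(array(v, od), rep(target_mm, 3), vol$origin_mm),
    mask = roi_mask(array(m > 0.5, od), rep(target_mm, 3))
  )
}
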