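#' Construct an OCT radial-scan volume
#'
#' Container for a stack of radial B-scans sharing one raster geometry. Depth
#' of row `r` is `r * axial_um_per_px`; lateral position of column `c` is
#' `(c - vertex_column) * lateral_um_per_px` along the cut meridian.
#'
#' @param bscans list of `H x W` non-negative intensity matrices in \[0, 1\].
#' @param angles_deg radial cut angles, strictly increasing in \[0, 180).
#' @param axial_um_per_px,lateral_um_per_px pixel scales, um.
#' @param vertex_column column index of the corneal vertex (the saturation
#'   artifact column).
#' @param metadata free-form named list.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, angles_deg, axial_um_per_px, lateral_um_per_px,
                       vertex_column, metadata = list()) {
  vol <- structure(
    list(bscans = bscans, angles_deg = as.numeric(angles_deg),
         axial_um_per_px = axial_um_per_px, lateral_um_per_px = lateral_um_per_px,
         vertex_column = as.integer(vertex_column), metadata = metadata),
    class = "oct_volume")
  validate_volume(vol)
  vol
}

validate_volume <- function(vol) {
  dims <- vapply(vol$bscans, dim, integer(2))
  if (ncol(dims) == 0) abort("volume has no B-scans")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all B-scans must share the same height and width")
  if (length(vol$angles_deg) != length(vol$bscans))
    abort("number of cut angles must equal the number of B-scans")
  if (any(diff(vol$angles_deg) <= 0) || any(vol$angles_deg < 0) ||
      any(vol$angles_deg >= 180))
    abort("cut angles must be strictly increasing within [0, 180)")
  if (any(vapply(vol$bscans, function(b) any(b < 0), logical(1))))
    abort("B-scan intensities must be non-negative")
  invisible(vol)
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1]])
  cat(sprintf("<oct_volume> %d radial B-scans, %d x %d px, %.3g um/px axial, %.3g um/px lateral\n",
              length(x$bscans), d[1], d[2], x$axial_um_per_px, x$lateral_um_per_px))
  invisible(x)
}

#' Write an OCT volume as a multi-page TIFF plus JSON sidecar
#'
#' One 16-bit TIFF page per radial B-scan; geometry and metadata go to a JSON
#' sidecar next to the TIFF. The round trip through [read_volume()] is
#' lossless for volumes whose intensities are 16-bit quantised (as rendered by
#' [render_volume()]).
#'
#' @param volume an `oct_volume`.
#' @param path path to the TIFF file to write.
#' @param sidecar_path path of the JSON sidecar (default: same name, `.json`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path,
                         sidecar_path = paste0(tools::file_path_sans_ext(path), ".json")) {
  validate_volume(volume)
  tiff::writeTIFF(volume$bscans, path, bits.per.sample = 16L, compression = "none")
  side <- list(
    axial_um_per_px = volume$axial_um_per_px,
    lateral_um_per_px = volume$lateral_um_per_px,
    angles_deg = volume$angles_deg,
    vertex_column = volume$vertex_column,
    metadata = volume$metadata
  )
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' Accepts 8- or 16-bit TIFF stacks; intensities are normalised to \[0, 1\]
#' (the tiff reader divides by the sample-depth maximum). A missing sidecar or
#' missing sidecar keys raise an error naming what is required.
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path.
#' @return An `oct_volume`.
#' @export
read_volume <- function(path,
                        sidecar_path = paste0(tools::file_path_sans_ext(path), ".json")) {
  if (!file.exists(sidecar_path))
    abort(paste0("sidecar not found: ", sidecar_path,
                 " (required keys: axial_um_per_px, lateral_um_per_px, angles_deg, vertex_column)"))
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("axial_um_per_px", "lateral_um_per_px", "angles_deg", "vertex_column")
  missing <- setdiff(need, names(side))
  if (length(missing))
    abort(paste0("sidecar is missing required key(s): ", paste(missing, collapse = ", ")))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("TIFF pages disagree in size: all B-scans must share one raster")
  meta <- side$metadata %||% list()
  oct_volume(pages, angles_deg = side$angles_deg,
             axial_um_per_px = side$axial_um_per_px,
             lateral_um_per_px = side$lateral_um_per_px,
             vertex_column = side$vertex_column, metadata = meta)
}
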