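#' Read an EPID image from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`raster_plus_sidecar`}{a little-endian float64 binary raster
#'     (`.raw`, row-major) with a YAML sidecar (`<path>.yaml`) carrying the
#'     grid shape and the four geometry fields.  Lossless: the round trip
#'     through [write_epid_image()] is bit-for-bit.}
#'   \item{`dicom_rtimage`}{a DICOM RT Image file (explicit VR little
#'     endian).  Pixel data are 16-bit; the detector-plane pixel spacing is
#'     rescaled to the isocenter plane by SAD/SID.}
#' }
#'
#' @param path file path.
#' @param format `"raster_plus_sidecar"` or `"dicom_rtimage"`; default is
#'   guessed from the extension (`.dcm` means DICOM).
#' @return An [epid_image].
#' @export
read_epid_image <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE))
      "dicom_rtimage" else "raster_plus_sidecar"
  }
  format <- match.arg(format, c("raster_plus_sidecar", "dicom_rtimage"))
  if (!file.exists(path)) stop("read_epid_image: file not found: ", path)
  switch(format,
    raster_plus_sidecar = read_raster_sidecar(path),
    dicom_rtimage = read_dicom_rtimage(path)
  )
}

#' Write an EPID image to disk
#'
#' @param img an [epid_image].
#' @param path output path; `.raw` for raster + sidecar (a `<path>.yaml`
#'   sidecar is written next to it), `.dcm` for DICOM RT Image.
#' @param format see [read_epid_image()].
#' @return `path`, invisibly.
#' @export
write_epid_image <- function(img, path, format = NULL) {
  stopifnot(inherits(img, "epid_image"))
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE))
      "dicom_rtimage" else "raster_plus_sidecar"
  }
  format <- match.arg(format, c("raster_plus_sidecar", "dicom_rtimage"))
  switch(format,
    raster_plus_sidecar = write_raster_sidecar(img, path),
    dicom_rtimage = write_dicom_rtimage(img, path)
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

write_raster_sidecar <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major: one inplane row at a time
  writeBin(as.vector(t(img$pixels)), con, size = 8, endian = "little")
  meta <- list(
    dtype = "float64_le", order = "row_major",
    rows = nrow(img$pixels), cols = ncol(img$pixels),
    pixel_spacing = img$pixel_spacing, sdd = img$sdd,
    gantry_angle = img$gantry_angle, collimator_angle = img$collimator_angle,
    acquisition_mode = img$acquisition_mode
  )
  yaml::write_yaml(meta, sidecar_path(path))
  path
}

read_raster_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("read_epid_image: missing sidecar file ", sc,
         " (missing pixel_spacing and geometry metadata)")
  meta <- yaml::read_yaml(sc)
  for (f in c("rows", "cols", "pixel_spacing", "sdd", "gantry_angle",
              "collimator_angle")) {
    if (is.null(meta[[f]])) stop("read_epid_image: sidecar missing ", f)
  }
  n <- meta$rows * meta$cols
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    stop("read_epid_image: truncated pixel data (expected ", n,
         " values, got ", length(vals), ")")
  px <- matrix(vals, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
  epid_image(px, meta$pixel_spacing, meta$sdd, meta$gantry_angle,
             meta$collimator_angle,
             if (is.null(meta$acquisition_mode)) "integrated" else meta$acquisition_mode)
}

#' Write a profile or measurement table as CSV
#'
#' Thin wrapper kept for a uniform export surface.
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
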