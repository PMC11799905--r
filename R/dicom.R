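# Minimal DICOM RT Image codec (explicit VR little endian only).
# No R DICOM reader exists in this package's dependency tier, so the small
# subset needed here -- 16-bit monochrome pixel data plus the geometry tags
# of the RT Image module -- is implemented directly.  Sequences and other
# transfer syntaxes are out of scope and rejected loudly.

RTIMAGE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.1"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  # explicit VR: OB/OW/UN/SQ/UT carry a 2-byte reserved field + 4-byte length
  long_form <- vr %in% c("OB", "OW", "UN", "SQ", "UT")
  len <- length(value_raw)
  if (len %% 2 == 1) {  # even-length padding
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1
  }
  c(.u16(group), .u16(elem), charToRaw(vr),
    if (long_form) c(as.raw(c(0, 0)), .u32(len)) else .u16(len),
    value_raw)
}

dcm_str_element <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(as.character(s)))
}

dcm_ds <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

write_dicom_rtimage <- function(img, path) {
  px <- img$pixels
  mx <- max(px)
  slope <- if (mx > 0) mx / 65535 else 1
  stored <- matrix(as.integer(round(px / slope)), nrow(px), ncol(px))
  sid_mm <- img$sdd * 10
  sad_mm <- 1000  # SAD fixed at 100 cm; detector spacing = iso spacing * SID/SAD
  det_spacing <- img$pixel_spacing * sid_mm / sad_mm
  # deterministic pseudo-UID: derived from image shape and content, no RNG
  uid <- sprintf("1.2.826.0.1.3680043.9999.%d.%d.%.0f",
                 nrow(px), ncol(px), sum(as.numeric(stored)) %% 1e8)

  ds <- c(
    dcm_str_element(0x0008, 0x0016, "UI", RTIMAGE_SOP_CLASS),
    dcm_str_element(0x0008, 0x0018, "UI", uid),
    dcm_str_element(0x0008, 0x0060, "CS", "RTIMAGE"),
    dcm_element(0x0028, 0x0002, "US", .u16(1)),
    dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", .u16(nrow(px))),
    dcm_element(0x0028, 0x0011, "US", .u16(ncol(px))),
    dcm_element(0x0028, 0x0100, "US", .u16(16)),
    dcm_element(0x0028, 0x0101, "US", .u16(16)),
    dcm_element(0x0028, 0x0102, "US", .u16(15)),
    dcm_element(0x0028, 0x0103, "US", .u16(0)),
    dcm_str_element(0x0028, 0x1052, "DS", "0"),
    dcm_str_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
    dcm_str_element(0x3002, 0x0011, "DS",
                    paste(dcm_ds(det_spacing), dcm_ds(det_spacing), sep = "\\")),
    dcm_str_element(0x3002, 0x000C, "CS", img$acquisition_mode),
    dcm_str_element(0x3002, 0x0022, "DS", dcm_ds(sad_mm)),
    dcm_str_element(0x3002, 0x0026, "DS", dcm_ds(sid_mm)),
    dcm_str_element(0x300A, 0x011E, "DS", dcm_ds(img$gantry_angle)),
    dcm_str_element(0x300A, 0x0120, "DS", dcm_ds(img$collimator_angle)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.vector(t(stored)), raw(), size = 2, endian = "little"))
  )

  meta_body <- c(
    dcm_str_element(0x0002, 0x0002, "UI", RTIMAGE_SOP_CLASS),
    dcm_str_element(0x0002, 0x0003, "UI", uid),
    dcm_str_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", .u32(length(meta_body))), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  path
}

read_dicom_rtimage <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 132 || !identical(buf[129:132], charToRaw("DICM")))
    stop("read_epid_image: not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  tags <- list()
  n <- length(buf)
  rd_u16 <- function(at) readBin(buf[at:(at + 1)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
  rd_u32 <- function(at) readBin(buf[at:(at + 3)], "integer", size = 4,
                                 endian = "little")
  while (pos + 7 <= n) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("read_epid_image: unsupported transfer syntax (implicit VR?) in ", path)
    if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
      len <- rd_u32(pos + 8L); hdr <- 12L
    } else {
      len <- rd_u16(pos + 6L); hdr <- 8L
    }
    if (vr == "SQ") stop("read_epid_image: DICOM sequences are not supported")
    val <- if (len > 0) buf[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tags[[dcm_tag(group, elem)]] <- list(vr = vr, bytes = val)
    pos <- pos + hdr + len
  }
  get_str <- function(tag, what) {
    el <- tags[[tag]]
    if (is.null(el)) stop("read_epid_image: DICOM file missing ", what,
                          " (tag ", tag, ")")
    trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))  # drop UI nul padding
  }
  get_num <- function(tag, what) as.numeric(get_str(tag, what))

  ts <- get_str("0002,0010", "transfer syntax UID")
  if (ts != TS_EXPLICIT_LE)
    stop("read_epid_image: unsupported transfer syntax ", ts)

  rows <- readBin(tags[["0028,0010"]]$bytes, "integer", size = 2,
                  endian = "little", signed = FALSE)
  cols <- readBin(tags[["0028,0011"]]$bytes, "integer", size = 2,
                  endian = "little", signed = FALSE)
  spacing <- get_str("3002,0011", "pixel_spacing (ImagePlanePixelSpacing)")
  det_spacing <- as.numeric(strsplit(spacing, "\\", fixed = TRUE)[[1]][1])
  sid_mm <- get_num("3002,0026", "sdd (RTImageSID)")
  sad_mm <- get_num("3002,0022", "SAD (RadiationMachineSAD)")
  gantry <- get_num("300A,011E", "gantry_angle")
  coll <- get_num("300A,0120", "collimator_angle")
  slope <- if (!is.null(tags[["0028,1053"]])) get_num("0028,1053", "rescale slope") else 1
  icpt <- if (!is.null(tags[["0028,1052"]])) get_num("0028,1052", "rescale intercept") else 0
  mode <- if (!is.null(tags[["3002,000C"]]))
    tolower(get_str("3002,000C", "acquisition mode")) else "integrated"
  if (!mode %in% c("integrated", "cine_frame")) mode <- "integrated"

  pel <- tags[["7FE0,0010"]]
  if (is.null(pel)) stop("read_epid_image: DICOM file missing pixel data")
  expected <- as.numeric(rows) * cols * 2
  if (length(pel$bytes) < expected)
    stop("read_epid_image: truncated pixel data (", length(pel$bytes),
         " bytes, expected ", expected, ")")
  stored <- readBin(pel$bytes, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = FALSE)
  px <- matrix(stored * slope + icpt, nrow = rows, ncol = cols, byrow = TRUE)
  epid_image(px, det_spacing * sad_mm / sid_mm, sid_mm / 10, gantry, coll, mode)
}
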