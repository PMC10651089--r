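#' Read a TIFF z-stack into a calibrated stack
#'
#' Reads a single-channel 3D stack from a (baseline or ImageJ-hyperstack) TIFF
#' file. Voxel calibration is recovered from the X/Y resolution tags together
#' with an ImageJ-style description block (`spacing=`, `unit=`); only `micron`
#' (`um`) and `nm` units are interpreted — any other unit leaves the
#' calibration absent (`NA`). Multi-channel hyperstacks are reduced to one
#' channel: the lowest channel index by default.
#'
#' @param path Path to a readable TIFF file.
#' @param channel Optional 0-based channel override; default is channel 0.
#' @return A [psf_stack()] with axis order `(z, y, x)` and intensities promoted
#'   to double.
#' @details Files whose page layout cannot be interpreted unambiguously
#'   (time-lapse `frames > 1`, or a page count inconsistent with the declared
#'   `channels`/`slices`) are rejected rather than guessed at: a silently
#'   misread axis order would corrupt every derived FWHM.
#' @export
read_stack <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    # as.is = TRUE keeps integer data in original counts; float images reject
    # it, so fall back (floats are stored unscaled either way).
    tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
             error = function(e) {
               if (grepl("as.is", conditionMessage(e), fixed = TRUE)) {
                 tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
               } else stop(e)
             }),
    error = function(e) stop("format error: cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("format error: empty TIFF", call. = FALSE)

  meta <- parse_tiff_metadata(attributes(pages[[1]]))

  # Per-page extra sample dimension (e.g. RGB) counts as channels.
  page_channels <- if (length(dim(pages[[1]])) == 3L) dim(pages[[1]])[3] else 1L
  ch <- if (is.null(channel)) 0L else as.integer(channel)
  if (ch < 0L) stop("channel index must be >= 0", call. = FALSE)

  if (page_channels > 1L) {
    if (ch >= page_channels) stop("channel ", ch, " not present (", page_channels, " channels)", call. = FALSE)
    pages <- lapply(pages, function(p) p[, , ch + 1L])
  } else if (meta$channels > 1L) {
    if (meta$frames > 1L) {
      stop("dimension error: time-lapse hyperstacks (frames > 1) are ambiguous; supply a single z-stack", call. = FALSE)
    }
    if (length(pages) %% meta$channels != 0L) {
      stop("dimension error: page count ", length(pages),
           " inconsistent with channels=", meta$channels, call. = FALSE)
    }
    if (ch >= meta$channels) {
      stop("channel ", ch, " not present (", meta$channels, " channels)", call. = FALSE)
    }
    # ImageJ page order is channel-fastest (CZT).
    pages <- pages[seq(ch + 1L, length(pages), by = meta$channels)]
  } else if (meta$frames > 1L) {
    stop("dimension error: time-lapse hyperstacks (frames > 1) are ambiguous; supply a single z-stack", call. = FALSE)
  } else if (ch > 0L) {
    stop("channel ", ch, " not present (single-channel file)", call. = FALSE)
  }
  if (meta$slices > 0L && meta$slices != length(pages)) {
    stop("dimension error: page count ", length(pages),
         " inconsistent with declared slices=", meta$slices, call. = FALSE)
  }

  nz <- length(pages)
  if (nz < 3L) {
    stop("dimension error: a z-stack with >= 3 planes is required (got ", nz, " plane(s))",
         call. = FALSE)
  }
  dims <- dim(pages[[1]])[1:2]
  arr <- array(NA_real_, c(nz, dims[1], dims[2]))
  for (k in seq_len(nz)) {
    p <- pages[[k]]
    if (!identical(dim(p)[1:2], dims)) stop("format error: inconsistent page dimensions", call. = FALSE)
    arr[k, , ] <- p
  }

  psf_stack(arr, dx = meta$dx, dy = meta$dy, dz = meta$dz,
            source_name = basename(path), channel_index = ch)
}

# Extract dx/dy/dz (nm) and hyperstack layout from readTIFF attributes.
parse_tiff_metadata <- function(att) {
  out <- list(dx = NA_real_, dy = NA_real_, dz = NA_real_,
              channels = 1L, slices = 0L, frames = 1L)
  desc <- att$description
  kv <- list()
  if (is.character(desc) && length(desc) == 1L && nzchar(desc)) {
    lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      p <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(p) >= 2L) kv[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
    }
  }
  num <- function(key) suppressWarnings(as.numeric(kv[[key]]))
  int <- function(key) { v <- num(key); if (length(v) == 1L && is.finite(v)) as.integer(v) else NA_integer_ }
  if (!is.na(int("channels"))) out$channels <- int("channels")
  if (!is.na(int("slices")))   out$slices   <- int("slices")
  if (!is.na(int("frames")))   out$frames   <- int("frames")

  # nm per declared unit; anything outside micron/nm is not interpreted.
  unit <- kv[["unit"]]
  mult <- if (is.null(unit)) NA_real_
          else if (unit %in% c("micron", "um", "µm", "μm")) 1000
          else if (unit == "nm") 1
          else NA_real_
  if (!is.na(mult)) {
    # X/YResolution are pixels per unit.
    if (is.numeric(att$x.resolution) && att$x.resolution > 0) out$dx <- mult / att$x.resolution
    if (is.numeric(att$y.resolution) && att$y.resolution > 0) out$dy <- mult / att$y.resolution
    sp <- num("spacing")
    if (length(sp) == 1L && is.finite(sp) && sp > 0) out$dz <- mult * sp
  }
  out
}

#' Write a stack to an ImageJ-compatible TIFF
#'
#' Writes the stack as an uncompressed 32-bit float grayscale TIFF with one
#' page per z-plane. Calibration is encoded the way ImageJ does it — lateral
#' pixel sizes as rational X/Y resolution tags (pixels per micron) and the
#' axial step as `spacing=` in the description block — so that [read_stack()]
#' (and ImageJ itself) recovers it. Absent (`NA`) calibration values are simply
#' omitted and read back as absent.
#'
#' @param stack A [psf_stack()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_psf_stack(stack))
  cal <- stack$calibration
  nz <- dim(stack$data)[1]

  desc <- paste0("ImageJ=1.53t\nimages=", nz, "\nslices=", nz,
                 "\nhyperstack=true\nmode=grayscale\n")
  if (!is.na(cal$dz)) desc <- paste0(desc, "spacing=", format(cal$dz / 1000, digits = 17), "\n")
  if (!is.na(cal$dx) || !is.na(cal$dy) || !is.na(cal$dz)) desc <- paste0(desc, "unit=micron\n")

  pages <- lapply(seq_len(nz), function(k) stack$data[k, , ])
  write_tiff_pages(pages, path, description = desc,
                   xres_per_um = if (is.na(cal$dx)) NA_real_ else 1000 / cal$dx,
                   yres_per_um = if (is.na(cal$dy)) NA_real_ else 1000 / cal$dy)
  invisible(path)
}

# Minimal baseline TIFF writer (little-endian, float32, one strip per page).
# The installed TIFF bindings cannot emit description/resolution tags, which
# the calibration round trip requires, hence this dedicated writer; files are
# read back through the independent libtiff-based reader in tests.
write_tiff_pages <- function(pages, path, description = NULL,
                             xres_per_um = NA_real_, yres_per_um = NA_real_) {
  stopifnot(is.list(pages), length(pages) >= 1L, is.matrix(pages[[1]]))
  n <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  page_bytes <- ny * nx * 4L

  has_res <- !is.na(xres_per_um) && !is.na(yres_per_um)
  desc_raw <- NULL
  desc_count <- 0L
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    desc_count <- length(desc_raw)             # ASCII count includes one NUL
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  # Layout: header | page data | description | rationals | IFDs
  data_off <- 8L + (seq_len(n) - 1L) * page_bytes
  ext_off <- 8L + n * page_bytes
  desc_off <- if (!is.null(desc_raw)) ext_off else NA_integer_
  ext_off <- ext_off + if (!is.null(desc_raw)) length(desc_raw) else 0L
  xres_off <- if (has_res) ext_off else NA_integer_
  yres_off <- if (has_res) ext_off + 8L else NA_integer_
  ext_off <- ext_off + if (has_res) 16L else 0L

  n_entries <- function(k) {
    10L + (if (k == 1L && !is.null(desc_raw)) 1L else 0L) + (if (k == 1L && has_res) 3L else 0L)
  }
  ifd_sizes <- vapply(seq_len(n), function(k) 2L + n_entries(k) * 12L + 4L, integer(1))
  ifd_off <- ext_off + c(0L, cumsum(ifd_sizes))[seq_len(n)]

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot open '", path, "' for writing", call. = FALSE))
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")

  # header
  writeBin(charToRaw("II"), con)
  w2(42L); w4(ifd_off[1])
  # pixel data, row-major within each page
  for (p in pages) writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  # out-of-line values
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  if (has_res) {
    for (r in c(xres_per_um, yres_per_um)) { w4(round(r * 1e6)); w4(1e6) }
  }
  # IFDs
  entry <- function(tag, type, count, value, is_short = FALSE) {
    w2(tag); w2(type); w4(count)
    if (is_short) { w2(value); w2(0L) } else w4(value)
  }
  for (k in seq_len(n)) {
    w2(n_entries(k))
    entry(256L, 4L, 1L, nx)                      # ImageWidth
    entry(257L, 4L, 1L, ny)                      # ImageLength
    entry(258L, 3L, 1L, 32L, is_short = TRUE)    # BitsPerSample
    entry(259L, 3L, 1L, 1L, is_short = TRUE)     # Compression: none
    entry(262L, 3L, 1L, 1L, is_short = TRUE)     # Photometric: BlackIsZero
    if (k == 1L && !is.null(desc_raw)) entry(270L, 2L, desc_count, desc_off)
    entry(273L, 4L, 1L, data_off[k])             # StripOffsets
    entry(277L, 3L, 1L, 1L, is_short = TRUE)     # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                      # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)              # StripByteCounts
    if (k == 1L && has_res) {
      entry(282L, 5L, 1L, xres_off)              # XResolution
      entry(283L, 5L, 1L, yres_off)              # YResolution
      entry(296L, 3L, 1L, 1L, is_short = TRUE)   # ResolutionUnit: none (unit in description)
    }
    entry(339L, 3L, 1L, 3L, is_short = TRUE)     # SampleFormat: IEEE float
    w4(if (k < n) ifd_off[k + 1L] else 0L)
  }
  invisible(path)
}
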