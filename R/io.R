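# Volume I/O.  No NIfTI/TIFF package ships with the analysis environment, so
# minimal readers/writers for the two formats are implemented here by hand:
# NIfTI-1 single-file (.nii) with spacing in the header, and baseline
# uncompressed grayscale multi-page TIFF.

NIFTI_DTYPES <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L, 512L),
  what = c("integer", "integer", "integer", "numeric", "numeric", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))

#' Write a voxel grid as NIfTI-1
#'
#' Grayscale volumes are stored as float64 (bit-exact round trip), label
#' volumes as int32.  Spacing (um) goes into `pixdim`, with spatial units
#' flagged as micrometres.
#'
#' @param grid a `voxel_grid`.
#' @param path output path (conventionally `.nii`).
#' @export
write_nifti <- function(grid, path) {
  stopifnot_voxel_grid(grid)
  d <- dim(grid$data)
  labels <- grid$kind == "labels"
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348, 4)                          # sizeof_hdr
  wc(36)                              # data_type..dim_info
  wi(c(3, d, 1, 1, 1, 1), 2)          # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)            # intent
  wi(if (labels) 8 else 64, 2)        # datatype: int32 / float64
  wi(if (labels) 32 else 64, 2)       # bitpix
  wi(0, 2)                            # slice_start
  wf(c(1, grid$spacing, 1, 1, 1, 1))  # pixdim[8]
  wf(352)                             # vox_offset
  wf(1); wf(0)                        # scl_slope, scl_inter
  wi(0, 2); wc(1)                     # slice_end, slice_code
  writeBin(as.raw(3L), con)           # xyzt_units: micron
  wf(c(0, 0, 0, 0)); wi(c(0, 0), 4)   # cal/slice_duration/toffset/glmax/glmin
  wc(80 + 24)                         # descrip, aux_file
  wi(c(0, 0), 2)                      # qform_code, sform_code
  wf(rep(0, 6))                       # quatern/qoffset
  wf(c(grid$spacing[1], 0, 0, grid$origin[1],
       0, grid$spacing[2], 0, grid$origin[2],
       0, 0, grid$spacing[3], grid$origin[3]))
  wc(16)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  wc(4)                               # extension flag
  if (labels) {
    writeBin(as.integer(grid$data), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(grid$data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Minimal single-file reader: 3D volumes, datatypes uint8/int16/int32/
#' float32/float64/uint16, either endianness, `scl_slope` honoured.
#'
#' @param path a `.nii` file.
#' @param kind override the grid kind; default infers `labels` for integer
#'   datatypes.
#' @return a `voxel_grid`.
#' @export
read_nifti <- function(path, kind = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348) stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  if (dims[1] < 3) stop("expected a 3D volume")
  d <- dims[2:4]
  seek(con, 70)
  dtype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  row <- NIFTI_DTYPES[NIFTI_DTYPES$code == dtype, ]
  if (nrow(row) == 0) stop("unsupported NIfTI datatype ", dtype)
  seek(con, vox_offset)
  n <- prod(d)
  x <- readBin(con, row$what, n, size = row$size, signed = row$signed,
               endian = endian)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  if (is.null(kind)) kind <- if (row$what == "integer" &&
                                 !(scl_slope != 0 && scl_slope != 1))
    "labels" else "grayscale"
  spacing <- pixdim[2:4]
  if (any(spacing <= 0)) spacing <- rep(1, 3)
  voxel_grid(array(x, d), spacing, kind = kind)
}

# -- TIFF --------------------------------------------------------------------

#' Write a grayscale voxel grid as an uncompressed 16-bit multi-page TIFF
#'
#' One page per slice along the third axis.  Grayscale values are expected in
#' \[0, 1\] and scaled to the full 16-bit range; TIFF carries no physical
#' spacing, so [read_tiff()] requires a spacing argument.
#'
#' @param grid a grayscale `voxel_grid` with values in \[0, 1\].
#' @param path output path.
#' @export
write_tiff <- function(grid, path) {
  stopifnot_voxel_grid(grid)
  d <- dim(grid$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)
  page_bytes <- nx * ny * 2
  ifd_start <- 8 + nz * page_bytes
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  vals <- pmin(pmax(grid$data, 0), 1)
  vals <- as.integer(round(vals * 65535))
  for (k in seq_len(nz)) {
    v <- vals[seq((k - 1) * nx * ny + 1, k * nx * ny)]
    # writeBin has no uint16: write as raw pairs
    r <- as.raw(c(rbind(v %% 256L, v %/% 256L)))
    writeBin(r, con)
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  ifd_size <- 2 + 9 * 12 + 4
  for (k in seq_len(nz)) {
    writeBin(as.integer(9), con, size = 2, endian = "little")
    entry(256, 4, 1, nx)                        # ImageWidth
    entry(257, 4, 1, ny)                        # ImageLength
    entry(258, 3, 1, 16)                        # BitsPerSample
    entry(259, 3, 1, 1)                         # Compression: none
    entry(262, 3, 1, 1)                         # Photometric: BlackIsZero
    entry(273, 4, 1, 8 + (k - 1) * page_bytes)  # StripOffsets
    entry(277, 3, 1, 1)                         # SamplesPerPixel
    entry(278, 4, 1, ny)                        # RowsPerStrip
    entry(279, 4, 1, page_bytes)                # StripByteCounts
    nxt <- if (k < nz) ifd_start + k * ifd_size else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed grayscale multi-page TIFF stack
#'
#' Baseline reader for 8/16-bit single-sample uncompressed TIFF (little or
#' big endian).  TIFF stores no voxel spacing, so `spacing` is required.
#' 16-bit data are rescaled to \[0, 1\]; 8-bit to \[0, 1\] over 255.
#'
#' @param path TIFF file.
#' @param spacing physical voxel spacing (um), length 3 — mandatory.
#' @return a grayscale `voxel_grid` of shape (width, height, pages).
#' @export
read_tiff <- function(path, spacing = NULL) {
  if (is.null(spacing))
    stop("TIFF carries no voxel spacing: pass spacing = c(dx, dy, dz) in um")
  raw_all <- readBin(path, "raw", file.info(path)$size)
  byte_order <- rawToChar(raw_all[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM")
    "big" else stop("not a TIFF file")
  u16 <- function(off) readBin(raw_all[(off + 1):(off + 2)], "integer",
                               1, size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw_all[(off + 1):(off + 4)], "integer",
                               1, size = 4, endian = endian)
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    nent <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u16(base)
      type <- u16(base + 2)
      count <- u32(base + 4)
      val <- if (type == 3 && count == 1) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, off = base + 8)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    comp <- if ("259" %in% names(tags)) tags[["259"]]$value else 1
    if (comp != 1) stop("only uncompressed TIFF is supported")
    bits <- if ("258" %in% names(tags)) tags[["258"]]$value else 8
    if (!bits %in% c(8, 16)) stop("only 8/16-bit TIFF is supported")
    w <- tags[["256"]]$value
    h <- tags[["257"]]$value
    nstrip <- tags[["273"]]$count
    offs <- if (nstrip == 1) tags[["273"]]$value else
      vapply(seq_len(nstrip) - 1,
             function(s) u32(tags[["273"]]$value + 4 * s), numeric(1))
    cnts <- if (nstrip == 1) tags[["279"]]$value else
      vapply(seq_len(nstrip) - 1,
             function(s) u32(tags[["279"]]$value + 4 * s), numeric(1))
    pix <- integer(0)
    for (s in seq_len(nstrip)) {
      bytes <- raw_all[(offs[s] + 1):(offs[s] + cnts[s])]
      pix <- c(pix, if (bits == 16)
        readBin(bytes, "integer", cnts[s] / 2, size = 2, signed = FALSE,
                endian = endian)
        else as.integer(bytes))
    }
    pages[[length(pages) + 1]] <- list(w = w, h = h, bits = bits, pix = pix)
    ifd_off <- u32(ifd_off + 2 + nent * 12)
  }
  w <- pages[[1]]$w; h <- pages[[1]]$h; bits <- pages[[1]]$bits
  arr <- array(0, c(w, h, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]$pix
  arr <- arr / (2^bits - 1)
  voxel_grid(arr, spacing, kind = "grayscale")
}

# -- generic volume front door ----------------------------------------------

#' Read a volume from NIfTI-1 or TIFF
#'
#' Dispatches on the file extension.  NIfTI carries its spacing; TIFF
#' requires `spacing_override`.
#'
#' @param path `.nii`, `.tif` or `.tiff` file.
#' @param spacing_override spacing (um) for TIFF, or to override the NIfTI
#'   header.
#' @param kind optional grid kind override.
#' @return a `voxel_grid`.
#' @export
read_volume <- function(path, spacing_override = NULL, kind = NULL) {
  ext <- tolower(tools::file_ext(path))
  g <- switch(ext,
              nii = read_nifti(path, kind = kind),
              tif = ,
              tiff = read_tiff(path, spacing = spacing_override),
              stop("unsupported volume format: .", ext))
  if (!is.null(spacing_override)) g$spacing <- as.numeric(spacing_override)
  if (!is.null(kind)) g$kind <- kind
  g
}

#' Write a volume as NIfTI-1 or TIFF by extension
#' @param grid a `voxel_grid`
#' @param path output path (`.nii`, `.tif`, `.tiff`)
#' @export
write_volume <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nii = write_nifti(grid, path),
         tif = ,
         tiff = write_tiff(grid, path),
         stop("unsupported volume format: .", ext))
}

# -- seeds, graphs, reports --------------------------------------------------

#' Read seed points from CSV or JSON
#'
#' CSV columns: `x`, `y`, `z` (um) and optionally `type`.
#' @param path file path.
#' @return a [seed_points()] data.frame.
#' @export
read_seeds <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$type)) df$type <- "unknown"
  seed_points(df$x, df$y, df$z, df$type)
}

#' Serialize a skeleton graph to JSON
#' @param graph a `skeleton_graph`
#' @param path output path
#' @export
write_skeleton_json <- function(graph, path) {
  obj <- list(
    nodes = graph$nodes,
    edges = lapply(graph$edges, function(e) list(
      node_a = e$node_a, node_b = e$node_b, length_um = e$length,
      points_um = unname(e$points),
      radius_um = if (is.null(e$radius)) NULL else e$radius)),
    spacing_um = graph$spacing)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @noRd
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) # fold into 31 bits to stay integer
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
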