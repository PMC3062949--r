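# Format dispatch by file extension.
volumeFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "nrrd") return("nrrd")
  if (ext == "mhd") return("mhd")
  stop("unsupported volume format '.", ext, "'; supported: ",
       ".tif/.tiff (multi-page stack), .nrrd, .mhd (+.raw)")
}

rawTypeInfo <- function(type) {
  switch(type,
         double = list(what = "double", size = 8L, signed = TRUE),
         float = list(what = "double", size = 4L, signed = TRUE),
         short = list(what = "integer", size = 2L, signed = TRUE),
         ushort = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported element type '", type, "'"))
}

writeRawData <- function(con, data, type) {
  ti <- rawTypeInfo(type)
  v <- as.vector(data)
  if (ti$what == "integer") {
    v <- round(v)
    if (type == "ushort") {
      if (any(v < 0 | v > 65535))
        stop("intensities outside [0, 65535] cannot be stored as ushort")
      v <- ifelse(v > 32767, v - 65536, v)  # wraps back on unsigned read
    } else if (any(v < -32768 | v > 32767)) {
      stop("intensities outside short range")
    }
    writeBin(as.integer(v), con, size = ti$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = ti$size, endian = "little")
  }
}

readRawData <- function(con, n, type, endian = "little") {
  ti <- rawTypeInfo(type)
  v <- readBin(con, what = ti$what, n = n, size = ti$size,
               signed = ti$signed, endian = endian)
  if (length(v) < n)
    stop("truncated data: expected ", n, " voxels, read ", length(v))
  as.double(v)
}

#' Read and write 3D volumes
#'
#' Formats are selected by extension: multi-page TIFF stacks (\code{.tif} /
#' \code{.tiff}), NRRD (\code{.nrrd}, raw encoding) and MetaImage
#' (\code{.mhd} header + \code{.raw} companion). NRRD and MetaImage carry
#' voxel spacing and origin and store intensities at their native
#' calibration (\code{double}, \code{float}, \code{short} or \code{ushort}
#' element types, bit-exact round-trip for the integer types). TIFF stores
#' normalized intensities in [0, 1] (16- or 32-bit samples) and no 3D
#' spacing, so it is intended for visualization exports; writing values
#' outside [0, 1] rescales them with a warning.
#'
#' Voxel order on disk is x fastest, then y, then z, matching the in-memory
#' column-major array.
#'
#' @param path file path with a supported extension.
#' @param vol a [Volume-class].
#' @param type element type for NRRD/MetaImage: \code{"double"},
#'   \code{"float"}, \code{"short"} or \code{"ushort"}.
#' @param bitsPerSample TIFF sample width, 16 or 32.
#' @return \code{readVolume} returns a [Volume-class]; \code{writeVolume}
#'   returns \code{path} invisibly.
#' @export
readVolume <- function(path) {
  fmt <- volumeFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(fmt,
         tiff = readVolumeTiff(path),
         nrrd = readVolumeNrrd(path),
         mhd = readVolumeMhd(path))
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path, type = "double", bitsPerSample = 32L) {
  if (!is(vol, "Volume")) stop("'vol' must be a Volume")
  switch(volumeFormat(path),
         tiff = writeVolumeTiff(vol, path, bitsPerSample),
         nrrd = writeVolumeNrrd(vol, path, type),
         mhd = writeVolumeMhd(vol, path, type))
  invisible(path)
}

# ---- TIFF ------------------------------------------------------------------

writeVolumeTiff <- function(vol, path, bitsPerSample = 32L) {
  dat <- vol@data
  rng <- range(dat)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("intensities outside [0, 1] rescaled for TIFF storage; ",
            "use NRRD/MetaImage to keep calibration")
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    dat <- (dat - rng[1]) / span
  }
  slices <- lapply(seq_len(dim(dat)[3]), function(k) t(dat[, , k]))
  tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bitsPerSample),
                  compression = "none")
}

readVolumeTiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 3L) s <- s[, , 1]  # first channel
    t(s)
  })
  d <- dim(slices[[1]])
  arr <- array(unlist(slices, use.names = FALSE),
               c(d[1], d[2], length(slices)))
  Volume(arr)
}

# ---- NRRD ------------------------------------------------------------------

nrrdTypeName <- c(double = "double", float = "float", short = "short",
                  ushort = "unsigned short")

writeVolumeNrrd <- function(vol, path, type = "double") {
  if (!type %in% names(nrrdTypeName))
    stop("unsupported element type '", type, "'")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", nrrdTypeName[[type]]),
           "dimension: 3",
           paste0("sizes: ", paste(dim(vol@data), collapse = " ")),
           paste0("spacings: ", paste(format(vol@spacing, digits = 17),
                                      collapse = " ")),
           paste0("axis mins: ", paste(format(vol@origin, digits = 17),
                                       collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeRawData(con, vol@data, type)
}

readVolumeNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  enc <- tolower(fields[["encoding"]] %||% "raw")
  if (enc != "raw")
    stop("only raw NRRD encoding is supported (got '", enc, "')")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  typeName <- fields[["type"]]
  type <- names(nrrdTypeName)[match(typeName, nrrdTypeName)]
  if (is.na(type))
    type <- switch(typeName, "uint16" = "ushort", "int16" = "short",
                   "float32" = "float", "float64" = "double",
                   stop("unsupported NRRD type '", typeName, "'"))
  endian <- tolower(fields[["endian"]] %||% "little")
  dat <- readRawData(con, prod(sizes), type, endian = endian)
  sp <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], "\\s+")[[1]]) else c(0, 0, 0)
  Volume(array(dat, sizes), spacing = sp, origin = org)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- MetaImage -------------------------------------------------------------

mhdTypeName <- c(double = "MET_DOUBLE", float = "MET_FLOAT",
                 short = "MET_SHORT", ushort = "MET_USHORT")

writeVolumeMhd <- function(vol, path, type = "double") {
  if (!type %in% names(mhdTypeName))
    stop("unsupported element type '", type, "'")
  rawName <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste0("DimSize = ", paste(dim(vol@data), collapse = " ")),
           paste0("ElementSpacing = ", paste(format(vol@spacing, digits = 17),
                                             collapse = " ")),
           paste0("Offset = ", paste(format(vol@origin, digits = 17),
                                     collapse = " ")),
           paste0("ElementType = ", mhdTypeName[[type]]),
           paste0("ElementDataFile = ", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  writeRawData(con, vol@data, type)
}

readVolumeMhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  fields <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = " "), character(1)),
    vapply(kv, `[[`, character(1), 1))
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D MetaImage volumes are supported")
  type <- names(mhdTypeName)[match(fields[["ElementType"]], mhdTypeName)]
  if (is.na(type))
    stop("unsupported MetaImage element type '", fields[["ElementType"]], "'")
  msb <- isTRUE(toupper(fields["BinaryDataByteOrderMSB"]) == "TRUE") ||
    isTRUE(toupper(fields["ElementByteOrderMSB"]) == "TRUE")
  rawPath <- file.path(dirname(path), fields[["ElementDataFile"]])
  if (!file.exists(rawPath))
    stop("missing .raw companion file: ", rawPath)
  con <- file(rawPath, "rb")
  on.exit(close(con))
  dat <- readRawData(con, prod(sizes), type,
                     endian = if (msb) "big" else "little")
  sp <- if (!is.na(fields["ElementSpacing"]))
    as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]])
  else c(1, 1, 1)
  org <- if (!is.na(fields["Offset"]))
    as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  Volume(array(dat, sizes), spacing = sp, origin = org)
}

# ---- MIP -------------------------------------------------------------------

#' Maximum intensity projection
#'
#' Projects a volume onto a 2D image by taking the maximum intensity along
#' rays parallel to the chosen axis — the standard way to visualize a
#' filtered vascular volume.
#'
#' @param vol a [Volume-class].
#' @param axis 1 (x), 2 (y) or 3 (z), or one of \code{"x"}, \code{"y"},
#'   \code{"z"}.
#' @return a 2D matrix over the two remaining axes, in their original order.
#' @export
mipProject <- function(vol, axis = 3) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(axis) || !axis %in% 1:3) stop("'axis' must be x/y/z or 1/2/3")
  apply(vol@data, setdiff(1:3, axis), max)
}
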