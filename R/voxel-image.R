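#' Voxel image container
#'
#' A minimal carrier for 3D voxel data: a numeric 3D array plus isotropic (or
#' per-axis) voxel spacing in mm and the position of the corner of voxel
#' (1,1,1) in mm. Values are either binary (0/1 segmented bone) or relative
#' densities in \[0, 1\].
#'
#' @param values 3D numeric/logical array of voxel values.
#' @param spacing voxel edge length(s) in mm; scalar (isotropic) or length-3.
#' @param origin mm position of the (1,1,1) voxel corner; default c(0,0,0).
#' @return An object of class `voxel_image` with fields `values`, `spacing`,
#'   `origin`.
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  if (length(origin) != 3L) stop("origin must be length 3")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_image: %d x %d x %d voxels, spacing %s mm, BV/TV %.3f\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              bvtv(x)))
  invisible(x)
}

#' Bone volume fraction of an image
#'
#' @param image a `voxel_image`.
#' @return mean voxel value (BV/TV for a binary image).
#' @export
bvtv <- function(image) mean(image$values)

is_binary_image <- function(image) all(image$values %in% c(0, 1))

#' Write a MetaImage (.mhd + .raw) file pair
#'
#' Uncompressed little-endian MetaImage; binary images are written as
#' MET_UCHAR, other images as MET_DOUBLE.
#'
#' @param image a `voxel_image`.
#' @param path output path ending in `.mhd`; the raw file is written next to it.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(image, path) {
  stopifnot(grepl("\\.mhd$", path))
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(image$values)
  binary <- is_binary_image(image)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            image$spacing[1], image$spacing[2], image$spacing[3]),
    sprintf("Offset = %.9g %.9g %.9g",
            image$origin[1], image$origin[2], image$origin[3]),
    sprintf("ElementType = %s", if (binary) "MET_UCHAR" else "MET_DOUBLE"),
    sprintf("ElementDataFile = %s", basename(raw_path))
  )
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (binary) {
    writeBin(as.raw(as.integer(image$values)), con)
  } else {
    writeBin(as.vector(image$values), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) file pair
#'
#' Supports uncompressed MET_UCHAR, MET_SHORT, MET_USHORT, MET_FLOAT and
#' MET_DOUBLE data written by this package or other tools.
#'
#' @param path path to the `.mhd` header.
#' @return a `voxel_image`.
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  type <- get("ElementType", "MET_UCHAR")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(type,
    MET_UCHAR  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                    endian = "little")),
    MET_USHORT = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                    endian = "little")),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported ElementType: ", type)
  )
  voxel_image(array(v, dim = d), spacing, origin)
}

#' Write an NRRD file
#'
#' Attached-header NRRD (raw encoding, little-endian); binary images as uint8,
#' others as double.
#'
#' @param image a `voxel_image`.
#' @param path output path ending in `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(image, path) {
  d <- dim(image$values)
  binary <- is_binary_image(image)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (binary) "uint8" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.9g %.9g %.9g",
            image$spacing[1], image$spacing[2], image$spacing[3]),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (binary) {
    writeBin(as.raw(as.integer(image$values)), con)
  } else {
    writeBin(as.vector(image$values), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD file
#'
#' Attached-header raw-encoded NRRD with uint8, short, float or double data.
#'
#' @param path path to the `.nrrd` file.
#' @return a `voxel_image`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header bytes until the blank line
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("truncated NRRD header")
    hdr_raw <- c(hdr_raw, b)
    nh <- length(hdr_raw)
    if (nh >= 2 && hdr_raw[nh] == as.raw(10) && hdr_raw[nh - 1] == as.raw(10)) break
  }
  lines <- strsplit(rawToChar(hdr_raw), "\n")[[1]]
  field <- function(name, default = NULL) {
    hit <- grep(paste0("^", name, ":"), lines, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^", name, ":"), "", hit[1]))
  }
  d <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(field("spacings", "1 1 1"), "\\s+")[[1]])
  type <- field("type", "uint8")
  n <- prod(d)
  v <- switch(type,
    uint8 = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    short = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    float = readBin(con, "numeric", n, size = 4, endian = "little"),
    double = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NRRD type: ", type)
  )
  voxel_image(array(v, dim = d), spacing)
}

#' Write a voxel image, format chosen by extension
#'
#' @param image a `voxel_image`.
#' @param path `.mhd` or `.nrrd` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (grepl("\\.mhd$", path)) write_mhd(image, path)
  else if (grepl("\\.nrrd$", path)) write_nrrd(image, path)
  else stop("unsupported image extension (use .mhd or .nrrd): ", path)
}

#' Read a voxel image, format chosen by extension
#'
#' @param path `.mhd` or `.nrrd` path.
#' @return a `voxel_image`.
#' @export
read_image <- function(path) {
  if (grepl("\\.mhd$", path)) read_mhd(path)
  else if (grepl("\\.nrrd$", path)) read_nrrd(path)
  else stop("unsupported image extension (use .mhd or .nrrd): ", path)
}
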