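#' Write a volume in NRRD format
#'
#' Minimal attached-data NRRD writer (format version 4) for 3-D integer
#' label maps and floating-point intensity volumes, compatible with the
#' conventions of 3D Slicer exports (space directions from the voxel
#' spacing, `space origin` in mm).
#'
#' @param x a [label_volume()] or a plain 3-D numeric array.
#' @param path output path (`.nrrd`).
#' @param encoding `"raw"` or `"gzip"`.
#' @param spacing,origin used when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "gzip"),
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  encoding <- match.arg(encoding)
  if (inherits(x, "label_volume")) {
    arr <- x$voxels; spacing <- x$spacing; origin <- x$origin
    type <- "int"
  } else {
    arr <- as.array(x)
    type <- if (is.integer(arr)) "int" else "double"
  }
  stopifnot(length(dim(arr)) == 3)
  hdr <- c(
    "NRRD0004",
    "# produced by rhinoflow",
    sprintf("type: %s", type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
    "", "")  # blank line terminates the header
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste(hdr, collapse = "\n")), con)
  payload <- if (type == "int")
    writeBin(as.integer(arr), raw(), size = 4, endian = "little")
  else
    writeBin(as.numeric(arr), raw(), size = 8, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the subset written by [write_nrrd()] plus common integer and
#' float types, raw and gzip encodings, little endian, attached data.
#'
#' @param path NRRD path.
#' @param as_labels return a [label_volume()] (integer data only).
#' @param class_names class table when `as_labels = TRUE`.
#' @return A [label_volume()] or a numeric array with attributes
#'   `spacing` and `origin`.
#' @export
read_nrrd <- function(path, as_labels = FALSE,
                      class_names = head_class_table()) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10))
  hdr_end <- NA
  prev <- 0L
  for (k in nl) {
    if (k == prev + 1L) { hdr_end <- k; break }
    prev <- k
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no blank line after header")
  hdr <- strsplit(rawToChar(bytes[1:(hdr_end - 1L)]), "\n")[[1]]
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  type <- field("type")
  encoding <- field("encoding")
  sd <- field("space directions")
  spacing <- c(1, 1, 1)
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    spacing <- vapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
  }
  so <- field("space origin")
  origin <- if (is.null(so)) c(0, 0, 0)
            else as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
  payload <- bytes[(hdr_end + 1L):length(bytes)]
  if (identical(encoding, "gzip"))
    payload <- memDecompress(payload, "gzip")
  n <- prod(sizes)
  arr <- switch(type,
    "int" = , "int32" = , "signed int" =
      array(readBin(payload, "integer", n = n, size = 4,
                    endian = "little"), sizes),
    "short" = , "int16" =
      array(readBin(payload, "integer", n = n, size = 2,
                    endian = "little"), sizes),
    "uchar" = , "uint8" =
      array(as.integer(readBin(payload, "integer", n = n, size = 1,
                               signed = FALSE)), sizes),
    "float" =
      array(readBin(payload, "numeric", n = n, size = 4,
                    endian = "little"), sizes),
    "double" =
      array(readBin(payload, "numeric", n = n, size = 8,
                    endian = "little"), sizes),
    stop("unsupported NRRD type: ", type))
  if (as_labels) {
    storage.mode(arr) <- "integer"
    return(label_volume(arr, spacing = spacing, origin = origin,
                        class_names = class_names))
  }
  attr(arr, "spacing") <- spacing
  attr(arr, "origin") <- origin
  arr
}
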