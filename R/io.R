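#' Read a 3D volume from disk
#'
#' NIfTI-1 (\code{.nii}, \code{.nii.gz}) is the primary on-disk format and
#' the only one used for outputs; MetaImage (\code{.mhd}/\code{.mha}) and
#' NRRD (\code{.nrrd}) volumes are additionally accepted on import. On
#' load, images carrying a usable orientation are reoriented to the RAS
#' anatomical convention so that downstream hemisphere and laterality
#' logic is well defined regardless of acquisition orientation.
#'
#' @param path file path.
#' @param canonical reorient to RAS when the file stores an orientation.
#' @return A [volumetric_image].
#' @export
read_volume <- function(path, canonical = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    read_nifti_volume(path, canonical)
  } else if (grepl("\\.(mhd|mha)$", lower)) {
    read_metaimage_volume(path)
  } else if (grepl("\\.(nrrd|nhdr)$", lower)) {
    read_nrrd_volume(path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
}

#' @rdname read_volume
#' @param kind mask kind, see [label_mask].
#' @export
read_mask <- function(path, kind = "tumor", canonical = TRUE) {
  img <- read_volume(path, canonical = canonical)
  label_mask(round(img$voxels), img, kind = kind)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x a [volumetric_image] or [label_mask].
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "label_mask")) x$labels else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom_spacing(x)
  aff <- diag(4)
  aff[1:3, 1:3] <- geom_orientation(x) %*% diag(geom_spacing(x))
  aff[1:3, 4] <- geom_origin(x)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path, canonical) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume: ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  if (canonical && attr(xf, "code") > 0)
    RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  m <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  spacing[spacing == 0] <- 1
  volumetric_image(array(as.numeric(img), dim(img)), spacing = spacing,
                   origin = xf[1:3, 4],
                   orientation = sweep(m, 2L, spacing, `/`))
}

## Minimal MetaImage reader (uncompressed): header is `Key = Value` text,
## voxel data either LOCAL (appended, .mha) or in the referenced .raw file.
read_metaimage_volume <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw_all == as.raw(10L))
  hdr <- character(); data_at <- NULL; start <- 1L
  for (p in nl) {
    line <- rawToChar(raw_all[start:(p - 1L)])
    hdr <- c(hdr, sub("\r$", "", line))
    start <- p + 1L
    if (grepl("^ElementDataFile", line)) { data_at <- start; break }
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  val <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else kv[[i]][2L]
  }
  dims <- as.integer(strsplit(val("DimSize"), "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D MetaImage supported: ", path, call. = FALSE)
  if (identical(val("CompressedData", "False"), "True"))
    stop("compressed MetaImage not supported: ", path, call. = FALSE)
  spacing <- as.numeric(strsplit(val("ElementSpacing", "1 1 1"), "\\s+")[[1L]])
  origin <- as.numeric(strsplit(val("Offset", val("Position", "0 0 0")), "\\s+")[[1L]])
  tm <- as.numeric(strsplit(val("TransformMatrix", "1 0 0 0 1 0 0 0 1"), "\\s+")[[1L]])
  type <- val("ElementType", "MET_FLOAT")
  datafile <- val("ElementDataFile")
  bytes <- if (identical(datafile, "LOCAL")) raw_all[data_at:length(raw_all)] else {
    f <- file.path(dirname(path), datafile)
    readBin(f, "raw", file.info(f)$size)
  }
  vox <- decode_raw_voxels(bytes, type_map_met(type), prod(dims),
                           msb = identical(val("BinaryDataByteOrderMSB", "False"), "True"))
  volumetric_image(array(vox, dims), spacing = spacing, origin = origin,
                   orientation = matrix(tm, 3L, 3L, byrow = TRUE))
}

## Minimal NRRD reader: attached data only, raw or gzip encoding.
read_nrrd_volume <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw_all == as.raw(10L))
  hdr <- character(); data_at <- NULL; start <- 1L
  for (p in nl) {
    line <- if (p == start) "" else
      sub("\r$", "", rawToChar(raw_all[start:(p - 1L)]))
    start <- p + 1L
    if (nchar(line) == 0L) { data_at <- start; break }
    hdr <- c(hdr, line)
  }
  if (is.null(data_at)) stop("malformed NRRD (no blank line): ", path, call. = FALSE)
  hdr <- hdr[!grepl("^#", hdr)][-1L]            # drop magic and comments
  kv <- strsplit(hdr, ":\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  val <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else kv[[i]][2L]
  }
  if (!is.na(match("data file", keys)))
    stop("detached NRRD headers not supported: ", path, call. = FALSE)
  dims <- as.integer(strsplit(val("sizes"), "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D NRRD supported: ", path, call. = FALSE)
  enc <- val("encoding", "raw")
  bytes <- raw_all[data_at:length(raw_all)]
  if (enc %in% c("gzip", "gz")) bytes <- memDecompress(bytes, type = "gzip")
  else if (enc != "raw") stop("NRRD encoding not supported: ", enc, call. = FALSE)
  vox <- decode_raw_voxels(bytes, type_map_nrrd(val("type")), prod(dims),
                           msb = identical(val("endian", "little"), "big"))
  spacing <- c(1, 1, 1); orient <- diag(3)
  sd <- val("space directions")
  if (!is.null(sd)) {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1L]]
    m <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1L]]), numeric(3))
    spacing <- sqrt(colSums(m^2))
    orient <- sweep(m, 2L, spacing, `/`)
  } else if (!is.null(val("spacings"))) {
    spacing <- as.numeric(strsplit(val("spacings"), "\\s+")[[1L]])
  }
  origin <- c(0, 0, 0)
  so <- val("space origin")
  if (!is.null(so)) origin <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1L]])
  volumetric_image(array(vox, dims), spacing = spacing, origin = origin,
                   orientation = orient)
}

type_map_met <- function(type) {
  switch(type,
         MET_UCHAR = c("integer", 1, 0), MET_CHAR = c("integer", 1, 1),
         MET_USHORT = c("integer", 2, 0), MET_SHORT = c("integer", 2, 1),
         MET_UINT = c("integer", 4, 0), MET_INT = c("integer", 4, 1),
         MET_FLOAT = c("double", 4, 1), MET_DOUBLE = c("double", 8, 1),
         stop("unsupported MetaImage element type: ", type, call. = FALSE))
}

type_map_nrrd <- function(type) {
  switch(type,
         uchar = , uint8 = , "unsigned char" = c("integer", 1, 0),
         char = , int8 = c("integer", 1, 1),
         ushort = , uint16 = , "unsigned short" = c("integer", 2, 0),
         short = , int16 = c("integer", 2, 1),
         uint = , uint32 = c("integer", 4, 0),
         int = , int32 = c("integer", 4, 1),
         float = c("double", 4, 1), double = c("double", 8, 1),
         stop("unsupported NRRD type: ", type, call. = FALSE))
}

decode_raw_voxels <- function(bytes, spec, n, msb = FALSE) {
  what <- spec[1L]; size <- as.integer(spec[2L]); signed <- spec[3L] == "1"
  if (length(bytes) < n * size)
    stop("voxel payload shorter than header dimensions imply", call. = FALSE)
  readBin(bytes, what = what, n = n, size = size, signed = signed || size > 2,
          endian = if (msb) "big" else "little")
}
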