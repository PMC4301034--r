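#' @importFrom RNifti readNifti writeNifti asNifti pixdim `pixdim<-` xform `qform<-`
NULL

.formatError <- function(msg)
  stop(errorCondition(msg, class = c("nonunionFE_format_error", "error")))
.metadataError <- function(msg)
  stop(errorCondition(msg, class = c("nonunionFE_metadata_error", "error")))

.stackFormat <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) return("mhd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  .formatError(sprintf("unsupported stack format: '%s' (use .mhd or .nii/.nii.gz)",
                       basename(path)))
}

## --- MetaImage (.mhd header + .raw payload), MET_DOUBLE little-endian ------

.writeMhd <- function(stack, path) {
  rawName <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(stack@values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            stack@spacing[1], stack@spacing[2], stack@spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            stack@origin[1], stack@origin[2], stack@origin[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", rawName))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  writeBin(as.vector(stack@values), con, size = 8, endian = "little")
}

.readMhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m)) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m)) m[3] else NA_character_, "")
  get1 <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) NA_character_ else trimws(vals[i])
  }
  if (!identical(get1("ElementType"), "MET_DOUBLE"))
    .formatError("only MET_DOUBLE MetaImage payloads are supported")
  dimStr <- get1("DimSize")
  if (is.na(dimStr)) .metadataError("MetaImage header lacks DimSize")
  d <- as.integer(strsplit(dimStr, "\\s+")[[1]])
  spStr <- get1("ElementSpacing")
  if (is.na(spStr))
    .metadataError("MetaImage header lacks ElementSpacing (voxel size unknown)")
  sp <- as.numeric(strsplit(spStr, "\\s+")[[1]])
  offStr <- get1("Offset")
  org <- if (is.na(offStr)) c(0, 0, 0) else as.numeric(strsplit(offStr, "\\s+")[[1]])
  rawName <- get1("ElementDataFile")
  if (is.na(rawName)) .metadataError("MetaImage header lacks ElementDataFile")
  con <- file(file.path(dirname(path), rawName), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  new("ImageStack", values = array(v, dim = d), spacing = sp, origin = org)
}

## --- NIfTI-1 through RNifti ------------------------------------------------

.writeNii <- function(stack, path) {
  img <- RNifti::asNifti(stack@values)
  RNifti::pixdim(img) <- stack@spacing
  aff <- diag(4)
  diag(aff)[1:3] <- stack@spacing
  aff[1:3, 4] <- stack@origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
}

.readNii <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    .metadataError(sprintf("'%s' lacks positive voxel spacing metadata",
                           basename(path)))
  org <- RNifti::xform(img)[1:3, 4]
  new("ImageStack", values = array(as.numeric(img), dim = dim(img)),
      spacing = as.numeric(sp[1:3]), origin = as.numeric(org))
}

#' Read and write image stacks
#'
#' Stacks are exchanged as MetaImage (\code{.mhd} header plus \code{.raw}
#' payload, MET_DOUBLE) or NIfTI-1 (\code{.nii}/\code{.nii.gz}, via RNifti).
#' A write followed by a read preserves values, spacing and origin exactly.
#'
#' @param path file path; the extension selects the format.
#' @param stack an \linkS4class{ImageStack}.
#' @return \code{readStack} returns an \linkS4class{ImageStack};
#'   \code{writeStack} returns \code{path} invisibly.
#' @export
readStack <- function(path) {
  if (!file.exists(path))
    .formatError(sprintf("no such file: '%s'", path))
  switch(.stackFormat(path), mhd = .readMhd(path), nifti = .readNii(path))
}

#' @rdname readStack
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  switch(.stackFormat(path), mhd = .writeMhd(stack, path),
         nifti = .writeNii(stack, path))
  invisible(path)
}

#' Write a label volume as NIfTI plus a JSON code table
#'
#' The integer label codes go into the NIfTI file; a JSON sidecar (same path
#' with \code{.json} appended) records the code table and the nonunion-cell
#' count.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param path a \code{.nii}/\code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path) {
  stk <- new("ImageStack", values = array(as.numeric(labels@labels),
                                          dim = dim(labels@labels)),
             spacing = labels@spacing, origin = labels@origin)
  .writeNii(stk, path)
  side <- list(codes = as.list(setNames(0:4, TISSUE_CLASSES)),
               nonunion_cells = sum(labels@nonunion),
               thresholds = labels@thresholds)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
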