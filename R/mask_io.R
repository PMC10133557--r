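# MetaImage (.mhd + .raw) and NRRD voxel-mask readers and writers.
# Scalar uint8 masks, isotropic spacing; enough for round-tripping segmented
# micro-CT style occupancy grids.  Voxel order is i fastest, then j, then k.

#' Write a voxel specimen as a MetaImage or NRRD mask
#'
#' Format chosen from the file extension: `.mhd` writes a MetaImage header
#' plus a sibling `.raw` file; `.nrrd` writes a single-file NRRD (raw
#' encoding).  Data are uint8 (1 = occupied).
#'
#' @param spec A [voxel_specimen()].
#' @param path Output path ending in `.mhd` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_voxel_mask <- function(spec, path) {
  stopifnot(inherits(spec, "voxel_specimen"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(spec$occupancy)
  bytes <- as.raw(as.integer(spec$occupancy))
  if (ext == "mhd") {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    hdr <- c(
      "ObjectType = Image",
      "NDims = 3",
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
      sprintf("ElementSpacing = %g %g %g",
              spec$spacing, spec$spacing, spec$spacing),
      sprintf("Offset = %g %g %g",
              spec$origin[1], spec$origin[2], spec$origin[3]),
      "ElementType = MET_UCHAR",
      sprintf("ElementDataFile = %s", raw_name))
    writeLines(hdr, path)
    writeBin(bytes, file.path(dirname(path), raw_name))
  } else if (ext == "nrrd") {
    hdr <- c(
      "NRRD0004",
      "# cdmbone voxel mask (units: mm)",
      "type: uint8",
      "dimension: 3",
      sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
      sprintf("spacings: %g %g %g", spec$spacing, spec$spacing, spec$spacing),
      sprintf("axis mins: %g %g %g",
              spec$origin[1], spec$origin[2], spec$origin[3]),
      "encoding: raw",
      "endian: little",
      "")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(bytes, con)
  } else {
    stop("unsupported mask format '", ext, "' (use .mhd or .nrrd)",
         call. = FALSE)
  }
  invisible(path)
}

parse_kv <- function(lines, sep) {
  kv <- regmatches(lines, regexpr(sep, lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""))
  stats::setNames(vals, keys)
}

num3 <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' Read a voxel mask into a specimen
#'
#' Accepts MetaImage (`.mhd` + `.raw`) or NRRD (raw encoding) scalar masks
#' with isotropic spacing.  Nonzero voxels become occupied; only the largest
#' 26-connected component is retained (a warning reports discarded voxels),
#' preventing isolated voxels from producing singular stiffness matrices.
#'
#' @param path Path to the `.mhd` or `.nrrd` file.
#' @return A [voxel_specimen()].
#' @export
read_voxel_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") {
    hdr <- parse_kv(readLines(path, warn = FALSE), " = ")
    d <- as.integer(num3(hdr[["DimSize"]]))
    sp <- num3(hdr[["ElementSpacing"]])
    origin <- if ("Offset" %in% names(hdr)) num3(hdr[["Offset"]]) else c(0, 0, 0)
    if (!identical(toupper(hdr[["ElementType"]]), "MET_UCHAR")) {
      stop("only MET_UCHAR MetaImage masks are supported", call. = FALSE)
    }
    raw_path <- file.path(dirname(path), hdr[["ElementDataFile"]])
    bytes <- readBin(raw_path, "raw", n = prod(d))
  } else if (ext == "nrrd") {
    all_bytes <- readBin(path, "raw", n = file.size(path))
    # header ends at the first blank line (\n\n)
    nl <- which(all_bytes == as.raw(10L))
    brk <- nl[which(diff(nl) == 1L)[1]]
    if (is.na(brk)) stop("malformed NRRD: no blank line after header",
                         call. = FALSE)
    hdr_lines <- strsplit(rawToChar(all_bytes[seq_len(brk - 1L)]), "\n",
                          fixed = TRUE)[[1]]
    hdr_lines <- hdr_lines[!startsWith(hdr_lines, "#")]
    hdr <- parse_kv(hdr_lines[grepl(":", hdr_lines)], ": ")
    if (!identical(hdr[["type"]], "uint8")) {
      stop("only uint8 NRRD masks are supported", call. = FALSE)
    }
    if (!identical(hdr[["encoding"]], "raw")) {
      stop("only raw-encoded NRRD masks are supported", call. = FALSE)
    }
    d <- as.integer(num3(hdr[["sizes"]]))
    sp <- num3(hdr[["spacings"]])
    origin <- if ("axis mins" %in% names(hdr)) {
      num3(hdr[["axis mins"]])
    } else c(0, 0, 0)
    bytes <- all_bytes[(brk + 2L):length(all_bytes)]
  } else {
    stop("unsupported mask format '", ext, "' (use .mhd or .nrrd)",
         call. = FALSE)
  }
  if (length(bytes) != prod(d)) {
    stop("mask data truncated: expected ", prod(d), " voxels, got ",
         length(bytes), call. = FALSE)
  }
  if (max(abs(sp - sp[1])) > 1e-9 * sp[1]) {
    stop("anisotropic voxel spacing (", paste(sp, collapse = " x "),
         "): hex-voxel meshing assumes cubic voxels", call. = FALSE)
  }
  occ <- array(as.integer(bytes) != 0L, d)
  if (!any(occ)) stop("mask is empty: no nonzero voxels", call. = FALSE)
  occ <- keep_largest_component(occ, basename(path))
  voxel_specimen(occ, sp[1], origin)
}
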