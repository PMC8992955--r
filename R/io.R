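## Slice I/O.  PNG pairs (<case>_<slice>_img.png / _mask.png, 16-bit images,
## 8-bit masks) via the png package; NIfTI-1 volumes + label maps via the
## minimal reader/writer in nifti.R.  Images are normalized to [0, 1] at load
## so phantoms and real CT share one intensity contract.

#' Write phantom slices to disk
#'
#' @param slices List of `phantom_slice` records (or a `phantom_dataset`).
#' @param path Output directory (PNG) or file stem (NIfTI; writes
#'   `<stem>_img.nii.gz` and `<stem>_mask.nii.gz` per case).
#' @param format `"png"` or `"nifti"`.
#' @return Invisibly, the written file paths.
#' @export
write_slices <- function(slices, path, format = c("png", "nifti")) {
  format <- match.arg(format)
  if (inherits(slices, "phantom_dataset")) slices <- slices$slices
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (s in slices) {
      stem <- file.path(path, sprintf("%03d_%03d", s$case_id, s$slice_id))
      write_png16(s$image, paste0(stem, "_img.png"))
      png::writePNG(s$mask, paste0(stem, "_mask.png"))
      files <- c(files, paste0(stem, c("_img.png", "_mask.png")))
    }
    return(invisible(files))
  }
  ## NIfTI: one volume + one label file per case
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  cases <- split(slices, vapply(slices, function(s) s$case_id, 1L))
  files <- character(0)
  for (cid in names(cases)) {
    sl <- cases[[cid]][order(vapply(cases[[cid]],
                                    function(s) s$slice_id, 1L))]
    img <- simplify2array(lapply(sl, function(s) s$image))
    msk <- simplify2array(lapply(sl, function(s) s$mask))
    fi <- sprintf("%s_case%s_img.nii.gz", path, cid)
    fm <- sprintf("%s_case%s_mask.nii.gz", path, cid)
    write_nifti(img, fi, datatype = "float32")
    write_nifti(msk, fm, datatype = "uint8")
    files <- c(files, fi, fm)
  }
  invisible(files)
}

#' Read phantom slices from disk
#'
#' PNG masks with values in `{0, 255}` (or any 0/1-scaled coding) are
#' normalized to `{0, 1}`; NIfTI volumes of L slices yield L records with
#' consecutive `slice_id`. Images are min-max normalized to `[0, 1]` (NIfTI
#' window/level configurable).
#'
#' @param path Directory (PNG) or file stem used by [write_slices()].
#' @param format `"png"` or `"nifti"`.
#' @param window Optional `c(low, high)` intensity window for NIfTI images.
#' @return List of `phantom_slice` records.
#' @export
read_slices <- function(path, format = c("png", "nifti"), window = NULL) {
  format <- match.arg(format)
  if (format == "png") {
    imgs <- sort(list.files(path, pattern = "_img\\.png$", full.names = TRUE))
    out <- vector("list", length(imgs))
    for (i in seq_along(imgs)) {
      mf <- sub("_img\\.png$", "_mask.png", imgs[i])
      if (!file.exists(mf)) stop("missing mask for ", imgs[i])
      img <- png::readPNG(imgs[i])
      msk <- png::readPNG(mf)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
      if (!identical(dim(img), dim(msk)))
        stop("shape mismatch between image and mask: ", imgs[i])
      ids <- as.integer(strsplit(sub("_img\\.png$", "", basename(imgs[i])),
                                 "_")[[1]])
      out[[i]] <- structure(list(image = img, mask = (msk > 0.5) * 1,
                                 case_id = ids[1], slice_id = ids[2]),
                            class = "phantom_slice")
    }
    return(out)
  }
  vols <- sort(list.files(dirname(path),
                          pattern = paste0("^", basename(path),
                                           "_case.*_img\\.nii(\\.gz)?$"),
                          full.names = TRUE))
  if (length(vols) == 0L) stop("no NIfTI volumes found for stem ", path)
  out <- list()
  for (v in vols) {
    mf <- sub("_img\\.nii", "_mask.nii", v)
    if (!file.exists(mf)) stop("missing label volume for ", v)
    cid <- as.integer(sub(".*_case([0-9]+)_img.*", "\\1", basename(v)))
    img <- read_nifti(v)
    msk <- read_nifti(mf)
    if (!identical(dim(img$data), dim(msk$data)))
      stop("shape mismatch between volume and label: ", v)
    a <- img$data
    if (!is.null(window)) {
      a <- (a - window[1]) / (window[2] - window[1])
    } else if (diff(range(a)) > 0) {
      a <- (a - min(a)) / diff(range(a))
    }
    a <- pmin(pmax(a, 0), 1)
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    md <- msk$data
    if (length(dim(md)) == 2L) dim(md) <- c(dim(md), 1L)
    for (sl in seq_len(dim(a)[3])) {
      out[[length(out) + 1L]] <-
        structure(list(image = a[, , sl], mask = (md[, , sl] > 0.5) * 1,
                       case_id = cid, slice_id = sl,
                       spacing = img$pixdim[1:2]),
                  class = "phantom_slice")
    }
  }
  out
}

#' Write a dataset manifest
#'
#' @param dataset A `phantom_dataset`.
#' @param file Output CSV path.
#' @param paths Optional per-slice file paths to record.
#' @return The manifest data frame, invisibly.
#' @export
write_manifest <- function(dataset, file, paths = NA_character_) {
  df <- data.frame(
    case_id = vapply(dataset$slices, function(s) s$case_id, 1L),
    slice_id = vapply(dataset$slices, function(s) s$slice_id, 1L))
  df$fold <- unname(dataset$folds[as.character(df$case_id)])
  df$path <- paths
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

## --- minimal 16-bit grayscale PNG writer ------------------------------------
## The png package reads 16-bit PNGs but only writes 8-bit from doubles, which
## would break the "round-trip to 16-bit quantization" contract for images.

u32be <- function(x) {
  x <- as.double(x)
  as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  hex <- formatC(digest::digest(body, algo = "crc32", serialize = FALSE),
                 width = 8, flag = "0")
  crc <- as.raw(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
  c(u32be(length(data)), body, crc)
}

write_png16 <- function(image, file) {
  stopifnot(all(image >= 0), all(image <= 1))
  H <- nrow(image); W <- ncol(image)
  v <- round(t(image) * 65535)           # PNG scanlines are row-major
  hi <- as.raw(v %/% 256); lo <- as.raw(v %% 256)
  sc <- raw(H * (1L + 2L * W))
  pix <- raw(2L * W * H)
  pix[seq(1, by = 2, length.out = W * H)] <- hi
  pix[seq(2, by = 2, length.out = W * H)] <- lo
  dim(pix) <- c(2L * W, H)
  sc <- rbind(as.raw(0L), pix)           # filter byte 0 per scanline
  zlib <- memCompress(as.raw(sc), type = "gzip")
  # R's "gzip" memCompress emits an RFC 1950 zlib stream (0x78 0x9c ...),
  # which is exactly what a PNG IDAT chunk wants
  stopifnot(as.integer(zlib[1]) == 0x78)
  ihdr <- c(u32be(W), u32be(H), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, file)
  invisible(file)
}
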