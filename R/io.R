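# Dataset input/output: PNG/TIFF image+mask pairs in a DRIVE-style layout
#   root/{images,masks}/<stem>.<ext>  (+ optional root/{train,test}.txt)
# and reversible reflect-padding for pooling-compatible sizes.

imageExt <- function(path) tolower(sub(".*\\.", "", path))

readImageFile <- function(path) {
  arr <- switch(imageExt(path),
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    configError("unsupported image format '%s' (%s)", imageExt(path), path))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
    arr <- arr[, , 1:3]  # drop alpha
  arr
}

#' Load a DRIVE-style image/mask dataset
#'
#' Reads matching \code{images/} and \code{masks/} pairs (PNG or TIFF; the
#' stem before the extension identifies the pair). Images are returned with
#' values in [0, 1]; masks are binarized with the standard 8-bit threshold
#' (pixel > 127 is foreground). When \code{split} is given, the stem list in
#' \code{root/<split>.txt} is honored verbatim (order included).
#'
#' @param root Dataset directory.
#' @param split \code{NULL} (all pairs, sorted), \code{"train"} or
#'   \code{"test"}.
#' @return List of sample pairs \code{list(image, mask, id)}.
#' @export
loadDataset <- function(root, split = NULL) {
  imgDir <- file.path(root, "images")
  mskDir <- file.path(root, "masks")
  if (!dir.exists(imgDir) || !dir.exists(mskDir))
    configError("'%s' must contain images/ and masks/ subdirectories", root)
  imgs <- list.files(imgDir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  msks <- list.files(mskDir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  stemOf <- function(x) sub("\\.[^.]*$", "", x)
  istems <- stemOf(imgs)
  mstems <- stemOf(msks)
  orphans <- c(setdiff(istems, mstems), setdiff(mstems, istems))
  if (length(orphans))
    configError("unpaired image/mask stems: %s",
                paste(sort(unique(orphans)), collapse = ", "))
  stems <- sort(istems)
  if (!is.null(split)) {
    listFile <- file.path(root, paste0(split, ".txt"))
    if (!file.exists(listFile))
      configError("split list '%s' not found", listFile)
    stems <- readLines(listFile)
    stems <- stems[nzchar(stems)]
    missing <- setdiff(stems, istems)
    if (length(missing))
      configError("split list names missing stems: %s",
                  paste(missing, collapse = ", "))
  }
  names(imgs) <- istems
  names(msks) <- mstems
  lapply(stems, function(stem) {
    img <- readImageFile(file.path(imgDir, imgs[[stem]]))
    msk <- readImageFile(file.path(mskDir, msks[[stem]]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    d1 <- dim(img)[1:2]
    if (!all(d1 == dim(msk)))
      configError("image/mask size mismatch for '%s'", stem)
    list(image = img, mask = 1 * (msk > 127 / 255), id = stem)
  })
}

#' Write sample pairs as a DRIVE-style dataset
#'
#' Images as 8-bit grayscale/RGB PNG, masks as single-channel \{0, 255\}
#' PNG, plus optional \code{train.txt}/\code{test.txt} stem lists.
#'
#' @param pairs List of sample pairs.
#' @param root Output directory (created).
#' @param split Optional named list \code{list(train = stems, test = stems)}
#'   or a single integer: the first \code{split} stems go to train, the rest
#'   to test.
#' @param force Overwrite an existing non-empty directory.
#' @return \code{root}, invisibly.
#' @export
writeDataset <- function(pairs, root, split = NULL, force = FALSE) {
  if (dir.exists(root) && length(list.files(root)) > 0L && !force)
    configError("output directory '%s' is not empty (use force = TRUE)", root)
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  stems <- vapply(pairs, function(p) p$id, character(1))
  for (p in pairs) {
    png::writePNG(p$image, file.path(root, "images", paste0(p$id, ".png")))
    png::writePNG(p$mask, file.path(root, "masks", paste0(p$id, ".png")))
  }
  if (!is.null(split)) {
    if (is.numeric(split)) {
      ntr <- asCount(split, "split", 0L)
      split <- list(train = stems[seq_len(min(ntr, length(stems)))],
                    test = stems[setdiff(seq_along(stems),
                                         seq_len(min(ntr, length(stems))))])
    }
    for (nm in names(split))
      writeLines(split[[nm]], file.path(root, paste0(nm, ".txt")))
  }
  invisible(root)
}

reflectIndices <- function(L, Tlen) {
  if (Tlen == L) return(seq_len(L))
  padN <- Tlen - L
  if (padN > L - 1L)
    argumentError("cannot reflect-pad a side of length %d by %d", L, padN)
  c(seq_len(L), L - seq_len(padN))
}

#' Reflect-pad an image to a pooling-compatible size
#'
#' Pads the bottom/right edges by mirror reflection so that each side is
#' divisible by \code{2^(levels - 1)} (the resolution halvings of a
#' \code{levels}-deep contracting path). The returned record allows the
#' exact inverse crop: \code{unpadImage(padToDivisible(x, k)$image, rec)}
#' is \code{x}.
#'
#' @param image 2-D or 3-D array.
#' @param levels Pooling depth (>= 1); divisor is \code{2^(levels - 1)}.
#' @return \code{list(image, record)}.
#' @examples
#' p <- padToDivisible(matrix(1:12, 3, 4), levels = 3)
#' dim(p$image)  # 4 x 4
#' @export
padToDivisible <- function(image, levels) {
  levels <- asCount(levels, "levels")
  div <- 2L^(levels - 1L)
  d <- dim(image)
  if (is.null(d)) argumentError("image must be a matrix or array")
  hw <- d[1:2]
  target <- as.integer(ceiling(hw / div) * div)
  ih <- reflectIndices(hw[1], target[1])
  iw <- reflectIndices(hw[2], target[2])
  out <- if (length(d) == 2L) image[ih, iw, drop = FALSE]
         else image[ih, iw, , drop = FALSE]
  list(image = out, record = list(original = hw, padded = target))
}

#' @rdname padToDivisible
#' @param record Padding record returned by \code{padToDivisible}.
#' @export
unpadImage <- function(image, record) {
  hw <- record$original
  if (length(dim(image)) == 2L) image[seq_len(hw[1]), seq_len(hw[2]), drop = FALSE]
  else image[seq_len(hw[1]), seq_len(hw[2]), , drop = FALSE]
}
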