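# Seeded synthetic phantoms emulating the two evaluation regimes:
#   cell mode   - small low-resolution images of textured soft-edged
#                 elliptical blobs (multi-photon-microscopy-like cells)
#   vessel mode - thin bright curvilinear tracks (widths 1-4 px) on a
#                 textured background (retinal-vessel-like)
# Images are quantized to the 8-bit grid so a PNG write/read round-trip is
# pixel-identical; masks are strictly binary.

# low-frequency texture: white noise smoothed with a Gaussian kernel,
# rescaled to [-1, 1]
smoothNoise <- function(h, w, sigma = 3) {
  half <- ceiling(2 * sigma)
  ax <- seq(-half, half)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  x <- array(stats::rnorm(h * w), c(h, w, 1L, 1L))
  kw <- array(k, c(length(ax), length(ax), 1L, 1L))
  y <- .conv_fw(x, kw, 0, 1L)[, , 1L, 1L]
  m <- max(abs(y))
  if (m > 0) y / m else y
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

cellPhantom <- function(size, blobCountRange, noiseSd) {
  h <- size[1]; w <- size[2]
  gx <- matrix(rep(seq_len(h), w), h, w)
  gy <- matrix(rep(seq_len(w), each = h), h, w)
  bg <- 0.15 + 0.08 * smoothNoise(h, w, sigma = max(2, min(h, w) / 16))
  nb <- sample(seq(blobCountRange[1], blobCountRange[2]), 1L)
  mask <- matrix(0, h, w)
  fg <- matrix(0, h, w)
  rmin <- min(h, w) / 12
  rmax <- min(h, w) / 6
  for (i in seq_len(nb)) {
    # first blob centered well inside so every mask is non-empty
    margin <- if (i == 1L) 0.25 else 0.05
    cx <- stats::runif(1, margin * h, (1 - margin) * h)
    cy <- stats::runif(1, margin * w, (1 - margin) * w)
    a <- stats::runif(1, rmin, rmax)
    b <- stats::runif(1, rmin, rmax)
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 0.55, 0.9)
    dx <- gx - cx; dy <- gy - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    d2 <- u^2 + v^2
    mask[d2 <= 1] <- 1
    soft <- amp * exp(-pmax(d2 - 1, 0) * 6)  # soft edge beyond the support
    fg <- pmax(fg, soft)
  }
  tex <- 1 + 0.15 * smoothNoise(h, w, sigma = max(1.5, min(h, w) / 24))
  img <- pmax(bg, fg * tex) + stats::rnorm(h * w, sd = noiseSd)
  list(image = quantize8(img), mask = mask)
}

stampDisc <- function(mask, cx, cy, radius) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius)
  xs <- max(1L, floor(cx - r)):min(h, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(w, ceiling(cy + r))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) mask[x, y] <- 1
  mask
}

vesselPhantom <- function(size, curveCountRange, noiseSd) {
  h <- size[1]; w <- size[2]
  bg <- 0.2 + 0.1 * smoothNoise(h, w, sigma = max(2, min(h, w) / 12))
  nc <- sample(seq(curveCountRange[1], curveCountRange[2]), 1L)
  mask <- matrix(0, h, w)
  for (i in seq_len(nc)) {
    width <- sample(1:4, 1L)
    radius <- max(0.5, width / 2)
    x <- stats::runif(1, 2, h - 1)
    y <- stats::runif(1, 2, w - 1)
    heading <- stats::runif(1, 0, 2 * pi)
    nsteps <- round(1.2 * max(h, w))
    for (s in seq_len(nsteps)) {
      heading <- heading + stats::rnorm(1, sd = 0.18)
      x <- x + cos(heading)
      y <- y + sin(heading)
      if (x < 1 || x > h || y < 1 || y > w) {
        x <- min(max(x, 1), h)
        y <- min(max(y, 1), w)
        heading <- heading + pi / 2 + stats::runif(1, 0, pi)  # bounce inward
      }
      mask <- stampDisc(mask, x, y, radius)
    }
  }
  # soften vessel edges with a 3x3 mean before compositing; support stays exact
  mk <- array(mask, c(h, w, 1L, 1L))
  soft <- .conv_fw(mk, array(1 / 9, c(3L, 3L, 1L, 1L)), 0, 1L)[, , 1L, 1L]
  img <- bg + 0.55 * pmin(soft * 1.5, 1) + stats::rnorm(h * w, sd = noiseSd)
  list(image = quantize8(img), mask = mask)
}

#' Generate a seeded set of synthetic segmentation phantoms
#'
#' Two modes emulating the package's two evaluation regimes: \code{"cell"}
#' produces textured soft-edged elliptical blobs with binary foreground
#' masks (microscopy-cell-like; default 128x128, the scale of small
#' multi-photon microscopy sets), and \code{"vessel"} produces thin bright
#' random-walk tracks dilated to widths 1-4 px on a textured background
#' (retinal-vessel-like geometry at a configurable, typically scaled-down,
#' resolution). Generation is a pure function of the configuration: the same
#' seed gives bitwise-identical output. Images are pre-quantized to the
#' 8-bit grid, so writing and re-reading them as PNG is lossless.
#'
#' @param mode \code{"cell"} or \code{"vessel"}.
#' @param count Number of image/mask pairs.
#' @param size Image size (scalar or pair), sides >= 16.
#' @param seed Integer seed.
#' @param blobCountRange Integer range of blobs per cell image.
#' @param curveCountRange Integer range of tracks per vessel image.
#' @param noiseSd Additive Gaussian noise standard deviation.
#' @param prevalenceBand Acceptable (low, high) band for the set-level mean
#'   foreground fraction; generation fails loudly if the configuration
#'   produces masks outside it.
#' @return List of sample pairs \code{list(image, mask, id)}, with the
#'   configuration attached as attribute \code{"config"}.
#' @examples
#' ph <- generatePhantoms("cell", count = 2, size = 32, seed = 7)
#' range(ph[[1]]$image)
#' @export
generatePhantoms <- function(mode = c("cell", "vessel"), count, size = 128L,
                             seed = 1L,
                             blobCountRange = c(3L, 7L),
                             curveCountRange = c(3L, 6L),
                             noiseSd = 0.05,
                             prevalenceBand = if (match.arg(mode) == "cell")
                               c(0.05, 0.40) else c(0.02, 0.30)) {
  mode <- match.arg(mode)
  count <- asCount(count, "count")
  size <- asSizePair(size)
  if (any(size < 16L)) argumentError("phantom size sides must be >= 16")
  if (noiseSd < 0) argumentError("noiseSd must be non-negative")
  seed <- asCount(seed, "seed", 0L)
  pairs <- withSeed(seed, {
    lapply(seq_len(count), function(i) {
      p <- if (mode == "cell") cellPhantom(size, blobCountRange, noiseSd)
           else vesselPhantom(size, curveCountRange, noiseSd)
      p$id <- sprintf("%s_%03d", mode, i)
      p
    })
  })
  prev <- mean(vapply(pairs, function(p) mean(p$mask), numeric(1)))
  if (prev < prevalenceBand[1] || prev > prevalenceBand[2])
    configError(
      "set-level foreground prevalence %.3f outside the configured band [%.2f, %.2f]",
      prev, prevalenceBand[1], prevalenceBand[2])
  if (any(vapply(pairs, function(p) sum(p$mask) == 0, logical(1))))
    configError("generated an empty mask; adjust the phantom configuration")
  attr(pairs, "config") <- list(mode = mode, count = count, size = size,
                                seed = seed, blobCountRange = blobCountRange,
                                curveCountRange = curveCountRange,
                                noiseSd = noiseSd)
  pairs
}
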