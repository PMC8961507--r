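# R-level primitives of the CPU engine. Tensors are (H, W, C, N) arrays.
# Convolution / pooling / upsampling kernels live in src/convops.cpp.

#' @useDynLib eunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# reshape (H,W,C,N) -> (H*W*N, C) matrix; channelwise stats become colSums
channelMatrix <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

channelArray <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1L, 2L, 4L, 3L))
}

bnForward <- function(x, gamma, beta, rmean, rvar, training) {
  d <- dim(x)
  m <- channelMatrix(x)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m * m) - mu^2
    va[va < 0] <- 0
  } else {
    mu <- rmean
    va <- rvar
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(invstd, each = nrow(m))
  y <- xhat * rep(gamma, each = nrow(m)) + rep(beta, each = nrow(m))
  list(y = channelArray(y, d),
       cache = if (training) list(xhat = xhat, invstd = invstd, dims = d)
               else NULL,
       mu = mu, va = va)
}

bnBackward <- function(g, gamma, cache) {
  d <- cache$dims
  gm <- channelMatrix(g)
  n <- nrow(gm)
  gxhat <- gm * rep(gamma, each = n)
  sum_gx <- colSums(gxhat)
  sum_gx_xhat <- colSums(gxhat * cache$xhat)
  gx <- (gxhat - rep(sum_gx / n, each = n) -
         cache$xhat * rep(sum_gx_xhat / n, each = n)) *
        rep(cache$invstd, each = n)
  list(gx = channelArray(gx, d),
       ggamma = colSums(gm * cache$xhat),
       gbeta = colSums(gm))
}
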