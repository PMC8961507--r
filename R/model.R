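# Realization of a LayerGraph as a trainable model: execution-plan
# compilation, seeded parameter initialization, forward/backward passes,
# Dice loss, Adam/SGD updates.

# ---- execution plan -------------------------------------------------------

# Flatten the graph into an ordered list of primitive steps. Each step is a
# list(kind, x, y, ...) where x/y are tensor ids; concat steps carry xs (all
# inputs). Shapes are tracked so convolution/batch-norm parameters can be
# sized, and each step remembers the branch index of its node for
# branch-offset seeding.
compilePlan <- function(graph) {
  steps <- list()
  outId <- list(); preId <- list()
  tshape <- list(INPUT = c(graph@inputSize, graph@inputChannels))
  for (id in names(graph@nodes)) {
    nd <- graph@nodes[[id]]
    src <- forwardSource(graph, id)
    x <- if (is.na(src)) "INPUT" else outId[[src]]
    t <- 0L
    for (op in nd$ops) {
      t <- t + 1L
      y <- paste0(id, ":", t)
      shp <- tshape[[x]]
      step <- list(kind = op$kind, x = x, y = y, node = id,
                   branch = if (is.na(nd$branch_index)) 0L else nd$branch_index)
      tshape[[y]] <- switch(op$kind,
        conv = {
          step$kernel <- op$kernel
          step$cin <- shp[3]
          step$cout <- op$channels_out
          step$dilation <- op$dilation
          c(shp[1:2], op$channels_out)
        },
        pool = c(shp[1:2] %/% op$factor, shp[3]),
        upsample = c(shp[1:2] * op$factor, shp[3]),
        concat = {
          srcs <- concatSources(graph, id, op$source)
          xs <- vapply(srcs, function(s)
            if (op$source == "merge") outId[[s]] else preId[[s]], character(1))
          step$xs <- c(x, unname(xs))
          ctot <- shp[3] + sum(vapply(xs, function(tid) tshape[[tid]][3],
                                      numeric(1)))
          c(shp[1:2], ctot)
        },
        batchnorm = { step$channels <- shp[3]; shp },
        dropout = { step$rate <- op$rate; shp },
        activation = { step$fun <- op$fun; shp },
        shp)
      steps[[length(steps) + 1L]] <- step
      if (op$kind != "pool") preId[[id]] <- y
      x <- y
    }
    if (t == 0L) {  # split nodes: pure passthrough
      outId[[id]] <- x
      preId[[id]] <- x
      next
    }
    outId[[id]] <- x
    if (is.null(preId[[id]])) preId[[id]] <- x
  }
  list(steps = steps, output = outId[["Output"]], shapes = tshape)
}

#' Soft Dice loss
#'
#' \code{1 - (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)}
#' summed over all pixels (and images) of the batch; the smoothing constant
#' \code{s} keeps the ratio defined on empty masks and the loss lies in
#' [0, 1). Differentiable in \code{pred}.
#'
#' @param pred Numeric array of predicted probabilities in [0, 1].
#' @param target Binary array (same shape) of ground-truth labels.
#' @param smoothing Positive smoothing constant (default 1).
#' @return Numeric scalar.
#' @examples
#' diceLoss(c(1, 0, 1), c(1, 0, 1), smoothing = 1e-12)
#' @export
diceLoss <- function(pred, target, smoothing = 1) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    argumentError("pred and target must have identical shapes")
  if (any(pred < 0 | pred > 1)) argumentError("pred values must lie in [0, 1]")
  if (!all(target %in% c(0, 1))) argumentError("target must be binary")
  if (smoothing < 0) argumentError("smoothing must be non-negative")
  num <- 2 * sum(pred * target) + smoothing
  den <- sum(pred) + sum(target) + smoothing
  1 - num / den
}

diceGrad <- function(pred, target, smoothing = 1) {
  num <- 2 * sum(pred * target) + smoothing
  den <- sum(pred) + sum(target) + smoothing
  g <- -(2 * target * den - num) / den^2
  dim(g) <- dim(pred)
  g
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Realize a layer graph as a trainable model
#'
#' Allocates and seeds all parameters (He-initialized convolution kernels,
#' unit/zero batch-norm scale/offset) and compiles the execution plan.
#' Convolutions of different parallel branches draw from distinct
#' branch-offset seed streams, so branches of the same architecture start
#' from different weights under one master seed, while the same (graph,
#' seed) pair always reproduces identical parameters.
#'
#' @param graph A \linkS4class{LayerGraph}.
#' @param seed Integer master seed.
#' @return An \linkS4class{EUNetModel}.
#' @export
realizeModel <- function(graph, seed = 1L) {
  if (!is(graph, "LayerGraph")) argumentError("graph must be a LayerGraph")
  seed <- asCount(seed, "seed", min = 0L)
  plan <- compilePlan(graph)
  params <- new.env(parent = emptyenv())
  count <- 0
  for (i in seq_along(plan$steps)) {
    st <- plan$steps[[i]]
    if (st$kind == "conv") {
      fanIn <- st$kernel[1] * st$kernel[2] * st$cin
      sd <- sqrt(2 / fanIn)
      w <- withSeed(((seed + 1L) * 10007L + st$branch * 997L + i) %% 2147483647L,
                    stats::rnorm(fanIn * st$cout, sd = sd))
      dim(w) <- c(st$kernel, st$cin, st$cout)
      params[[st$y]] <- list(W = w, b = numeric(st$cout))
      count <- count + length(w) + st$cout
    } else if (st$kind == "batchnorm") {
      params[[st$y]] <- list(gamma = rep(1, st$channels),
                             beta = numeric(st$channels),
                             rmean = numeric(st$channels),
                             rvar = rep(1, st$channels))
      count <- count + 2 * st$channels
    }
  }
  new("EUNetModel", graph = graph, plan = plan, params = params,
      seed = seed, fingerprint = strHash(as.character(graphToJSON(graph))),
      parameterCount = count)
}

#' @describeIn realizeModel Analytic count of trainable scalars (convolution
#'   weights and biases plus batch-norm scales and offsets).
#' @param model An \linkS4class{EUNetModel}.
#' @export
parameterCount <- function(model) model@parameterCount

# ---- forward / backward ---------------------------------------------------

forwardPass <- function(model, x, training = FALSE, keepCache = training) {
  tensors <- new.env(parent = emptyenv())
  caches <- vector("list", length(model@plan$steps))
  tensors[["INPUT"]] <- x
  params <- model@params
  for (i in seq_along(model@plan$steps)) {
    st <- model@plan$steps[[i]]
    xin <- tensors[[st$x]]
    y <- switch(st$kind,
      conv = .conv_fw(xin, params[[st$y]]$W, params[[st$y]]$b, st$dilation),
      pool = {
        r <- .maxpool_fw(xin)
        if (keepCache) caches[[i]] <- list(idx = r$idx, xdim = dim(xin))
        r$y
      },
      upsample = .upsample_fw(xin),
      concat = {
        parts <- lapply(st$xs, function(t) tensors[[t]])
        sizes <- vapply(parts, function(p) dim(p)[3], numeric(1))
        if (keepCache) caches[[i]] <- list(sizes = sizes)
        d <- dim(parts[[1]])
        out <- array(0, c(d[1], d[2], sum(sizes), d[4]))
        off <- 0L
        for (p in parts) {
          out[, , off + seq_len(dim(p)[3]), ] <- p
          off <- off + dim(p)[3]
        }
        out
      },
      batchnorm = {
        pp <- params[[st$y]]
        r <- bnForward(xin, pp$gamma, pp$beta, pp$rmean, pp$rvar, training)
        if (training) {
          pp$rmean <- BN_MOMENTUM * pp$rmean + (1 - BN_MOMENTUM) * r$mu
          pp$rvar <- BN_MOMENTUM * pp$rvar + (1 - BN_MOMENTUM) * r$va
          params[[st$y]] <- pp
          if (keepCache) caches[[i]] <- r$cache
        }
        r$y
      },
      dropout = {
        if (training && st$rate > 0) {
          mask <- array((stats::runif(length(xin)) >= st$rate) / (1 - st$rate),
                        dim(xin))
          if (keepCache) caches[[i]] <- list(mask = mask)
          xin * mask
        } else xin
      },
      activation = {
        if (st$fun == "relu") {
          out <- xin
          out[out < 0] <- 0
          out
        } else {
          1 / (1 + exp(-xin))
        }
      },
      argumentError("unsupported op kind '%s' in execution plan", st$kind))
    tensors[[st$y]] <- y
  }
  list(out = tensors[[model@plan$output]], tensors = tensors, caches = caches)
}

backwardPass <- function(model, fw, gout) {
  grads <- new.env(parent = emptyenv())   # tensor-id -> gradient
  pgrads <- new.env(parent = emptyenv())  # param-id  -> gradient list
  grads[[model@plan$output]] <- gout
  params <- model@params
  addGrad <- function(id, g) {
    cur <- grads[[id]]
    grads[[id]] <- if (is.null(cur)) g else cur + g
  }
  for (i in rev(seq_along(model@plan$steps))) {
    st <- model@plan$steps[[i]]
    g <- grads[[st$y]]
    if (is.null(g)) next
    switch(st$kind,
      conv = {
        r <- .conv_bw(fw$tensors[[st$x]], params[[st$y]]$W, g, st$dilation)
        pgrads[[st$y]] <- list(W = r$gw, b = r$gb)
        addGrad(st$x, r$gx)
      },
      pool = {
        cc <- fw$caches[[i]]
        addGrad(st$x, .maxpool_bw(cc$idx, g, cc$xdim))
      },
      upsample = addGrad(st$x, .upsample_bw(g)),
      concat = {
        sizes <- fw$caches[[i]]$sizes
        off <- 0L
        for (jj in seq_along(st$xs)) {
          addGrad(st$xs[[jj]], g[, , off + seq_len(sizes[jj]), , drop = FALSE])
          off <- off + sizes[jj]
        }
      },
      batchnorm = {
        r <- bnBackward(g, params[[st$y]]$gamma, fw$caches[[i]])
        pgrads[[st$y]] <- list(gamma = r$ggamma, beta = r$gbeta)
        addGrad(st$x, r$gx)
      },
      dropout = {
        cc <- fw$caches[[i]]
        addGrad(st$x, if (is.null(cc)) g else g * cc$mask)
      },
      activation = {
        y <- fw$tensors[[st$y]]
        addGrad(st$x, if (st$fun == "relu") g * (y > 0) else g * y * (1 - y))
      })
  }
  pgrads
}

# ---- optimizers -----------------------------------------------------------

makeOptimizer <- function(config) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  lr <- config@learningRate
  if (config@optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(params, pgrads) {
      state$t <- state$t + 1L
      c1 <- 1 - b1^state$t
      c2 <- 1 - b2^state$t
      for (id in ls(pgrads)) {
        pg <- pgrads[[id]]
        pp <- params[[id]]
        ms <- state[[id]]
        if (is.null(ms))
          ms <- lapply(pg, function(g) list(m = g * 0, v = g * 0))
        for (nm in names(pg)) {
          g <- pg[[nm]]
          ms[[nm]]$m <- b1 * ms[[nm]]$m + (1 - b1) * g
          ms[[nm]]$v <- b2 * ms[[nm]]$v + (1 - b2) * g * g
          pp[[nm]] <- pp[[nm]] -
            lr * (ms[[nm]]$m / c1) / (sqrt(ms[[nm]]$v / c2) + eps)
        }
        state[[id]] <- ms
        params[[id]] <- pp
      }
    }
  } else {
    function(params, pgrads) {
      for (id in ls(pgrads)) {
        pg <- pgrads[[id]]
        pp <- params[[id]]
        for (nm in names(pg)) pp[[nm]] <- pp[[nm]] - lr * pg[[nm]]
        params[[id]] <- pp
      }
    }
  }
}

# ---- training / prediction ------------------------------------------------

#' Construct a training configuration
#'
#' @param seed Master seed (initialization was already fixed at
#'   [realizeModel()]; this seed drives dropout masks and shuffling).
#' @param epochs Number of epochs (0 leaves the model untouched).
#' @param batchSize Images per batch.
#' @param learningRate Step size (Adam default 1e-3).
#' @param optimizer \code{"adam"} or \code{"sgd"}.
#' @param diceSmoothing Dice smoothing constant.
#' @param deterministic Seeded, bitwise-reproducible run.
#' @param targetLoss Stop once the epoch training loss reaches this value
#'   (NA: never).
#' @param shuffle Reshuffle batch order each epoch (seeded).
#' @return A \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(seed = 1L, epochs = 100L, batchSize = 4L,
                           learningRate = 1e-3, optimizer = "adam",
                           diceSmoothing = 1, deterministic = TRUE,
                           targetLoss = NA_real_, shuffle = FALSE) {
  new("TrainingConfig", seed = asCount(seed, "seed", 0L),
      epochs = asCount(epochs, "epochs", 0L),
      batchSize = asCount(batchSize, "batchSize"),
      learningRate = learningRate, optimizer = optimizer,
      diceSmoothing = diceSmoothing, deterministic = deterministic,
      targetLoss = as.numeric(targetLoss), shuffle = shuffle)
}

sampleImage <- function(p) {
  im <- p$image
  if (length(dim(im)) == 2L || is.null(dim(im))) dim(im) <- c(dim(as.matrix(im)), 1L)
  im
}

stackSamples <- function(pairs, graph) {
  n <- length(pairs)
  hw <- graph@inputSize
  x <- array(0, c(hw[1], hw[2], graph@inputChannels, n))
  ymask <- array(0, c(hw[1], hw[2], 1L, n))
  for (i in seq_len(n)) {
    im <- sampleImage(pairs[[i]])
    if (!all(dim(im) == c(hw, graph@inputChannels)))
      argumentError(
        "image '%s' (%s) does not match the graph input %dx%dx%d",
        pairs[[i]]$id %||% i, paste(dim(im), collapse = "x"),
        hw[1], hw[2], graph@inputChannels)
    x[, , , i] <- im
    ymask[, , 1L, i] <- pairs[[i]]$mask
  }
  list(x = x, y = ymask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a realized model with Dice loss
#'
#' Full in-memory training on image/mask pairs. Under
#' \code{deterministic = TRUE} (default) the whole run is a pure function of
#' (model parameters, data, config): two runs from the same realized model
#' and seed produce bitwise-identical loss traces. Training aborts with a
#' diagnostic naming the epoch and batch if the loss becomes non-finite.
#'
#' @param model An \linkS4class{EUNetModel}; parameters are updated in place.
#' @param trainSet List of sample pairs (\code{list(image, mask, id)}), all
#'   at the graph's input size.
#' @param valSet Optional validation pairs; per-epoch validation loss and
#'   metrics are added to the trace.
#' @param config A \linkS4class{TrainingConfig}.
#' @return A \linkS4class{TrainingResult}.
#' @export
trainModel <- function(model, trainSet, valSet = NULL,
                       config = trainingConfig()) {
  if (!is(model, "EUNetModel")) argumentError("model must be an EUNetModel")
  if (length(trainSet) == 0L) argumentError("empty training set")
  validObject(config)
  tr <- stackSamples(trainSet, model@graph)
  va <- if (!is.null(valSet) && length(valSet))
    stackSamples(valSet, model@graph) else NULL
  n <- dim(tr$x)[4]
  opt <- makeOptimizer(config)
  rows <- list()

  runEpochs <- function() {
    for (ep in seq_len(config@epochs)) {
      idx <- seq_len(n)
      if (config@shuffle) idx <- sample(idx)
      starts <- seq(1L, n, by = config@batchSize)
      epochLoss <- 0
      for (bi in seq_along(starts)) {
        take <- idx[starts[bi]:min(starts[bi] + config@batchSize - 1L, n)]
        xb <- tr$x[, , , take, drop = FALSE]
        yb <- tr$y[, , , take, drop = FALSE]
        fw <- forwardPass(model, xb, training = TRUE)
        loss <- diceLoss(fw$out, yb, config@diceSmoothing)
        if (!is.finite(loss))
          eunetError("eunetNumericError",
                     "non-finite training loss at epoch %d, batch %d", ep, bi)
        gout <- diceGrad(fw$out, yb, config@diceSmoothing)
        pg <- backwardPass(model, fw, gout)
        opt(model@params, pg)
        epochLoss <- epochLoss + loss * length(take)
      }
      row <- data.frame(epoch = ep, train_loss = epochLoss / n)
      if (!is.null(va)) {
        fwv <- forwardPass(model, va$x, training = FALSE, keepCache = FALSE)
        row$val_loss <- diceLoss(fwv$out, va$y, config@diceSmoothing)
        rep <- metricReport(confusionCounts(1 * (fwv$out > 0.5), va$y))
        row$val_accuracy <- rep@accuracy
        row$val_precision <- rep@precision
        row$val_specificity <- rep@specificity
        row$val_miou <- rep@miou
      }
      rows[[length(rows) + 1L]] <<- row
      if (!is.na(config@targetLoss) && row$train_loss <= config@targetLoss)
        break
    }
  }
  if (config@deterministic) withSeed(config@seed, runEpochs()) else runEpochs()

  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoch = integer(), train_loss = numeric())
  new("TrainingResult", trace = trace, config = config, model = model)
}

#' Predict a probability map
#'
#' The realized network is fully convolutional: any input whose sides are
#' divisible by the architecture's pooling requirement is accepted. With
#' \code{pad = "reflect"}, incompatible sizes are reflect-padded to the next
#' valid multiple and the output is cropped back to the original size.
#'
#' @param model An \linkS4class{EUNetModel}.
#' @param image 2-D (grayscale) or 3-D (H, W, channels) array in [0, 1].
#' @param pad \code{"error"} (default) or \code{"reflect"}.
#' @return Matrix of foreground probabilities in [0, 1], same spatial size
#'   as the input.
#' @export
predictModel <- function(model, image, pad = c("error", "reflect")) {
  pad <- match.arg(pad)
  im <- image
  if (is.null(dim(im)) || length(dim(im)) == 2L)
    dim(im) <- c(dim(as.matrix(image)), 1L)
  if (dim(im)[3] != model@graph@inputChannels)
    argumentError("image has %d channel(s); the model expects %d",
                  dim(im)[3], model@graph@inputChannels)
  levels <- maxDescent(model@graph@spec) + 1L
  div <- 2L^(levels - 1L)
  orig <- dim(im)[1:2]
  rec <- NULL
  if (any(orig %% div != 0L)) {
    if (pad == "error")
      argumentError(
        "image size %dx%d is not divisible by %d; use pad = \"reflect\"",
        orig[1], orig[2], div)
    padded <- padToDivisible(im, levels)
    im <- padded$image
    rec <- padded$record
  }
  x <- im
  dim(x) <- c(dim(im), 1L)
  out <- forwardPass(model, x, training = FALSE, keepCache = FALSE)$out
  pm <- out[, , 1L, 1L]
  if (!is.null(rec)) pm <- unpadImage(pm, rec)
  pm
}

#' Save / load a trained model
#'
#' Weights go to an RDS checkpoint next to a JSON sidecar recording the
#' graph, its fingerprint, and the seed, so a loaded model can be checked
#' against the architecture that produced it.
#'
#' @param model An \linkS4class{EUNetModel}.
#' @param path Basename; writes \code{<path>.rds} and \code{<path>.json}.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: an
#'   \linkS4class{EUNetModel}.
#' @export
saveModel <- function(model, path) {
  ids <- ls(model@params)
  saveRDS(list(params = mget(ids, envir = model@params), seed = model@seed),
          paste0(path, ".rds"))
  writeLines(as.character(jsonlite::toJSON(list(
    fingerprint = model@fingerprint, seed = model@seed,
    parameter_count = model@parameterCount,
    notation = formatArchitecture(model@graph@spec),
    input_size = model@graph@inputSize,
    base_filters = model@graph@baseFilters), auto_unbox = TRUE)),
    paste0(path, ".json"))
  invisible(path)
}

#' @rdname saveModel
#' @param graph The \linkS4class{LayerGraph} the checkpoint belongs to.
#' @export
loadModel <- function(path, graph) {
  blob <- readRDS(paste0(path, ".rds"))
  model <- realizeModel(graph, blob$seed)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  if (!identical(side$fingerprint, model@fingerprint))
    configError("checkpoint fingerprint %s does not match the graph (%s)",
                side$fingerprint, model@fingerprint)
  for (id in names(blob$params)) model@params[[id]] <- blob$params[[id]]
  model
}

setMethod("show", "EUNetModel", function(object) {
  cat("EUNetModel:", formatArchitecture(object@graph@spec), "\n")
  cat(sprintf("  input %dx%dx%d, base filters %d, seed %d\n",
              object@graph@inputSize[1], object@graph@inputSize[2],
              object@graph@inputChannels, object@graph@baseFilters,
              object@seed))
  cat(sprintf("  %s trainable parameters, fingerprint %s\n",
              format(object@parameterCount, big.mark = ","),
              object@fingerprint))
})

setMethod("show", "TrainingResult", function(object) {
  nt <- nrow(object@trace)
  cat(sprintf("TrainingResult: %d epoch(s)\n", nt))
  if (nt > 0) {
    cat(sprintf("  final train loss %.4f\n", object@trace$train_loss[nt]))
    if ("val_loss" %in% names(object@trace))
      cat(sprintf("  final val loss %.4f\n", object@trace$val_loss[nt]))
  }
})

#' Write a training trace as CSV
#'
#' @param result A \linkS4class{TrainingResult}.
#' @param file Output path.
#' @export
writeTrace <- function(result, file) {
  utils::write.csv(result@trace, file, row.names = FALSE)
  invisible(file)
}
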