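# Compile an ArchitectureSpec into an explicit layer graph.
#
# Construction schedule (the reference single-high-peak cascade
# "U_1(4-4)-U_2(4-4)" at 128x128 compiles to blocks Lay1..Lay13 + Output):
#   down block at elevation e : two 3x3 convs at f_d*2^(-e) (+BN+ReLU), 2x2 pool
#   valley                    : two 3x3 convs at f_d*2^(-e), dropout, no pool
#   up block at elevation e   : 2x upsample, 2x2 conv halving channels, concat
#                               with the equal-elevation skip partner of the
#                               same U-structure, two 3x3 convs (+BN+ReLU)
#   peak (cascade joint)      : up block ops, then the next segment's 2x2 pool
#   terminal up block         : up block whose second conv is 1x1
#   output head               : 3x3 conv to 2 channels, 1x1 conv to 1, sigmoid
# Parallel branch groups split at the segment input and fuse (channel concat
# + one 3x3 fusion conv) at the valleys and at the branch output layers.

opConv <- function(k, channels, mult = NA_real_, dilation = 1L)
  list(kind = "conv", kernel = c(k, k), channels_out = as.integer(channels),
       mult = mult, dilation = as.integer(dilation))
opPool <- function() list(kind = "pool", factor = 2L)
opUpsample <- function() list(kind = "upsample", factor = 2L)
opConcat <- function(source) list(kind = "concat", source = source)
opDropout <- function(rate) list(kind = "dropout", rate = rate)
opBatchnorm <- function() list(kind = "batchnorm")
opActivation <- function(fun = "relu") list(kind = "activation", fun = fun)

#' Compile an architecture into a layer graph
#'
#' Turns a parsed architecture (or a notation string) into an explicit
#' directed acyclic graph of layer blocks with concrete primitive operations,
#' channel counts, and skip/split/merge wiring. For the reference single
#' high-peak cascade \code{"U_1(4-4)-U_2(4-4)"} at 128x128 the compiled graph
#' consists of the thirteen indexed blocks \code{Lay1..Lay13} plus the output
#' head, with the 128/64/32/16 feature-size schedule.
#'
#' @param spec An \linkS4class{ArchitectureSpec} or a notation string.
#' @param inputSize Integer pair (or scalar) image size; each side must be
#'   divisible by \code{2^maxDescent(spec)}.
#' @param baseFilters Base filter count f_d of the top level; deeper levels
#'   use f_d x 2, x 4, x 8, ...
#' @param inputChannels 1 (grayscale) or 3 (RGB).
#' @param peakToOutputConcat Concatenate the pre-pool features of every
#'   cascade joint sitting at the input height into the output head (the
#'   "cascaded output of the input/output layer and peak layer"). Joints at
#'   lower heights (low-peak forms) are never concatenated: their resolution
#'   differs from the output.
#' @param batchNorm Insert batch normalization after each 3x3 convolution.
#' @param dropoutRate Dropout rate at the valleys.
#' @return A \linkS4class{LayerGraph}.
#' @examples
#' g <- buildLayerGraph("U_1(4-4)-U_2(4-4)", inputSize = 128, baseFilters = 4)
#' countLayerBlocks(g@spec)
#' @export
buildLayerGraph <- function(spec, inputSize = c(128L, 128L), baseFilters = 64L,
                            inputChannels = 1L, peakToOutputConcat = TRUE,
                            batchNorm = TRUE, dropoutRate = 0.5) {
  if (is.character(spec)) spec <- parseArchitecture(spec)
  if (!is(spec, "ArchitectureSpec"))
    argumentError("spec must be an ArchitectureSpec or a notation string")
  validObject(spec)
  inputSize <- asSizePair(inputSize)
  f <- asCount(baseFilters, "baseFilters")
  chIn <- asCount(inputChannels, "inputChannels")
  div <- 2L^maxDescent(spec)
  if (any(inputSize %% div != 0L))
    configError(
      "input size %dx%d incompatible with %d pooling level(s): each side must be a multiple of %d",
      inputSize[1], inputSize[2], maxDescent(spec), div)

  nodes <- list()
  esrc <- character(); edst <- character(); ekind <- character()
  addNode <- function(id, role, u_labels, branch, elev, ops) {
    nodes[[id]] <<- list(id = id, role = role, u_label = u_labels[1],
                         u_labels = u_labels, branch_index = branch,
                         elevation = as.integer(elev), ops = ops)
  }
  addEdge <- function(s, d, k) {
    esrc <<- c(esrc, s); edst <<- c(edst, d); ekind <<- c(ekind, k)
  }
  chan <- function(e) f * 2L^(-e)
  bnOps <- function() if (batchNorm) list(opBatchnorm()) else list()
  convBlock <- function(e) c(
    list(opConv(3L, chan(e), 2^(-e))), bnOps(), list(opActivation()),
    list(opConv(3L, chan(e), 2^(-e))), bnOps(), list(opActivation()))

  nseg <- length(spec@segments)
  k <- 0L             # running block index along the main chain
  prevOut <- NA_character_
  peaks0 <- character()  # elevation-0 cascade joints, for the output concat
  e0 <- 0L

  for (s in seq_len(nseg)) {
    grp <- spec@segments[[s]]
    b <- length(grp@branches)
    d <- grp@branches[[1L]]@down
    u <- grp@branches[[1L]]@up
    eV <- e0 - (d - 1L)
    e1 <- e0 - d + u
    nextD <- if (s < nseg) spec@segments[[s + 1L]]@branches[[1L]]@down else NA_integer_
    jointId <- prevOut  # pre-segment joint: skip source at elevation e0

    if (u == 1L && s < nseg && !is.na(nextD) && nextD >= 2L)
      validationError(
        "segment %d ends at its valley and cannot cascade into a deeper segment",
        s)

    branchSrc <- prevOut
    firstKind <- "forward"
    if (b > 1L) {
      sid <- paste0("Split", s)
      flowElev <- if (s == 1L) e0 else e0 - 1L
      addNode(sid, "split", NA_character_, NA_integer_, flowElev, list())
      if (s > 1L) addEdge(prevOut, sid, "forward")
      branchSrc <- sid
      firstKind <- "branch_split"
    }

    kStart <- k
    state <- vector("list", b)
    for (j in seq_len(b)) {
      ub <- grp@branches[[j]]
      sfx <- if (b > 1L) sub("^U", "", ub@label) else ""
      kb <- kStart
      elevMap <- list()
      if (s > 1L) elevMap[[as.character(e0)]] <- jointId
      prev <- branchSrc
      kind <- firstKind

      downElevs <- if (s == 1L) {
        if (d >= 2L) seq(e0, by = -1L, length.out = d - 1L) else integer()
      } else {
        if (d >= 3L) seq(e0 - 1L, by = -1L, length.out = d - 2L) else integer()
      }
      for (e in downElevs) {
        kb <- kb + 1L
        id <- paste0("Lay", kb, sfx)
        role <- if (s == 1L && e == e0) "input_down" else "down"
        addNode(id, role, ub@label, j, e, c(convBlock(e), list(opPool())))
        if (!is.na(prev)) addEdge(prev, id, kind)
        kind <- "forward"
        elevMap[[as.character(e)]] <- id
        prev <- id
      }

      kb <- kb + 1L
      vid <- paste0("Lay", kb, sfx)
      vrole <- if (s == 1L && d == 1L) "input_down" else "valley"
      addNode(vid, vrole, ub@label, j,
              eV, c(convBlock(eV), list(opDropout(dropoutRate))))
      if (!is.na(prev)) addEdge(prev, vid, kind)
      state[[j]] <- list(prev = vid, valley = vid, kb = kb,
                         elevMap = elevMap, sfx = sfx, label = ub@label)
    }

    mergeV <- NA_character_
    if (b > 1L) {
      mergeV <- paste0("MergeV", s)
      labs <- vapply(grp@branches, function(x) x@label, character(1))
      addNode(mergeV, "merge", labs, NA_integer_, eV,
              c(list(opConcat("merge"),
                     opConv(3L, chan(eV), 2^(-eV))),
                bnOps(), list(opActivation())))
      for (j in seq_len(b))
        addEdge(state[[j]]$valley, mergeV,
                if (j == 1L) "forward" else "branch_merge")
    }

    terminals <- character(b)
    for (j in seq_len(b)) {
      st <- state[[j]]
      prev <- if (b > 1L) mergeV else st$prev
      kb <- st$kb
      upElevs <- if (u >= 2L) seq(eV + 1L, e1, by = 1L) else integer()
      for (e in upElevs) {
        kb <- kb + 1L
        id <- paste0("Lay", kb, st$sfx)
        isTerm <- (e == e1)
        role <- if (!isTerm || b > 1L) "up"
                else if (s == nseg) "output_up" else "peak"
        skipSrc <- st$elevMap[[as.character(e)]]
        ops <- c(list(opUpsample(),
                      opConv(2L, chan(e), 2^(-e)),
                      opActivation()),
                 if (!is.null(skipSrc)) list(opConcat("skip")),
                 list(opConv(3L, chan(e), 2^(-e))), bnOps(),
                 list(opActivation()),
                 list(opConv(if (isTerm && s == nseg) 1L else 3L,
                             chan(e), 2^(-e))), bnOps(),
                 list(opActivation()))
        if (isTerm && s < nseg && b == 1L && nextD >= 2L)
          ops <- c(ops, list(opPool()))
        addNode(id, role, st$label, j, e, ops)
        addEdge(prev, id, "forward")
        if (!is.null(skipSrc)) addEdge(skipSrc, id, "skip")
        prev <- id
      }
      terminals[j] <- prev
      state[[j]]$kb <- kb
    }
    k <- state[[1L]]$kb

    if (b > 1L) {
      if (u >= 2L) {
        mo <- paste0("MergeO", s)
        labs <- vapply(grp@branches, function(x) x@label, character(1))
        if (s < nseg)
          labs <- c(labs, vapply(spec@segments[[s + 1L]]@branches,
                                 function(x) x@label, character(1)))
        ops <- c(list(opConcat("merge"),
                      opConv(3L, chan(e1), 2^(-e1))),
                 bnOps(), list(opActivation()))
        if (s < nseg && nextD >= 2L) ops <- c(ops, list(opPool()))
        addNode(mo, "merge", labs, NA_integer_, e1, ops)
        for (j in seq_len(b))
          addEdge(terminals[j], mo,
                  if (j == 1L) "forward" else "branch_merge")
        prevOut <- mo
      } else {
        prevOut <- mergeV  # u == 1: the fused valley is the segment output
      }
    } else {
      prevOut <- terminals[1L]
      if (s < nseg) {
        # the joint also serves as the next U's top-level skip source
        nxt <- vapply(spec@segments[[s + 1L]]@branches,
                      function(x) x@label, character(1))
        nodes[[prevOut]]$u_labels <- c(nodes[[prevOut]]$u_labels, nxt)
      }
    }
    if (s < nseg && e1 == 0L) peaks0 <- c(peaks0, prevOut)
    e0 <- e1
  }

  hops <- c(if (peakToOutputConcat && length(peaks0)) list(opConcat("peaks")),
            list(opConv(3L, 2L), opActivation(),
                 opConv(1L, 1L), opActivation("sigmoid")))
  addNode("Output", "output_head", NA_character_, NA_integer_, 0L, hops)
  addEdge(prevOut, "Output", "forward")
  if (peakToOutputConcat) for (p in peaks0) addEdge(p, "Output", "skip")

  g <- new("LayerGraph", nodes = nodes,
           edges = data.frame(src = esrc, dst = edst, kind = ekind,
                              stringsAsFactors = FALSE),
           inputSize = inputSize, inputChannels = chIn,
           baseFilters = f, spec = spec)
  validObject(g)
  g
}

segmentBlockCount <- function(s, d, u) {
  downs <- if (s == 1L) d - 1L else max(0L, d - 2L)
  downs + 1L + max(0L, u - 1L)
}

#' Count the indexed layer blocks of an architecture
#'
#' Number of indexed blocks (the \code{LayN} labels) along the longest
#' root-to-output chain of one branch; parallel branches share the same
#' indices. The reference cascade \code{"U_1(4-4)-U_2(4-4)"} has 13.
#'
#' @param spec An \linkS4class{ArchitectureSpec} or notation string.
#' @return Integer.
#' @export
countLayerBlocks <- function(spec) {
  if (is.character(spec)) spec <- parseArchitecture(spec)
  if (!is(spec, "ArchitectureSpec"))
    argumentError("spec must be an ArchitectureSpec or a notation string")
  total <- 0L
  for (s in seq_along(spec@segments)) {
    br <- spec@segments[[s]]@branches[[1L]]
    total <- total + segmentBlockCount(s, br@down, br@up)
  }
  total
}

#' Effective extent of a dilated convolution kernel
#'
#' One-sided receptive extent of a single dilated convolution:
#' \code{kernel + (kernel - 1) * (rate - 1)}. A 3x3 kernel covers 3 pixels
#' per side at rate 1 and 5 at rate 2.
#'
#' @param kernel Odd positive kernel size.
#' @param rate Dilation rate >= 1.
#' @return Integer extent in pixels per side.
#' @examples
#' dilatedKernelExtent(3, 2)  # 5
#' @export
dilatedKernelExtent <- function(kernel, rate) {
  kernel <- asCount(kernel, "kernel")
  rate <- asCount(rate, "rate")
  as.integer(kernel + (kernel - 1L) * (rate - 1L))
}

#' Build a baseline U-Net graph
#'
#' The plain U-Net of a given depth is the degenerate single-segment cascade
#' \code{"U_1(d-d)"}; this is the same code path as [buildLayerGraph()], not
#' a re-implementation.
#'
#' @param depth Descending/ascending depth (levels including the valley).
#' @inheritParams buildLayerGraph
#' @param ... Passed on to [buildLayerGraph()].
#' @return A \linkS4class{LayerGraph}.
#' @export
buildBaselineUnet <- function(depth, inputSize = c(128L, 128L),
                              baseFilters = 64L, ...) {
  depth <- asCount(depth, "depth")
  buildLayerGraph(sprintf("U_1(%d-%d)", depth, depth),
                  inputSize = inputSize, baseFilters = baseFilters, ...)
}

#' Build a dilated U-Net graph
#'
#' Baseline U-Net whose top \code{dilatedLevels} contracting layers use
#' dilation-rate-2 convolutions in place of standard ones (the "(L1)", "(L2)"
#' ... family: L1 dilates only the top layer, L\emph{d} all contracting
#' levels including the valley).
#'
#' @param depth U depth.
#' @param dilatedLevels How many top contracting levels use dilated convs;
#'   between 1 and \code{depth}.
#' @inheritParams buildBaselineUnet
#' @return A \linkS4class{LayerGraph}.
#' @export
buildDilatedUnet <- function(depth, dilatedLevels, inputSize = c(128L, 128L),
                             baseFilters = 64L, ...) {
  depth <- asCount(depth, "depth")
  if (length(dilatedLevels) != 1L || is.na(dilatedLevels) ||
      dilatedLevels != round(dilatedLevels) ||
      dilatedLevels < 1L || dilatedLevels > depth)
    argumentError("dilatedLevels must be an integer in [1, depth]")
  g <- buildBaselineUnet(depth, inputSize = inputSize,
                         baseFilters = baseFilters, ...)
  for (id in names(g@nodes)) {
    nd <- g@nodes[[id]]
    if (nd$role %in% c("input_down", "down", "valley") &&
        nd$elevation >= -(dilatedLevels - 1L)) {
      nd$ops <- lapply(nd$ops, function(op) {
        if (op$kind == "conv" && op$kernel[1] == 3L) op$dilation <- 2L
        op
      })
      g@nodes[[id]] <- nd
    }
  }
  g
}

# single incoming forward-type predecessor of a node (NA for the entry)
forwardSource <- function(graph, id) {
  e <- graph@edges
  src <- e$src[e$dst == id & e$kind %in% c("forward", "branch_split")]
  if (length(src) == 0L) NA_character_
  else if (length(src) == 1L) src
  else validationError("node %s has %d forward predecessors", id, length(src))
}

concatSources <- function(graph, id, source) {
  e <- graph@edges
  switch(source,
    skip = ,
    peaks = e$src[e$dst == id & e$kind == "skip"],
    merge = e$src[e$dst == id & e$kind == "branch_merge"],
    validationError("unknown concat source '%s'", source))
}

#' Infer per-layer feature-map shapes
#'
#' Walks the graph in topological order simulating every primitive operation
#' and returns one row per layer block with the resolution and channel count
#' of its feature map (for blocks ending in a pool, the pre-pool
#' convolutional output, which is what architecture tables report), plus
#' Input and Output rows. For the reference cascade at 128x128 this
#' reproduces the 128/64/32/16 schedule and the f_d x {1,2,4,8} channel
#' multipliers exactly.
#'
#' @param graph A \linkS4class{LayerGraph}.
#' @return A \code{data.frame} (classed \code{ShapeTable}) with columns
#'   \code{id}, \code{role}, \code{height}, \code{width}, \code{channels},
#'   \code{mult} (channel count as a multiple of f_d, NA for fixed-width
#'   layers).
#' @export
inferShapes <- function(graph) {
  if (!is(graph, "LayerGraph")) argumentError("graph must be a LayerGraph")
  shp <- list()  # id -> list(out = c(h,w,c), pre = c(h,w,c))
  rows <- list()
  rows[[1]] <- data.frame(id = "Input", role = "input",
                          height = graph@inputSize[1],
                          width = graph@inputSize[2],
                          channels = graph@inputChannels, mult = NA_real_,
                          stringsAsFactors = FALSE)
  for (id in names(graph@nodes)) {
    nd <- graph@nodes[[id]]
    src <- forwardSource(graph, id)
    cur <- if (is.na(src)) c(graph@inputSize, graph@inputChannels)
           else shp[[src]]$out
    pre <- cur
    mult <- NA_real_
    for (op in nd$ops) {
      cur <- switch(op$kind,
        conv = {
          if (is.na(mult) && !is.null(op$mult) && !is.na(op$mult))
            mult <- op$mult
          c(cur[1:2], op$channels_out)
        },
        pool = {
          if (any(cur[1:2] %% op$factor != 0L))
            configError("cannot pool %dx%d at node %s: not divisible by %d",
                        cur[1], cur[2], id, op$factor)
          c(cur[1:2] %/% op$factor, cur[3])
        },
        upsample = c(cur[1:2] * op$factor, cur[3]),
        concat = {
          extra <- 0L
          for (sid in concatSources(graph, id, op$source)) {
            sshp <- if (op$source == "merge") shp[[sid]]$out else shp[[sid]]$pre
            if (!all(sshp[1:2] == cur[1:2]))
              validationError(
                "concat shape conflict at %s: %dx%d (from %s) vs %dx%d",
                id, sshp[1], sshp[2], sid, cur[1], cur[2])
            extra <- extra + sshp[3]
          }
          c(cur[1:2], cur[3] + extra)
        },
        cur)  # dropout / batchnorm / activation keep the shape
      if (op$kind != "pool") pre <- cur
    }
    shp[[id]] <- list(out = cur, pre = pre)
    if (nd$role != "split")
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, role = nd$role, height = pre[1], width = pre[2],
        channels = pre[3], mult = mult, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ShapeTable", "data.frame")
  out
}

#' Structural isomorphism of two layer graphs
#'
#' Compares two graphs up to node identifiers: node order, roles, elevations
#' and primitive-operation schedules must agree, and the edge sets must map
#' onto each other under the positional correspondence.
#'
#' @param g1,g2 \linkS4class{LayerGraph} objects.
#' @return Logical.
#' @export
graphIsomorphic <- function(g1, g2) {
  sig <- function(g) {
    idx <- stats::setNames(seq_along(g@nodes), names(g@nodes))
    nodeSig <- lapply(g@nodes, function(nd)
      list(role = nd$role, elevation = nd$elevation,
           ops = lapply(nd$ops, function(op) op[setdiff(names(op), "mult")])))
    edges <- data.frame(src = unname(idx[g@edges$src]),
                        dst = unname(idx[g@edges$dst]),
                        kind = g@edges$kind, stringsAsFactors = FALSE)
    edges <- edges[order(edges$src, edges$dst, edges$kind), ]
    rownames(edges) <- NULL
    list(nodes = unname(nodeSig), edges = edges,
         inputSize = g@inputSize, baseFilters = g@baseFilters)
  }
  isTRUE(all.equal(sig(g1), sig(g2)))
}

#' Export a layer graph as JSON
#'
#' @param graph A \linkS4class{LayerGraph}.
#' @param file Optional path; when given, writes the JSON and returns it
#'   invisibly.
#' @return JSON string.
#' @export
graphToJSON <- function(graph, file = NULL) {
  obj <- list(
    notation = formatArchitecture(graph@spec),
    input_size = graph@inputSize,
    input_channels = graph@inputChannels,
    base_filters = graph@baseFilters,
    nodes = lapply(unname(graph@nodes), function(nd)
      list(id = nd$id, role = nd$role, u_label = nd$u_label,
           branch_index = nd$branch_index, elevation = nd$elevation,
           ops = nd$ops)),
    edges = graph@edges)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Export a layer graph in DOT format for visualization
#'
#' @param graph A \linkS4class{LayerGraph}.
#' @param file Optional output path.
#' @return Character vector of DOT lines, invisibly when \code{file} given.
#' @export
graphToDOT <- function(graph, file = NULL) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph eunet {", "  rankdir=LR;")
  for (nd in graph@nodes) {
    lines <- c(lines, sprintf("  %s [label=%s shape=box];",
                              q(nd$id), q(sprintf("%s\\n%s", nd$id, nd$role))))
  }
  style <- c(forward = "", skip = " [style=dashed]",
             branch_split = " [color=blue]", branch_merge = " [color=red]")
  for (i in seq_len(nrow(graph@edges))) {
    e <- graph@edges[i, ]
    lines <- c(lines, sprintf("  %s -> %s%s;", q(e$src), q(e$dst),
                              style[[e$kind]]))
  }
  lines <- c(lines, "}")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

setMethod("show", "LayerGraph", function(object) {
  roles <- vapply(object@nodes, `[[`, character(1), "role")
  cat("LayerGraph:", formatArchitecture(object@spec), "\n")
  cat(sprintf("  input %dx%dx%d, base filters %d\n",
              object@inputSize[1], object@inputSize[2],
              object@inputChannels, object@baseFilters))
  cat(sprintf("  %d nodes (%d indexed blocks), %d edges\n",
              length(object@nodes), sum(grepl("^Lay", names(object@nodes))),
              nrow(object@edges)))
  cat("  roles:", paste(sprintf("%s=%d", names(table(roles)), table(roles)),
                        collapse = " "), "\n")
})
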