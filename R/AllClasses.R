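#' @import methods
NULL

#' One U-shaped contract--expand unit
#'
#' A single U-structure \code{U(d-u)}: \code{down} descending levels
#' (including the valley) and \code{up} ascending levels (including the
#' terminal layer). The high-peak form has \code{down == up}; low-peak and
#' raised transitions differ by exactly one level.
#'
#' @slot label Branch identifier such as \code{"U_1"} or \code{"U^1"};
#'   subscript/superscript decorations are opaque and carry no structure.
#' @slot down Descending depth (levels, including the valley), >= 1.
#' @slot up Ascending depth (levels, including the terminal layer), >= 1.
#' @export
setClass("UStructureSpec",
  representation(label = "character", down = "integer", up = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@down) != 1L || is.na(object@down) || object@down < 1L)
      msg <- c(msg, "down depth must be a single integer >= 1")
    if (length(object@up) != 1L || is.na(object@up) || object@up < 1L)
      msg <- c(msg, "up depth must be a single integer >= 1")
    if (length(msg) == 0L && abs(object@down - object@up) > 1L)
      msg <- c(msg, sprintf(
        "|down - up| must be <= 1 (got %d-%d); only adjacent-height peaks are representable",
        object@down, object@up))
    if (length(msg)) msg else TRUE
  })

#' A group of parallel U-structure branches
#'
#' One cascade segment. A group of size one is an ordinary horizontal
#' segment; larger groups are the spatial (parallel-branch) form, split at
#' the segment input and fused at the valleys and the branch output layers.
#'
#' @slot branches List of \linkS4class{UStructureSpec}, length >= 1; all
#'   branches of one group share the same (down, up) depths so that their
#'   valleys and outputs sit at equal resolution for fusion.
#' @export
setClass("BranchGroup",
  representation(branches = "list"),
  validity = function(object) {
    if (length(object@branches) < 1L)
      return("a branch group needs at least one U-structure")
    if (!all(vapply(object@branches, is, logical(1), "UStructureSpec")))
      return("branches must be UStructureSpec objects")
    d <- vapply(object@branches, function(b) b@down, integer(1))
    u <- vapply(object@branches, function(b) b@up, integer(1))
    if (length(unique(d)) > 1L || length(unique(u)) > 1L)
      return("all branches in a parallel group must share the same (down-up) depths")
    labs <- vapply(object@branches, function(b) b@label, character(1))
    if (anyDuplicated(labs))
      return("branch labels within a group must be distinct")
    TRUE
  })

#' A validated elastomeric U-Net architecture description
#'
#' An ordered cascade of \linkS4class{BranchGroup} segments. Elevation
#' bookkeeping starts at 0 (the input height); segment i ends at elevation
#' \code{e_{i-1} - down_i + up_i}. Every accepted architecture returns to
#' elevation 0 at the output, so the output layer sits at the input height.
#'
#' @slot segments List of \linkS4class{BranchGroup}, cascade order.
#' @slot peakElevations Integer vector, the elevation reached after each
#'   segment (the last entry is always 0).
#' @export
setClass("ArchitectureSpec",
  representation(segments = "list", peakElevations = "integer"),
  validity = function(object) {
    if (length(object@segments) < 1L)
      return("an architecture needs at least one segment")
    if (!all(vapply(object@segments, is, logical(1), "BranchGroup")))
      return("segments must be BranchGroup objects")
    e <- 0L
    elev <- integer(length(object@segments))
    for (i in seq_along(object@segments)) {
      b <- object@segments[[i]]@branches[[1L]]
      e <- e - b@down + b@up
      elev[i] <- e
      if (e > 0L)
        return(sprintf("elevation rises above the input height after segment %d", i))
    }
    if (!identical(elev, object@peakElevations))
      return("peakElevations is inconsistent with the segment depths")
    if (e != 0L)
      return(sprintf("output not at input height (final elevation %d)", e))
    TRUE
  })

#' Compiled layer graph of an EUNet architecture
#'
#' Directed acyclic graph of layer blocks. Each node is a list with fields
#' \code{id}, \code{role} (one of input_down, down, valley, up, peak,
#' output_up, output_head, split, merge), \code{u_label}, \code{branch_index},
#' \code{elevation} (<= 0) and \code{ops} (ordered list of primitive
#' operations: conv, pool, upsample, concat, dropout, batchnorm, activation).
#' Edges carry kinds forward, skip, branch_split, branch_merge. Skip edges
#' always join nodes of equal elevation within one U-structure; different
#' U-structures share no interior connections.
#'
#' @slot nodes Named list of layer-node lists, topological order.
#' @slot edges data.frame with columns src, dst, kind.
#' @slot inputSize Integer pair (height, width).
#' @slot inputChannels Integer, channels of the input image (1 or 3).
#' @slot baseFilters Integer, the base filter count f_d of the first level.
#' @slot spec The \linkS4class{ArchitectureSpec} the graph was compiled from.
#' @export
setClass("LayerGraph",
  representation(nodes = "list", edges = "data.frame",
                 inputSize = "integer", inputChannels = "integer",
                 baseFilters = "integer", spec = "ArchitectureSpec"),
  validity = function(object) {
    ids <- names(object@nodes)
    if (anyDuplicated(ids)) return("duplicate node ids")
    e <- object@edges
    if (!all(c("src", "dst", "kind") %in% names(e)))
      return("edges must have src, dst, kind columns")
    if (!all(c(e$src, e$dst) %in% ids)) return("edge endpoint not in nodes")
    if (!all(e$kind %in% c("forward", "skip", "branch_split", "branch_merge")))
      return("unknown edge kind")
    roles <- vapply(object@nodes, `[[`, character(1), "role")
    if (sum(roles == "output_head") != 1L)
      return("exactly one output_head node required")
    entry <- setdiff(ids, e$dst)
    if (length(entry) != 1L)
      return("exactly one entry (in-degree zero) node required")
    TRUE
  })

#' Realized trainable model
#'
#' A \linkS4class{LayerGraph} bound to concrete parameters (convolution
#' kernels, biases, batch-norm scales/offsets and running statistics) in an
#' environment, together with the execution plan used by the forward and
#' backward passes.
#'
#' @slot graph The compiled \linkS4class{LayerGraph}.
#' @slot plan Ordered list of primitive execution steps.
#' @slot params Environment holding parameter arrays, keyed by step id.
#' @slot seed Integer seed the parameters were initialized from.
#' @slot fingerprint Character, hash of the graph's JSON export.
#' @slot parameterCount Integer, analytic count of trainable scalars.
#' @export
setClass("EUNetModel",
  representation(graph = "LayerGraph", plan = "list", params = "environment",
                 seed = "integer", fingerprint = "character",
                 parameterCount = "numeric"))

#' Training configuration
#'
#' @slot seed Integer, master seed for initialization and dropout streams.
#' @slot epochs Non-negative integer.
#' @slot batchSize Positive integer.
#' @slot learningRate Positive numeric, Adam step size.
#' @slot optimizer Character, currently \code{"adam"} or \code{"sgd"}.
#' @slot diceSmoothing Positive numeric, the Dice smoothing constant.
#' @slot deterministic Logical; seeded, bitwise-reproducible training.
#' @slot targetLoss Numeric scalar or NA; stop early once the training loss
#'   reaches this value.
#' @slot shuffle Logical; reshuffle batches each epoch (seeded).
#' @export
setClass("TrainingConfig",
  representation(seed = "integer", epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 diceSmoothing = "numeric", deterministic = "logical",
                 targetLoss = "numeric", shuffle = "logical"),
  validity = function(object) {
    if (object@epochs < 0L) return("epochs must be >= 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@diceSmoothing <= 0) return("diceSmoothing must be > 0")
    if (!object@optimizer %in% c("adam", "sgd"))
      return("optimizer must be 'adam' or 'sgd'")
    TRUE
  })

#' Training result traces
#'
#' @slot trace data.frame with one row per completed epoch: epoch,
#'   train_loss and (when a validation set was given) val_loss plus the
#'   four validation metrics.
#' @slot config The \linkS4class{TrainingConfig} used.
#' @slot model The trained \linkS4class{EUNetModel} (parameters updated in
#'   place; kept here for provenance).
#' @export
setClass("TrainingResult",
  representation(trace = "data.frame", config = "TrainingConfig",
                 model = "EUNetModel"))

#' Pixel-level confusion counts
#'
#' @slot tp,fp,tn,fn Non-negative pixel counts (foreground = 1).
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric",
                 fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
    TRUE
  })

#' Segmentation metric report
#'
#' Accuracy, precision, specificity and mean IoU (two-class mean of
#' foreground and background IoU), all as percentages in [0, 100]. A metric
#' whose denominator is zero is undefined: it is reported as NA and named in
#' the \code{undefined} slot rather than silently zeroed.
#'
#' @slot accuracy,precision,specificity,miou Percentages (or NA).
#' @slot undefined Character vector naming undefined metrics.
#' @export
setClass("MetricReport",
  representation(accuracy = "numeric", precision = "numeric",
                 specificity = "numeric", miou = "numeric",
                 undefined = "character"),
  validity = function(object) {
    v <- c(object@accuracy, object@precision, object@specificity, object@miou)
    v <- v[!is.na(v)]
    if (any(v < 0 | v > 100)) return("metrics must lie in [0, 100]")
    TRUE
  })
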