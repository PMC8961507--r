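# The reference shape schedule of the single high-peak cascade
# U_1(4-4)-U_2(4-4) at 128x128: resolution and channel multiplier of every
# indexed block plus the input and output head.
shpSchedule <- data.frame(
  id = c("Input", paste0("Lay", 1:13), "Output"),
  res = c(128, 128, 64, 32, 16, 32, 64, 128, 64, 32, 16, 32, 64, 128, 128),
  mult = c(NA, 1, 2, 4, 8, 4, 2, 1, 2, 4, 8, 4, 2, 1, NA))

test_that("the reference cascade reproduces the published shape schedule exactly", {
  g <- buildLayerGraph("U_1(4-4)-U_2(4-4)", inputSize = 128, baseFilters = 64)
  st <- inferShapes(g)
  expect_identical(st$id, shpSchedule$id)
  expect_identical(st$height, as.integer(shpSchedule$res))
  expect_identical(st$width, as.integer(shpSchedule$res))
  expect_equal(st$mult, shpSchedule$mult)
  expect_identical(st$channels[st$id == "Lay2"], 128L)   # f_d x 2
  expect_identical(st$channels[st$id == "Output"], 1L)
  # valley blocks carry dropout and no pool; the peak ends with a pool
  kinds <- function(id) vapply(g@nodes[[id]]$ops, `[[`, character(1), "kind")
  expect_true("dropout" %in% kinds("Lay4"))
  expect_false("pool" %in% kinds("Lay4"))
  expect_identical(tail(kinds("Lay7"), 1), "pool")
  # the terminal block ends in a 1x1 convolution
  convs <- Filter(function(op) op$kind == "conv", g@nodes[["Lay13"]]$ops)
  expect_identical(convs[[length(convs)]]$kernel, c(1L, 1L))
})

test_that("shape inference follows the input size", {
  st <- inferShapes(buildLayerGraph("U_1(4-4)-U_2(4-4)", 64, 4))
  # valley of a depth-4 descent from 64: three halvings -> 8
  expect_identical(st$height[st$id == "Lay4"], 8L)
  expect_identical(st$height[st$id == "Lay13"], 64L)
})

test_that("layer-block counts match the labeling scheme", {
  expect_identical(countLayerBlocks("U_1(4-4)-U_2(4-4)"), 13L)
  expect_identical(countLayerBlocks("U_1(4-4)"), 7L)
  expect_identical(countLayerBlocks("U_1(2-2)"), 3L)
  expect_identical(countLayerBlocks("U_1(1-1)"), 1L)
  expect_identical(countLayerBlocks("U_1(4-3)-U_2(3-4)"), 11L)
  # the graph's indexed nodes agree with the count (longest chain per branch)
  for (nt in c("U_1(4-4)-U_2(4-4)", "U_1(3-3)", "U_1(4)//U^1(4)",
               "U_1(4-3)-U_2(3-4)", "U_1(3)//U^1(3)-U_2(5)")) {
    g <- buildLayerGraph(nt, 128, 2)
    idx <- grep("^Lay", names(g@nodes), value = TRUE)
    nums <- as.integer(sub("^Lay([0-9]+).*$", "\\1", idx))
    expect_identical(max(nums), countLayerBlocks(nt), info = nt)
  }
})

test_that("dilated kernel extents follow the receptive-field arithmetic", {
  expect_identical(dilatedKernelExtent(3, 2), 5L)
  expect_identical(dilatedKernelExtent(3, 1), 3L)
  expect_identical(dilatedKernelExtent(5, 1), 5L)
  expect_identical(dilatedKernelExtent(3, 3), 7L)
  expect_error(dilatedKernelExtent(0, 1), class = "eunetArgumentError")
  expect_error(dilatedKernelExtent(3, 0), class = "eunetArgumentError")
})

test_that("the baseline U-Net is the single-segment degenerate cascade", {
  for (d in 1:5) {
    b <- buildBaselineUnet(d, inputSize = 128, baseFilters = 4)
    g <- buildLayerGraph(parseArchitecture(sprintf("U_1(%d-%d)", d, d)),
                         inputSize = 128, baseFilters = 4)
    expect_true(graphIsomorphic(b, g), info = d)
  }
  # depth 1 is a two-conv passthrough: no pooling anywhere
  g1 <- buildBaselineUnet(1, inputSize = 16, baseFilters = 2)
  kinds <- unlist(lapply(g1@nodes, function(n)
    vapply(n$ops, `[[`, character(1), "kind")))
  expect_false("pool" %in% kinds)
  expect_identical(min(inferShapes(g1)$height), 16L)
})

test_that("dilated U-Nets dilate exactly the requested top levels", {
  convDilations <- function(g, id) vapply(
    Filter(function(op) op$kind == "conv" && op$kernel[1] == 3L,
           g@nodes[[id]]$ops), `[[`, integer(1), "dilation")
  g1 <- buildDilatedUnet(4, 1, inputSize = 64, baseFilters = 2)
  expect_true(all(convDilations(g1, "Lay1") == 2L))
  expect_true(all(convDilations(g1, "Lay2") == 1L))
  expect_true(all(convDilations(g1, "Lay4") == 1L))
  g4 <- buildDilatedUnet(4, 4, inputSize = 64, baseFilters = 2)
  for (id in paste0("Lay", 1:4))
    expect_true(all(convDilations(g4, id) == 2L), info = id)
  expect_true(all(convDilations(g4, "Lay5") == 1L))  # expansive path untouched
  expect_error(buildDilatedUnet(4, 0, 64, 2), class = "eunetArgumentError")
  expect_error(buildDilatedUnet(4, 5, 64, 2), class = "eunetArgumentError")
})

test_that("incompatible input sizes are rejected naming the required multiple", {
  expect_error(buildBaselineUnet(5, inputSize = 40, baseFilters = 2),
               "multiple of 16", class = "eunetConfigError")
  expect_silent(g <- buildBaselineUnet(5, inputSize = 64, baseFilters = 2))
  # 48 = 3 * 16 is divisible through four poolings and therefore valid
  expect_silent(g <- buildBaselineUnet(5, inputSize = 48, baseFilters = 2))
  expect_error(buildLayerGraph("U_1(4-4)-U_2(4-4)", 100, 2),
               class = "eunetConfigError")
})

test_that("parallel branches split at the input and fuse at valley and output", {
  g <- buildLayerGraph("U_1(4)//U^1(4)", 64, 4)
  e <- g@edges
  expect_setequal(e$dst[e$kind == "branch_split"], c("Lay1_1", "Lay1^1"))
  # fusion points: both valleys into the valley merge, both branch outputs
  # into the output merge (first branch rides the forward edge)
  expect_setequal(e$src[e$dst == "MergeV1"], c("Lay4_1", "Lay4^1"))
  expect_setequal(e$src[e$dst == "MergeO1"], c("Lay7_1", "Lay7^1"))
  # the fused valley feeds both expansive paths
  expect_setequal(e$dst[e$src == "MergeV1" & e$kind == "forward"],
                  c("Lay5_1", "Lay5^1"))
  # each branch's skips stay within the branch
  expect_true(all(e$src[e$dst == "Lay7_1" & e$kind == "skip"] == "Lay1_1"))
  expect_true(all(e$src[e$dst == "Lay7^1" & e$kind == "skip"] == "Lay1^1"))
})

test_that("concat shape conflicts are reported with both source nodes", {
  g <- buildLayerGraph("U_1(3-3)", 32, 2)
  # sabotage: drop the upsample so the concat partners disagree spatially
  g@nodes[["Lay4"]]$ops <- Filter(function(op) op$kind != "upsample",
                                  g@nodes[["Lay4"]]$ops)
  expect_error(inferShapes(g), "Lay4", class = "eunetValidationError")
})

test_that("structural invariants hold on random specs", {
  set.seed(515)
  for (i in 1:25) {
    nt <- randomSpecString()
    g <- buildLayerGraph(nt, 64, 2)
    st <- inferShapes(g)
    # resolution conservation: output head at input resolution
    expect_identical(st$height[st$id == "Output"], 64L, info = nt)
    expect_identical(st$width[st$id == "Output"], 64L, info = nt)
    # skip symmetry: equal elevations and a shared owning U-structure
    e <- g@edges
    sk <- e[e$kind == "skip" & e$dst != "Output", ]
    for (r in seq_len(nrow(sk))) {
      a <- g@nodes[[sk$src[r]]]
      b <- g@nodes[[sk$dst[r]]]
      expect_identical(a$elevation, b$elevation, info = nt)
      expect_true(length(intersect(a$u_labels, b$u_labels)) > 0, info = nt)
    }
  }
})

test_that("total parameter count grows with width, length, and branching", {
  n <- function(nt, f) realizeModel(buildLayerGraph(nt, 32, f), 1)@parameterCount
  expect_lt(n("U_1(3-3)", 2), n("U_1(3-3)", 4))
  expect_lt(n("U_1(3-3)", 2), n("U_1(3-3)-U_2(3-3)", 2))
  expect_lt(n("U_1(3-3)", 2), n("U_1(3)//U^1(3)", 2))
})

test_that("graph export emits well-formed JSON and DOT", {
  g <- buildLayerGraph("U_1(2-2)", 16, 2)
  js <- jsonlite::fromJSON(graphToJSON(g))
  expect_identical(js$notation, "U_1(2-2)")
  expect_identical(nrow(js$edges), nrow(g@edges))
  dot <- graphToDOT(g)
  expect_identical(dot[1], "digraph eunet {")
  expect_identical(tail(dot, 1), "}")
})
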