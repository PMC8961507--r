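test_that("Dice loss matches direct arithmetic oracles", {
  # perfect overlap is exactly zero for any smoothing
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_identical(diceLoss(m, m, smoothing = 1), 0)
  expect_identical(diceLoss(m, m, smoothing = 1e-9), 0)
  # disjoint prediction approaches 1 as the smoothing vanishes
  z <- matrix(0, 4, 4); o <- matrix(1, 4, 4)
  expect_lt(abs(diceLoss(z, o, smoothing = 1e-12) - 1), 1e-12)
  # half-overlap on a 4x4 all-ones mask: 8 predicted ones, all correct:
  # 1 - 2*8 / (8 + 16) = 1/3
  pred <- matrix(0, 4, 4); pred[1:8] <- 1
  expect_equal(diceLoss(pred, o, smoothing = 0), 1 / 3)
  # contracts
  expect_error(diceLoss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "eunetArgumentError")
  expect_error(diceLoss(matrix(2, 2, 2), matrix(1, 2, 2)),
               class = "eunetArgumentError")
  # gradient agrees with finite differences away from the clamp
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  t0 <- matrix(rbinom(16, 1, 0.4), 4, 4)
  g <- eunet:::diceGrad(p, t0, 1)
  eps <- 1e-7
  for (i in c(1, 7, 16)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    expect_equal(g[i], (diceLoss(p1, t0, 1) - diceLoss(p2, t0, 1)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("realization is seed-deterministic and branch-distinct", {
  g <- buildLayerGraph("U_1(4)//U^1(4)", 32, 2)
  m1 <- realizeModel(g, 7)
  m2 <- realizeModel(g, 7)
  expect_identical(paramChecksum(m1), paramChecksum(m2))
  m3 <- realizeModel(g, 8)
  expect_false(identical(paramChecksum(m1), paramChecksum(m3)))
  # parallel branches draw from distinct streams under one master seed
  w1 <- m1@params[["Lay1_1:1"]]$W
  w2 <- m1@params[["Lay1^1:1"]]$W
  expect_identical(dim(w1), dim(w2))
  expect_false(identical(w1, w2))
})

test_that("the analytic parameter count matches a hand-summed schedule", {
  # independent tally for U_1(4-4)-U_2(4-4), f_d = 4, 1 input channel:
  # each row is (kernel, cin, cout); batch norm adds 2 * cout after every
  # 3x3/1x1 conv of the main blocks
  convs <- rbind(
    c(3, 1, 4),  c(3, 4, 4),                 # Lay1
    c(3, 4, 8),  c(3, 8, 8),                 # Lay2
    c(3, 8, 16), c(3, 16, 16),               # Lay3
    c(3, 16, 32), c(3, 32, 32),              # Lay4 (valley)
    c(2, 32, 16), c(3, 32, 16), c(3, 16, 16),  # Lay5 (up: halve, concat)
    c(2, 16, 8),  c(3, 16, 8),  c(3, 8, 8),    # Lay6
    c(2, 8, 4),   c(3, 8, 4),   c(3, 4, 4),    # Lay7 (peak)
    c(3, 4, 8),  c(3, 8, 8),                 # Lay8
    c(3, 8, 16), c(3, 16, 16),               # Lay9
    c(3, 16, 32), c(3, 32, 32),              # Lay10
    c(2, 32, 16), c(3, 32, 16), c(3, 16, 16),  # Lay11
    c(2, 16, 8),  c(3, 16, 8),  c(3, 8, 8),    # Lay12
    c(2, 8, 4),   c(3, 8, 4),   c(1, 4, 4),    # Lay13 (1x1 terminal conv)
    c(3, 8, 2),  c(1, 2, 1))                 # Output (peak concat: 4+4 in)
  wb <- sum(convs[, 1]^2 * convs[, 2] * convs[, 3] + convs[, 3])
  # BN follows every conv except the six 2x2 up-convs and the output head
  bnChannels <- convs[convs[, 1] != 2, 3]
  bnChannels <- bnChannels[seq_len(length(bnChannels) - 2)]  # no BN on head
  expected <- wb + sum(2 * bnChannels)
  m <- realizeModel(buildLayerGraph("U_1(4-4)-U_2(4-4)", 32, 4), 1)
  expect_identical(m@parameterCount, expected)
})

test_that("parameter counts equal an op-walk tally for the named variants", {
  for (f in c(2L, 4L)) {
    for (nt in unname(namedVariants)) {
      g <- buildLayerGraph(nt, 32, f)
      m <- realizeModel(g, 1)
      # independent tally from the shape table and the op schedules
      st <- inferShapes(g)
      tally <- 0
      outCh <- list()
      for (id in names(g@nodes)) {
        src <- eunet:::forwardSource(g, id)
        cur <- if (is.na(src)) g@inputChannels else outCh[[src]]
        for (op in g@nodes[[id]]$ops) {
          if (op$kind == "conv") {
            tally <- tally + op$kernel[1] * op$kernel[2] * cur *
              op$channels_out + op$channels_out
            cur <- op$channels_out
          } else if (op$kind == "batchnorm") {
            tally <- tally + 2 * cur
          } else if (op$kind == "concat") {
            srcs <- eunet:::concatSources(g, id, op$source)
            cur <- cur + sum(st$channels[match(srcs, st$id)])
          }
        }
        outCh[[id]] <- cur
      }
      expect_identical(m@parameterCount, tally, info = paste(nt, f))
    }
  }
})

test_that("training is reproducible, interruptible, and numerically sane", {
  ph <- toyCellSet()
  g <- buildLayerGraph("U_1(2-2)", 32, 2)

  # epochs = 0: empty trace, untouched weights
  m <- realizeModel(g, 3)
  before <- paramChecksum(m)
  r0 <- trainModel(m, ph, config = trainingConfig(seed = 3, epochs = 0))
  expect_identical(nrow(r0@trace), 0L)
  expect_identical(paramChecksum(m), before)

  # bitwise-identical traces from the same seed under deterministic mode
  r1 <- trainModel(realizeModel(g, 3), ph,
                   config = trainingConfig(seed = 3, epochs = 8))
  r2 <- trainModel(realizeModel(g, 3), ph,
                   config = trainingConfig(seed = 3, epochs = 8))
  expect_identical(r1@trace$train_loss, r2@trace$train_loss)
  expect_true(all(is.finite(r1@trace$train_loss)))

  # validation trace carries the four metrics
  rv <- trainModel(realizeModel(g, 3), ph[1:3], valSet = ph[4],
                   config = trainingConfig(seed = 3, epochs = 2, batchSize = 3))
  expect_true(all(c("val_loss", "val_accuracy", "val_miou") %in%
                  names(rv@trace)))
})

test_that("a small model memorizes the toy set and the loss never climbs for long", {
  ph <- toyCellSet()
  m <- realizeModel(buildLayerGraph("U_1(3-3)", 32, 4), 1)
  res <- trainModel(m, ph, config = overfitConfig(300))
  tr <- res@trace$train_loss
  expect_lte(tail(tr, 1), 0.1)  # smoke bound; the named variants are held
                                # to the strict 0.05 bar in the end-to-end suite
  # early epochs trend downward; no sustained increase over any 10-epoch run
  expect_lt(tr[min(10, length(tr))], tr[1])
  runs <- rle(diff(tr) > 0)
  expect_lt(max(c(0, runs$lengths[runs$values])), 10)
})

test_that("prediction respects the output range, padding, and zeroed head", {
  g <- buildLayerGraph("U_1(3-3)", 32, 2)
  m <- realizeModel(g, 5)
  pm <- predictModel(m, matrix(runif(32 * 32), 32))
  expect_identical(dim(pm), c(32L, 32L))
  expect_true(all(pm >= 0 & pm <= 1))
  # odd-sized input: reflect-pad then crop back
  odd <- matrix(runif(30 * 27), 30, 27)
  expect_error(predictModel(m, odd), class = "eunetArgumentError")
  pmo <- predictModel(m, odd, pad = "reflect")
  expect_identical(dim(pmo), c(30L, 27L))
  # zero the output head: sigmoid(0) = 0.5 everywhere
  headConvs <- grep("^Output:", ls(m@params), value = TRUE)
  for (id in headConvs) {
    p <- m@params[[id]]
    p$W[] <- 0; p$b[] <- 0
    m@params[[id]] <- p
  }
  expect_true(all(predictModel(m, matrix(runif(32 * 32), 32)) == 0.5))
  # channel mismatch is a contract violation
  expect_error(predictModel(m, array(0.5, c(32, 32, 3))),
               class = "eunetArgumentError")
})

test_that("checkpoints round-trip through save/load with fingerprint checking", {
  ph <- toyCellSet()
  g <- buildLayerGraph("U_1(2-2)", 32, 2)
  m <- realizeModel(g, 9)
  trainModel(m, ph, config = trainingConfig(seed = 9, epochs = 3))
  path <- tempfile()
  saveModel(m, path)
  m2 <- loadModel(path, g)
  img <- ph[[1]]$image
  expect_identical(predictModel(m2, img), predictModel(m, img))
  # wrong graph: fingerprint mismatch
  expect_error(loadModel(path, buildLayerGraph("U_1(3-3)", 32, 2)),
               class = "eunetConfigError")
})
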