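# Shared fixtures, generated in code at load time (all seeded).

# tiny 4-image memorization set used by the training tests
toyCellSet <- function() generatePhantoms("cell", count = 4, size = 32, seed = 11)

# the five named architecture variants at toy scale
namedVariants <- c(
  "SHP-EUNet"  = "U_1(4-4)-U_2(4-4)",
  "DHP-EUNet"  = "U_1(4-4)-U_2(4-4)-U_3(4-4)",
  "THP-EUNet"  = "U_1(4-4)-U_2(4-4)-U_3(4-4)-U_4(4-4)",
  "U*UNet"     = "U_1(4)//U^1(4)",
  "U*U*UNet"   = "U_1(4)//U^1(4)//U^11(4)")

# toy-scale memorization protocol shared by the training/overfit tests:
# one image per optimizer step, Adam at 3e-3, early stop at the 0.05 bar
overfitConfig <- function(epochs = 500L)
  trainingConfig(seed = 1, epochs = epochs, batchSize = 1,
                 learningRate = 3e-3, targetLoss = 0.05)

# random elevation-balanced architecture specs (peaks stay at or one level
# below the input; every walk returns to elevation 0)
randomSpecString <- function() {
  nseg <- sample(1:4, 1)
  e <- 0L
  parts <- character(nseg)
  for (s in seq_len(nseg)) {
    delta <- if (s == nseg) -e else {
      choices <- intersect(c(-1L, 0L, 1L), seq(-1L - e, -e))  # keep e in {0,-1}
      sample(choices, 1)
    }
    d <- sample(2:5, 1)
    # a non-final segment must end above its valley to host the next pool
    if (s < nseg && d + delta < 2L) d <- d + 1L
    u <- d + delta
    nb <- sample(1:3, 1)
    term <- vapply(seq_len(nb), function(j)
      sprintf("U%s(%d-%d)",
              if (j == 1) sprintf("_%d", s) else
                sprintf("^%s", strrep(as.character(s), j - 1)), d, u),
      character(1))
    parts[s] <- paste(term, collapse = "//")
    e <- e + delta
  }
  paste(parts, collapse = "-")
}

# independent per-pixel confusion tally (brute-force oracle)
bruteConfusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

paramChecksum <- function(model) {
  ids <- sort(ls(model@params))
  sum(vapply(ids, function(id)
    sum(vapply(model@params[[id]], function(p) sum(p * seq_along(p)),
               numeric(1))), numeric(1)))
}
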