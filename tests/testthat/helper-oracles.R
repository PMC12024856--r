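# Independent oracles used across the suite.

# Brute-force "same"-padded 2-D convolution on a (C,H,W,N) array.
ref_conv2d <- function(x, w, b, dil = 1L) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  wd <- dim(w); Co <- wd[1]; k <- wd[3]; p <- dil * (k - 1) / 2
  y <- array(0, c(Co, H, W, N))
  for (n in seq_len(N)) for (j in seq_len(W)) for (i in seq_len(H)) {
    for (o in seq_len(Co)) {
      acc <- b[o]
      for (v in seq_len(k)) for (u in seq_len(k)) {
        ii <- i + (u - 1) * dil - p
        jj <- j + (v - 1) * dil - p
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + sum(w[o, , u, v] * x[, ii, jj, n])
        }
      }
      y[o, i, j, n] <- acc
    }
  }
  y
}

# Brute-force confusion counts by explicit pixel enumeration.
ref_confusion <- function(pred, target) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && target[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && target[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && target[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# 8-connected components of a binary matrix (BFS flood fill).
n_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  ncomp <- 0L
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- (cur - 1L) %% H + 1L
      cj <- (cur - 1L) %/% H + 1L
      for (dj in -1:1) for (di in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W) {
          id <- ni + (nj - 1L) * H
          if (mask[id] == 1 && lab[id] == 0L) {
            lab[id] <- ncomp
            queue <- c(queue, id)
          }
        }
      }
    }
  }
  ncomp
}

# Soft Dice score of a probability map against a binary mask.
soft_dice <- function(prob, mask) 1 - dice_loss(prob, mask)

# A small model configuration that keeps property tests fast while
# exercising every architectural component.
tiny_config <- function(seed = 7L, ...) {
  frnet_config(trunk_channels = 6L, num_stages = 2L, expansion_width = 9L,
               fc_hidden = 11L, spatial_mid_channels = 7L, eag_width = 5L,
               seed = seed, ...)
}
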