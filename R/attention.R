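# ---------------------------------------------------------------------------
# DWAM hybrid attention and EFF feature fusion.
#
# DWAM: three multi-scale depthwise-separable branches feed a channel
# self-attention block (global average pooling -> FC -> two sigmoid heads
# giving per-channel gates a, a') and a spatial self-attention block (two
# sigmoid maps beta, beta' that cross-calibrate the fused features).
# EFF: an additive attention gate (EAG) modulates the trunk skip, then an
# efficient channel-attention gate (1-D conv over the pooled channel
# descriptor) and a spatial gate (7x7 conv over channel mean/max maps).
# ---------------------------------------------------------------------------

# broadcast helpers ----------------------------------------------------------

# (C,N) -> (C,H,W,N)
expand_cn <- function(a, H, W) {
  C <- nrow(a); N <- ncol(a)
  array(a[, rep(seq_len(N), each = H * W), drop = FALSE], dim = c(C, H, W, N))
}

# (C,H,W,N) -> (C,N), summing over space
reduce_hw <- function(x) {
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(C, HW * N)
  vapply(seq_len(N),
         function(n) rowSums(xm[, ((n - 1) * HW + 1):(n * HW), drop = FALSE]),
         numeric(C))
}

# (1,H,W,N) -> (C,H,W,N)
expand_sp <- function(b, C) {
  d <- dim(b)
  array(rep(as.vector(b), each = C), dim = c(C, d[2], d[3], d[4]))
}

# (C,H,W,N) -> (1,H,W,N), summing over channels
reduce_ch <- function(x) {
  d <- dim(x)
  y <- colSums(matrix(x, nrow = d[1]))
  array(y, dim = c(1L, d[2], d[3], d[4]))
}

#' Global average pooling over space
#' @param x `(C, H, W, N)` array
#' @return `(C, N)` matrix of per-channel spatial means
#' @export
global_avg_pool <- function(x) {
  d <- dim(x)
  reduce_hw(x) / (d[2] * d[3])
}

# ---------------------------------------------------------------------------
# DWAM
# ---------------------------------------------------------------------------

#' DWAM configuration
#'
#' @param channels trunk width the module attaches to
#' @param dilation dilation of the third multi-scale branch (default 3, so a
#'   3x3 kernel has an effective receptive field of 7)
#' @param recursion_R recursion depth of the 3x3 and 5x5 branches
#' @param fc_hidden width of the shared FC layer of the channel block
#'   (default 512, an inverted-bottleneck expansion; this is the module's
#'   main capacity knob and lives on pooled vectors, so it is cheap at any
#'   image size)
#' @param spatial_mid_channels hidden width of the spatial block's 1x1
#'   convolutions (default 96)
#' @param final_kernel kernel of the closing fusion convolution
#' @export
dwam_config <- function(channels = 32L, dilation = 3L, recursion_R = 2L,
                        fc_hidden = 512L, spatial_mid_channels = 96L,
                        final_kernel = 1L) {
  stopifnot(dilation >= 1, channels > 0, fc_hidden > 0,
            spatial_mid_channels > 0, final_kernel %% 2 == 1)
  list(channels = as.integer(channels), dilation = as.integer(dilation),
       recursion_R = as.integer(recursion_R), fc_hidden = as.integer(fc_hidden),
       spatial_mid_channels = as.integer(spatial_mid_channels),
       final_kernel = as.integer(final_kernel))
}

#' Build the DWAM hybrid attention module
#' @param cfg a [dwam_config()]
#' @export
new_dwam <- function(cfg = dwam_config()) {
  C <- cfg$channels; M <- cfg$spatial_mid_channels; Fh <- cfg$fc_hidden
  new_module("dwam",
    children = list(
      branch3 = new_seq(conv = new_ds_conv(C, C, 3L, 1L, cfg$recursion_R),
                        bn = new_bn2d(C), relu = new_act("relu")),
      branch5 = new_seq(conv = new_ds_conv(C, C, 5L, 1L, cfg$recursion_R),
                        bn = new_bn2d(C), relu = new_act("relu")),
      branchD = new_seq(conv = new_ds_conv(C, C, 3L, cfg$dilation, 1L),
                        bn = new_bn2d(C), relu = new_act("relu")),
      ch_fc1 = new_linear(C, Fh),
      ch_bn = new_bn1d(Fh),
      ch_head_a = new_linear(Fh, C),
      ch_head_a2 = new_linear(Fh, C),
      sp_s = new_seq(conv = new_conv2d(C, M, 1L), bn = new_bn2d(M),
                     relu = new_act("relu")),
      sp_c = new_seq(conv = new_conv2d(C, M, 1L), bn = new_bn2d(M),
                     relu = new_act("relu")),
      beta1 = new_seq(conv = new_conv2d(M, 1L, 1L), bn = new_bn2d(1L),
                      relu = new_act("relu")),
      beta2 = new_seq(conv = new_conv2d(M, 1L, 1L), bn = new_bn2d(1L),
                      relu = new_act("relu")),
      final = new_conv2d(M, C, cfg$final_kernel)
    ),
    extra = list(cfg = cfg))
}

#' Multi-scale branches of DWAM
#'
#' Applies the three parallel depthwise-separable branches (recursive 3x3,
#' recursive 5x5, dilated 3x3), each followed by batch norm and ReLU.
#' Inference mode; used for inspection and testing.
#'
#' @param mod a DWAM module
#' @param x `(C, H, W, N)` input
#' @return list with `F3`, `F5`, `FD`
#' @export
multiscale_branches <- function(mod, x) {
  list(F3 = fr_forward(mod$children$branch3, x)$out,
       F5 = fr_forward(mod$children$branch5, x)$out,
       FD = fr_forward(mod$children$branchD, x)$out)
}

#' Channel self-attention block of DWAM
#'
#' `FG = GAP(F5 + FD)`; `FfG = ReLU(BN(FC(FG)))`; two parallel FC heads with
#' sigmoid give the channel gates `a` and `a'`; `F_CD = a * FD`,
#' `F_C5 = a' * F5` (per-channel broadcast).  Inference mode.
#'
#' @param mod a DWAM module
#' @param F5,FD same-shape branch outputs
#' @return list with `F_CD`, `F_C5`, `F_C = F_CD + F_C5`, and `state`
#'   (vectors `FG`, `FfG`, `a`, `a_prime`)
#' @export
channel_self_attention <- function(mod, F5, FD) {
  if (!identical(dim(F5), dim(FD))) stop("channel attention: shape mismatch")
  d <- dim(F5)
  FG <- global_avg_pool(F5 + FD)
  FfG <- pmax(fr_forward(mod$children$ch_bn,
                         fr_forward(mod$children$ch_fc1, FG)$out)$out, 0)
  a <- plogis(fr_forward(mod$children$ch_head_a, FfG)$out)
  a2 <- plogis(fr_forward(mod$children$ch_head_a2, FfG)$out)
  F_CD <- expand_cn(a, d[2], d[3]) * FD
  F_C5 <- expand_cn(a2, d[2], d[3]) * F5
  list(F_CD = F_CD, F_C5 = F_C5, F_C = F_CD + F_C5,
       state = list(FG = FG, FfG = FfG, a = a, a_prime = a2))
}

#' Spatial self-attention block of DWAM
#'
#' Projects `F3` and the channel-calibrated sum `F_C` to the hidden width,
#' forms two sigmoid spatial maps `beta`, `beta'` from their ReLU-ed sum,
#' cross-calibrates, and fuses with the closing convolution.  Inference mode.
#'
#' @param mod a DWAM module
#' @param F3 output of the 3x3 branch
#' @param F_C output of the channel self-attention block
#' @return list with `out` and `state` (maps `beta`, `beta_prime`)
#' @export
spatial_self_attention <- function(mod, F3, F_C) {
  if (!identical(dim(F3), dim(F_C))) stop("spatial attention: shape mismatch")
  Fs1 <- fr_forward(mod$children$sp_s, F3)$out
  FCs1 <- fr_forward(mod$children$sp_c, F_C)$out
  s <- pmax(Fs1 + FCs1, 0)
  beta <- plogis(fr_forward(mod$children$beta1, s)$out)
  beta2 <- plogis(fr_forward(mod$children$beta2, s)$out)
  M <- dim(Fs1)[1]
  fuse_in <- expand_sp(beta, M) * FCs1 + expand_sp(beta2, M) * Fs1
  out <- fr_forward(mod$children$final, fuse_in)$out
  list(out = out, state = list(beta = beta, beta_prime = beta2))
}

#' @export
fr_forward.fr_dwam <- function(mod, x, training = FALSE) {
  ch <- mod$children
  d <- dim(x); H <- d[2]; W <- d[3]; HW <- H * W
  r3 <- fr_forward(ch$branch3, x, training); F3 <- r3$out
  r5 <- fr_forward(ch$branch5, x, training); F5 <- r5$out
  rD <- fr_forward(ch$branchD, x, training); FD <- rD$out

  FG <- global_avg_pool(F5 + FD)
  rf1 <- fr_forward(ch$ch_fc1, FG, training)
  rbn <- fr_forward(ch$ch_bn, rf1$out, training)
  FfG <- pmax(rbn$out, 0)
  rha <- fr_forward(ch$ch_head_a, FfG, training)
  rha2 <- fr_forward(ch$ch_head_a2, FfG, training)
  a <- plogis(rha$out); a2 <- plogis(rha2$out)
  FCD <- expand_cn(a, H, W) * FD
  FC5 <- expand_cn(a2, H, W) * F5
  FC <- FCD + FC5

  rs <- fr_forward(ch$sp_s, F3, training); Fs1 <- rs$out
  rc <- fr_forward(ch$sp_c, FC, training); FCs1 <- rc$out
  s <- pmax(Fs1 + FCs1, 0)
  rb1 <- fr_forward(ch$beta1, s, training)
  rb2 <- fr_forward(ch$beta2, s, training)
  beta <- plogis(rb1$out); beta2 <- plogis(rb2$out)
  M <- dim(Fs1)[1]
  fuse_in <- expand_sp(beta, M) * FCs1 + expand_sp(beta2, M) * Fs1
  rf <- fr_forward(ch$final, fuse_in, training)

  cache <- if (training) {
    list(b3 = r3$cache, b5 = r5$cache, bD = rD$cache,
         fc1 = rf1$cache, bn = rbn$cache, bnout = rbn$out,
         ha = rha$cache, ha2 = rha2$cache, a = a, a2 = a2,
         F3 = F3, F5 = F5, FD = FD,
         sp_s = rs$cache, sp_c = rc$cache, Fs1 = Fs1, FCs1 = FCs1,
         smask = (s > 0), b1 = rb1$cache, b2 = rb2$cache,
         beta = beta, beta2 = beta2, final = rf$cache,
         H = H, W = W)
  }
  list(out = rf$out, cache = cache)
}

#' @export
fr_backward.fr_dwam <- function(mod, cache, gy) {
  ch <- mod$children
  H <- cache$H; W <- cache$W; HW <- H * W
  M <- dim(cache$Fs1)[1]

  gfuse <- fr_backward(ch$final, cache$final, gy)
  bexp <- expand_sp(cache$beta, M)
  b2exp <- expand_sp(cache$beta2, M)
  gbeta <- reduce_ch(gfuse * cache$FCs1)
  gbeta2 <- reduce_ch(gfuse * cache$Fs1)
  gFCs1 <- bexp * gfuse
  gFs1 <- b2exp * gfuse

  gb1 <- gbeta * cache$beta * (1 - cache$beta)
  gb2 <- gbeta2 * cache$beta2 * (1 - cache$beta2)
  gs <- fr_backward(ch$beta1, cache$b1, gb1) +
    fr_backward(ch$beta2, cache$b2, gb2)
  gs <- gs * cache$smask
  gFs1 <- gFs1 + gs
  gFCs1 <- gFCs1 + gs

  gF3 <- fr_backward(ch$sp_s, cache$sp_s, gFs1)
  gFC <- fr_backward(ch$sp_c, cache$sp_c, gFCs1)

  ga <- reduce_hw(gFC * cache$FD)
  ga2 <- reduce_hw(gFC * cache$F5)
  gFD <- expand_cn(cache$a, H, W) * gFC
  gF5 <- expand_cn(cache$a2, H, W) * gFC

  gha <- ga * cache$a * (1 - cache$a)
  gha2 <- ga2 * cache$a2 * (1 - cache$a2)
  gFfG <- fr_backward(ch$ch_head_a, cache$ha, gha) +
    fr_backward(ch$ch_head_a2, cache$ha2, gha2)
  gFfG <- gFfG * (cache$bnout > 0)
  gfc1 <- fr_backward(ch$ch_bn, cache$bn, gFfG)
  gFG <- fr_backward(ch$ch_fc1, cache$fc1, gfc1)

  gsum <- expand_cn(as.matrix(gFG), H, W) / HW
  gF5 <- gF5 + gsum
  gFD <- gFD + gsum

  fr_backward(ch$branch3, cache$b3, gF3) +
    fr_backward(ch$branch5, cache$b5, gF5) +
    fr_backward(ch$branchD, cache$bD, gFD)
}

# ---------------------------------------------------------------------------
# EFF fusion
# ---------------------------------------------------------------------------

#' Build the EFF feature-fusion stage
#'
#' Fuses the attention output with the trunk skip: an additive attention
#' gate (EAG) modulates the skip before summation, an efficient channel
#' attention (ECA: 1-D conv of kernel 3 over the pooled channel descriptor,
#' no bias) gates channels, and a spatial attention (SA: 7x7 conv over the
#' channel-mean and channel-max maps) gates positions.
#'
#' @param channels trunk width
#' @param eag_width intermediate width of the additive gate (default 64)
#' @export
new_eff <- function(channels = 32L, eag_width = 64L) {
  new_module("eff",
    par = list(eca_w = kaiming_uniform(3L, 3)),
    children = list(
      eag_g = new_conv2d(channels, eag_width, 1L),
      eag_x = new_conv2d(channels, eag_width, 1L),
      eag_psi = new_conv2d(eag_width, 1L, 1L),
      sa_conv = new_conv2d(2L, 1L, 7L)
    ),
    extra = list(channels = channels, eag_width = eag_width))
}

# 1-D conv (kernel 3, zero padding, no bias) over the channel dimension of a
# (C, N) descriptor.
eca_conv1d <- function(d, w) {
  C <- nrow(d)
  up <- rbind(0, d[-C, , drop = FALSE])    # d[c-1]
  dn <- rbind(d[-1, , drop = FALSE], 0)    # d[c+1]
  w[1] * up + w[2] * d + w[3] * dn
}

eca_conv1d_bwd <- function(d, w, g) {
  C <- nrow(d)
  up <- rbind(0, d[-C, , drop = FALSE])
  dn <- rbind(d[-1, , drop = FALSE], 0)
  gup <- rbind(0, g[-C, , drop = FALSE])
  gdn <- rbind(g[-1, , drop = FALSE], 0)
  list(gw = c(sum(g * up), sum(g * d), sum(g * dn)),
       gd = w[1] * gdn + w[2] * g + w[3] * gup)
}

# channel-max map with argmax bookkeeping; x is (C,H,W,N)
channel_max <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  tm <- t(xm)
  idx <- max.col(tm, ties.method = "first")
  val <- tm[cbind(seq_along(idx), idx)]
  list(map = array(val, dim = c(1L, d[2], d[3], d[4])), idx = idx)
}

#' @export
fr_forward.fr_eff <- function(mod, x, training = FALSE) {
  x_att <- x$att; x_skip <- x$skip
  if (!identical(dim(x_att), dim(x_skip))) stop("eff: shape mismatch")
  ch <- mod$children
  d <- dim(x_att); C <- d[1]; H <- d[2]; W <- d[3]; HW <- H * W

  rg <- fr_forward(ch$eag_g, x_att, training)
  rx <- fr_forward(ch$eag_x, x_skip, training)
  q_pre <- rg$out + rx$out
  q <- pmax(q_pre, 0)
  rpsi <- fr_forward(ch$eag_psi, q, training)
  gate <- plogis(rpsi$out)                       # (1,H,W,N)
  skip_g <- expand_sp(gate, C) * x_skip
  fused <- x_att + skip_g

  desc <- global_avg_pool(fused)                 # (C,N)
  e_pre <- eca_conv1d(desc, mod$par$eca_w)
  e <- plogis(e_pre)                             # (C,N) channel gate
  fused2 <- expand_cn(e, H, W) * fused

  mean_map <- reduce_ch(fused2) / C
  mx <- channel_max(fused2)
  stack <- array(0, dim = c(2L, H, W, d[4]))
  stack[1, , , ] <- mean_map
  stack[2, , , ] <- mx$map
  rsa <- fr_forward(ch$sa_conv, stack, training)
  m <- plogis(rsa$out)                           # (1,H,W,N) spatial gate
  out <- expand_sp(m, C) * fused2

  cache <- if (training) {
    list(x_att = x_att, x_skip = x_skip, g = rg$cache, x = rx$cache,
         qmask = (q_pre > 0), psi = rpsi$cache, gate = gate,
         fused = fused, desc = desc, e = e, fused2 = fused2,
         sa = rsa$cache, m = m, maxidx = mx$idx, d = d)
  }
  list(out = out, cache = cache)
}

#' @export
fr_backward.fr_eff <- function(mod, cache, gy) {
  ch <- mod$children
  d <- cache$d; C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]; HW <- H * W

  gm <- reduce_ch(gy * cache$fused2)
  gfused2 <- expand_sp(cache$m, C) * gy
  gm_pre <- gm * cache$m * (1 - cache$m)
  gstack <- fr_backward(ch$sa_conv, cache$sa, gm_pre)
  gmean <- array(gstack[1, , , ], dim = c(1L, H, W, N))
  gmax <- gstack[2, , , ]
  gfused2 <- gfused2 + expand_sp(gmean, C) / C
  gm2 <- matrix(gfused2, nrow = C)
  gm2[cbind(cache$maxidx, seq_len(HW * N))] <-
    gm2[cbind(cache$maxidx, seq_len(HW * N))] + as.vector(gmax)
  gfused2 <- array(gm2, dim = d)

  ge <- reduce_hw(gfused2 * cache$fused)
  gfused <- expand_cn(cache$e, H, W) * gfused2
  ge_pre <- ge * cache$e * (1 - cache$e)
  eb <- eca_conv1d_bwd(cache$desc, mod$par$eca_w, ge_pre)
  acc_grad(mod, "eca_w", eb$gw)
  gfused <- gfused + expand_cn(eb$gd, H, W) / HW

  gx_att <- gfused
  ggate <- reduce_ch(gfused * cache$x_skip)
  gx_skip <- expand_sp(cache$gate, C) * gfused
  gpsi <- ggate * cache$gate * (1 - cache$gate)
  gq <- fr_backward(ch$eag_psi, cache$psi, gpsi)
  gq <- gq * cache$qmask
  gx_att <- gx_att + fr_backward(ch$eag_g, cache$g, gq)
  gx_skip <- gx_skip + fr_backward(ch$eag_x, cache$x, gq)
  list(att = gx_att, skip = gx_skip)
}

#' Fuse an attention output with a trunk skip via EFF
#'
#' Inference-mode convenience wrapper around the EFF module.
#'
#' @param mod an EFF module
#' @param x_att attention-stage output `(C, H, W, N)`
#' @param x_skip trunk output of the same shape
#' @export
eff_fuse <- function(mod, x_att, x_skip) {
  fr_forward(mod, list(att = x_att, skip = x_skip))$out
}
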