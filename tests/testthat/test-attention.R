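dw_cfg <- dwam_config(channels = 5L, fc_hidden = 8L,
                      spatial_mid_channels = 6L)

test_that("multi-scale branches preserve shape and are non-negative after ReLU", {
  set.seed(21)
  dw <- new_dwam(dw_cfg)
  x <- array(rnorm(5 * 12 * 10), c(5, 12, 10, 1))
  br <- multiscale_branches(dw, x)
  for (f in br) {
    expect_identical(dim(f), dim(x))
    expect_true(all(f >= 0))
  }
})

test_that("dilated branch has effective receptive field 7 at k=3, d=3", {
  # k + (k-1)(d-1): an impulse must not influence pixels beyond offset 3
  expect_equal(3 + (3 - 1) * (3 - 1), 7)
  dwc <- new_dwconv2d(1L, 3L, dilation = 3L)
  dwc$par$w[] <- 1; dwc$par$b[] <- 0
  x <- array(0, c(1, 15, 15, 1))
  x[1, 8, 8, 1] <- 1
  y <- fr_forward(dwc, x)$out
  on <- which(y != 0, arr.ind = TRUE)
  expect_equal(max(abs(on[, 2] - 8)), 3)   # taps exactly at offsets {-3, 0, 3}
  expect_equal(max(abs(on[, 3] - 8)), 3)
})

test_that("channel attention gates lie in (0,1) and calibrate the branches", {
  set.seed(22)
  dw <- new_dwam(dw_cfg)
  F5 <- array(rnorm(5 * 9 * 9 * 2), c(5, 9, 9, 2))
  FD <- array(rnorm(5 * 9 * 9 * 2), c(5, 9, 9, 2))
  ca <- channel_self_attention(dw, F5, FD)
  expect_true(all(ca$state$a > 0 & ca$state$a < 1))
  expect_true(all(ca$state$a_prime > 0 & ca$state$a_prime < 1))
  # FG is the per-channel spatial mean of F5 + FD
  expect_equal(ca$state$FG, global_avg_pool(F5 + FD), tolerance = 1e-12)
  # per-channel broadcast: F_CD / FD recovers a on every pixel
  rat <- ca$F_CD / FD
  expect_equal(rat[, 1, 1, 1], unname(ca$state$a[, 1]), tolerance = 1e-12)
  expect_equal(ca$F_C, ca$F_CD + ca$F_C5, tolerance = 1e-12)
  # a gate of all ones would leave FD untouched (identity calibration)
  ones <- matrix(1, 5, 2)
  expect_equal(frnetv2:::expand_cn(ones, 9, 9) * FD, FD)
  expect_error(channel_self_attention(dw, F5, FD[, 1:8, , , drop = FALSE]),
               "mismatch")
})

test_that("zeroed channel block yields gates of exactly 0.5", {
  # hand trace with all weights/biases zero: FG -> FC -> BN -> ReLU all zero,
  # heads output zero, sigmoid(0) = 0.5
  dw <- new_dwam(dw_cfg)
  for (w in frnetv2:::fr_walk(dw)) w$mod$par[[w$name]][] <- 0
  F5 <- array(rnorm(5 * 6 * 6), c(5, 6, 6, 1))
  FD <- array(rnorm(5 * 6 * 6), c(5, 6, 6, 1))
  ca <- channel_self_attention(dw, F5, FD)
  expect_equal(unname(as.vector(ca$state$a)), rep(0.5, 5))
  expect_equal(unname(as.vector(ca$state$a_prime)), rep(0.5, 5))
  expect_equal(ca$F_CD, 0.5 * FD, tolerance = 1e-12)
})

test_that("GAP is invariant to permutations of spatial positions", {
  set.seed(23)
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  g1 <- global_avg_pool(x)
  perm <- sample(36)
  xp <- x
  for (n in 1:2) {
    xm <- matrix(x[, , , n], nrow = 4)
    xp[, , , n] <- array(xm[, perm], c(4, 6, 6))
  }
  expect_equal(global_avg_pool(xp), g1, tolerance = 1e-12)
})

test_that("spatial attention maps are bounded and shapes are preserved", {
  set.seed(24)
  dw <- new_dwam(dw_cfg)
  x <- array(rnorm(5 * 11 * 8), c(5, 11, 8, 1))
  br <- multiscale_branches(dw, x)
  ca <- channel_self_attention(dw, br$F5, br$FD)
  sp <- spatial_self_attention(dw, br$F3, ca$F_C)
  expect_identical(dim(sp$out), dim(x))
  expect_true(all(sp$state$beta > 0 & sp$state$beta < 1))
  expect_true(all(sp$state$beta_prime > 0 & sp$state$beta_prime < 1))
  expect_identical(dim(sp$state$beta), c(1L, 11L, 8L, 1L))
  # composition through the module agrees with the three-step trace
  full <- fr_forward(dw, x)$out
  expect_equal(full, sp$out, tolerance = 1e-10)
})

test_that("DWAM is deterministic and preserves shape", {
  set.seed(25)
  dw <- new_dwam(dw_cfg)
  x <- array(rnorm(5 * 10 * 14), c(5, 10, 14, 1))
  y1 <- fr_forward(dw, x)$out
  y2 <- fr_forward(dw, x)$out
  expect_identical(y1, y2)
  expect_identical(dim(y1), dim(x))
})

test_that("recursion depth changes DWAM outputs but never its parameter count", {
  base <- dwam_config(channels = 5L, fc_hidden = 8L, spatial_mid_channels = 6L,
                      recursion_R = 1L)
  rec <- dwam_config(channels = 5L, fc_hidden = 8L, spatial_mid_channels = 6L,
                     recursion_R = 2L)
  set.seed(26); d1 <- new_dwam(base)
  set.seed(26); d2 <- new_dwam(rec)
  expect_identical(count_parameters(d1)$total, count_parameters(d2)$total)
  x <- array(rnorm(5 * 8 * 8), c(5, 8, 8, 1))
  expect_gt(max(abs(fr_forward(d1, x)$out - fr_forward(d2, x)$out)), 0)
})

test_that("EFF fusion preserves shape and its gates are bounded", {
  set.seed(27)
  eff <- new_eff(5L, eag_width = 4L)
  a <- array(rnorm(5 * 9 * 9 * 2), c(5, 9, 9, 2))
  s <- array(rnorm(5 * 9 * 9 * 2), c(5, 9, 9, 2))
  out <- eff_fuse(eff, a, s)
  expect_identical(dim(out), dim(a))
  expect_error(eff_fuse(eff, a, s[, 1:8, , , drop = FALSE]), "mismatch")
})

test_that("EFF with zeroed parameters follows the hand-computed 0.5-gate trace", {
  eff <- new_eff(3L, eag_width = 4L)
  for (w in frnetv2:::fr_walk(eff)) w$mod$par[[w$name]][] <- 0
  eff$par$eca_w[] <- 0
  set.seed(28)
  a <- array(rnorm(3 * 7 * 7), c(3, 7, 7, 1))
  s <- array(rnorm(3 * 7 * 7), c(3, 7, 7, 1))
  # all gates are sigmoid(0) = 0.5: out = 0.5 * 0.5 * (a + 0.5 * s)
  expect_equal(eff_fuse(eff, a, s), 0.25 * (a + 0.5 * s), tolerance = 1e-12)
})

test_that("attention stage backward matches numeric gradients", {
  set.seed(29)
  dw <- new_dwam(dwam_config(channels = 3L, fc_hidden = 5L,
                             spatial_mid_channels = 4L))
  x <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  fwd <- fr_forward(dw, x, training = TRUE)
  r <- array(rnorm(length(fwd$out)), dim(fwd$out))
  fr_zero_grads(dw)
  gx <- fr_backward(dw, fwd$cache, r)
  state0 <- fr_state_dict(dw)
  loss <- function() {
    fr_load_state(dw, state0)
    sum(fr_forward(dw, x, training = TRUE)$out * r)
  }
  walk <- frnetv2:::fr_walk(dw)
  for (w in walk[sample(length(walk), 8)]) {
    ii <- sample(length(w$mod$par[[w$name]]), 1)
    eps <- 1e-5
    orig <- state0$par[[w$path]][ii]
    state0$par[[w$path]][ii] <- orig + eps; fp <- loss()
    state0$par[[w$path]][ii] <- orig - eps; fm <- loss()
    state0$par[[w$path]][ii] <- orig
    expect_equal(w$mod$grd[[w$name]][ii], (fp - fm) / (2 * eps),
                 tolerance = 2e-3, label = w$path)
  }
})
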