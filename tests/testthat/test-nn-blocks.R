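test_that("convolution layers match the brute-force oracle", {
  set.seed(1)
  cases <- list(c(3, 4, 3, 1), c(2, 5, 1, 1), c(3, 3, 3, 3), c(1, 2, 7, 1))
  for (cs in cases) {
    ci <- cs[1]; co <- cs[2]; k <- cs[3]; dil <- cs[4]
    x <- array(rnorm(ci * 6 * 7 * 2), c(ci, 6, 7, 2))
    conv <- new_conv2d(ci, co, k, dil)
    got <- fr_forward(conv, x)$out
    want <- ref_conv2d(x, conv$par$w, conv$par$b, dil)
    expect_equal(got, want, tolerance = 1e-12)
    expect_identical(dim(got), c(as.integer(co), 6L, 7L, 2L))  # same padding
  }
})

test_that("depthwise-separable conv has the closed-form parameter count", {
  # 32 -> 32, k = 7: 32*49 + 32 depthwise plus 32*32 + 32 pointwise
  ds <- new_ds_conv(32L, 32L, 7L)
  expect_identical(count_parameters(ds)$total, 32L * 49L + 32L + 32L * 32L + 32L)
  expect_identical(count_parameters(ds)$total, 2656L)

  # formula C_in*k^2 + C_in + C_in*C_out + C_out for random specs
  set.seed(42)
  for (i in 1:20) {
    ci <- sample(1:8, 1); co <- sample(1:8, 1); k <- sample(c(1, 3, 5, 7), 1)
    ds <- new_ds_conv(ci, co, k)
    expect_identical(count_parameters(ds)$total,
                     as.integer(ci * k^2 + ci + ci * co + co))
  }

  # single standard 3x3 conv 1 -> 32 with bias
  expect_identical(count_parameters(new_conv2d(1L, 32L, 3L))$total, 320L)
})

test_that("dilated depthwise-separable conv preserves shape and zero maps to zero", {
  set.seed(2)
  x <- array(rnorm(4 * 11 * 13), c(4, 11, 13, 1))
  ds <- new_ds_conv(4L, 4L, 3L, dilation = 3L)  # effective receptive field 7
  y <- fr_forward(ds, x)$out
  expect_identical(dim(y), dim(x))
  # zero input with zero biases -> zero output (linearity)
  ds$par <- lapply(ds$par, function(p) p)  # leaf module has no own params
  for (w in frnetv2:::fr_walk(ds)) {
    if (w$name == "b") w$mod$par$b[] <- 0
  }
  expect_equal(max(abs(fr_forward(ds, x * 0)$out)), 0)
})

test_that("channel mismatch and even kernels are rejected", {
  x <- array(0, c(3, 8, 8, 1))
  conv <- new_conv2d(4L, 4L, 3L)
  expect_error(fr_forward(conv, x), "channels")
  expect_error(new_conv2d(3L, 4L, 4L), "odd")
  expect_error(new_dwconv2d(3L, 2L), "odd")
})

test_that("recursive application follows y_t = f(x + y_(t-1)) with shared weights", {
  # base case: R = 1 is a single application
  set.seed(3)
  x <- array(rnorm(3 * 6 * 6), c(3, 6, 6, 1))
  conv <- new_conv2d(3L, 3L, 3L)
  rec1 <- new_recursive(conv, 1L)
  expect_equal(fr_forward(rec1, x)$out, fr_forward(conv, x)$out)

  # identity operator, R = 2, constant input c: y1 = c, y2 = c + c = 2c
  f <- function(z) z
  cst <- array(0.7, c(2, 4, 4, 1))
  expect_equal(recursive_apply(f, cst, 2L), 2 * cst)
  expect_equal(recursive_apply(f, cst, 1L), cst)
  expect_error(recursive_apply(f, cst, 0L), "R must be >= 1")
  expect_error(new_recursive(conv, 0L), "R must be >= 1")

  # recursion never changes parameter counts
  expect_identical(count_parameters(new_recursive(new_conv2d(3L, 3L, 3L), 2L))$total,
                   count_parameters(new_conv2d(3L, 3L, 3L))$total)

  # channel-changing operator is rejected for R > 1
  up <- new_conv2d(3L, 5L, 3L)
  expect_error(fr_forward(new_recursive(up, 2L), x), "preserve")
})

test_that("GRN is the identity at zero init and follows its formula", {
  set.seed(4)
  x <- array(rnorm(5 * 7 * 7 * 2), c(5, 7, 7, 2))
  g <- new_grn(5L)  # gamma = beta = 0 at init
  expect_equal(max(abs(fr_forward(g, x)$out - x)), 0)

  # all-zero input stays zero for any gamma with beta = 0
  g$par$gamma <- rnorm(5)
  expect_equal(max(abs(fr_forward(g, x * 0)$out)), 0)

  # single channel: N ratio is ~1, output = gamma*x + beta + x
  g1 <- new_grn(1L, eps = 0)
  g1$par$gamma <- 0.3; g1$par$beta <- 0.1
  x1 <- array(rnorm(9 * 9), c(1, 9, 9, 1))
  expect_equal(fr_forward(g1, x1)$out, 0.3 * x1 + 0.1 + x1, tolerance = 1e-12)
})

test_that("trunk blocks preserve spatial dims for arbitrary sizes", {
  set.seed(5)
  blocks <- list(new_convnext_block(6L, 9L, 2L),
                 new_convnext_block_original(6L, 9L),
                 new_residual_block(6L))
  for (b in blocks) {
    for (hw in list(c(16, 16), c(17, 23), c(40, 18))) {
      x <- array(rnorm(6 * hw[1] * hw[2]), c(6, hw[1], hw[2], 1))
      expect_identical(dim(fr_forward(b, x)$out), dim(x))
    }
  }
})

test_that("block parameter counts follow the closed forms", {
  C <- 32L; E <- 48L
  improved <- count_parameters(new_convnext_block(C, E, 2L))$total
  # dw7 + LN + 3x3 expand + GRN + 3x3 project
  expect_identical(improved,
                   as.integer(C * 49 + C + 2 * C +
                              E * C * 9 + E + 2 * E + C * E * 9 + C))
  original <- count_parameters(new_convnext_block_original(C, E))$total
  expect_identical(original,
                   as.integer(C * 49 + C + 2 * C +
                              E * C + E + 2 * E + C * E + C))
  expect_lt(original, improved)  # 1x1 vs full 3x3 channel mixing

  residual <- count_parameters(new_residual_block(C))$total
  expect_identical(residual, as.integer(2 * (C * C * 9 + C) + 2 * 2 * C))

  # recursion depth does not change the improved block's count
  expect_identical(count_parameters(new_convnext_block(C, E, 1L))$total, improved)
})

test_that("blocks with zeroed parameters map zero to zero", {
  set.seed(6)
  for (b in list(new_convnext_block(4L, 6L, 2L),
                 new_convnext_block_original(4L, 6L))) {
    for (w in frnetv2:::fr_walk(b)) {
      if (w$name %in% c("b", "beta")) w$mod$par[[w$name]][] <- 0
      if (w$name == "gamma" && inherits(w$mod, "fr_grn")) w$mod$par$gamma[] <- 0
    }
    x0 <- array(0, c(4, 10, 10, 1))
    expect_equal(max(abs(fr_forward(b, x0)$out)), 0)
  }
})

test_that("backpropagation matches numeric gradients through a ConvNeXt block", {
  set.seed(7)
  b <- new_convnext_block(3L, 5L, 2L)
  x <- array(rnorm(3 * 6 * 6), c(3, 6, 6, 1))
  fwd <- fr_forward(b, x, training = TRUE)
  r <- array(rnorm(length(fwd$out)), dim(fwd$out))
  fr_zero_grads(b)
  gx <- fr_backward(b, fwd$cache, r)
  loss <- function() sum(fr_forward(b, x, training = TRUE)$out * r)
  walk <- frnetv2:::fr_walk(b)
  for (w in walk[sample(length(walk), 6)]) {
    ii <- sample(length(w$mod$par[[w$name]]), 1)
    eps <- 1e-5
    orig <- w$mod$par[[w$name]][ii]
    w$mod$par[[w$name]][ii] <- orig + eps; fp <- loss()
    w$mod$par[[w$name]][ii] <- orig - eps; fm <- loss()
    w$mod$par[[w$name]][ii] <- orig
    expect_equal(w$mod$grd[[w$name]][ii], (fp - fm) / (2 * eps),
                 tolerance = 1e-3)
  }
  eps <- 1e-5
  ii <- sample(length(x), 1)
  orig <- x[ii]
  x[ii] <- orig + eps; fp <- loss()
  x[ii] <- orig - eps; fm <- loss()
  x[ii] <- orig
  expect_equal(gx[ii], (fp - fm) / (2 * eps), tolerance = 1e-3)
})

test_that("one optimization step changes every trainable tensor", {
  set.seed(8)
  m <- build_model(tiny_config(seed = 11L))
  before <- fr_state_dict(m)$par
  x <- array(rnorm(1 * 14 * 14 * 2), c(1, 14, 14, 2))
  y <- (array(runif(1 * 14 * 14 * 2), c(1, 14, 14, 2)) > 0.75) * 1
  fwd <- fr_forward(m, x, training = TRUE)
  p <- plogis(fwd$out)
  fr_zero_grads(m)
  fr_backward(m, fwd$cache, dice_loss_grad(p, y) * p * (1 - p))
  walk <- frnetv2:::fr_walk(m)
  st <- frnetv2:::adam_init(walk)
  frnetv2:::adam_step(walk, st, 1L, 1e-3)
  after <- fr_state_dict(m)$par
  for (nm in names(before)) {
    expect_gt(max(abs(after[[nm]] - before[[nm]])), 0, label = nm)
  }
})

test_that("parameter reports total correctly and serialize", {
  m <- build_variant("frnet_v2")
  rep <- count_parameters(m)
  expect_identical(sum(rep$per_component$params), rep$total)
  expect_true(all(rep$per_component$params >= 0))
  expect_equal(rep$total_millions_2dp, frnetv2:::round_half_up(rep$total / 1e6, 2))
  paths <- write_param_report(rep, file.path(tempdir(), "params"))
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(paths[["json"]])
  expect_equal(j$total, rep$total)
})

test_that("round_half_up rounds .005 upward at 2 decimals", {
  expect_equal(frnetv2:::round_half_up(0.115, 2), 0.12)
  expect_equal(frnetv2:::round_half_up(0.1149, 2), 0.11)
  expect_equal(frnetv2:::round_half_up(0.125, 2), 0.13)
})
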