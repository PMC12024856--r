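#' @useDynLib frnetv2, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm dnorm plogis rnorm runif
NULL

# ---------------------------------------------------------------------------
# Minimal layer framework.
#
# Every layer ("module") is an environment of class c("fr_<kind>", "fr_module")
# holding trainable parameters in $par (named arrays), accumulated gradients in
# $grd (same shapes), non-trainable state in $st (e.g. batch-norm running
# statistics) and, for containers, child modules in $children.
#
# Feature maps are (C, H, W, N) arrays; vector features are (C, N) matrices.
# fr_forward() returns list(out, cache); fr_backward() consumes the cache,
# accumulates parameter gradients in-place and returns the input gradient.
# ---------------------------------------------------------------------------

new_module <- function(kind, par = list(), st = list(), children = list(),
                       extra = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- par
  e$grd <- lapply(par, function(a) a * 0)
  e$st <- st
  e$children <- children
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("fr_", kind), "fr_module")
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward pass through a layer or network
#'
#' @param mod a module created by one of the layer constructors
#' @param x input array, `(C, H, W, N)` for spatial layers or `(C, N)` for
#'   vector layers
#' @param training logical; in training mode batch statistics are used (and
#'   updated) by normalization layers and caches needed for [fr_backward()]
#'   are retained
#' @return list with elements `out` (same container type as the input) and
#'   `cache` (opaque, `NULL` unless `training = TRUE`)
#' @export
fr_forward <- function(mod, x, training = FALSE) UseMethod("fr_forward")

#' Backward pass through a layer or network
#'
#' Accumulates parameter gradients into the module (side effect) and returns
#' the gradient with respect to the input.
#'
#' @param mod module previously run with `fr_forward(..., training = TRUE)`
#' @param cache the cache returned by that forward call
#' @param gy gradient of the loss with respect to the module output
#' @return gradient with respect to the module input
#' @export
fr_backward <- function(mod, cache, gy) UseMethod("fr_backward")

acc_grad <- function(mod, name, g) {
  mod$grd[[name]] <- mod$grd[[name]] + g
  invisible(NULL)
}

#' Zero all accumulated gradients in a module tree
#' @param mod module
#' @export
fr_zero_grads <- function(mod) {
  for (w in fr_walk(mod)) {
    m <- w$mod
    m$grd[[w$name]][] <- 0
  }
  invisible(mod)
}

# Flat walk over every trainable tensor: list of (mod, name, path).
fr_walk <- function(mod, path = character()) {
  out <- list()
  for (nm in names(mod$par)) {
    out[[length(out) + 1L]] <- list(mod = mod, name = nm,
                                    path = paste(c(path, nm), collapse = "."))
  }
  kids <- mod$children
  for (nm in names(kids)) {
    out <- c(out, fr_walk(kids[[nm]], c(path, nm)))
  }
  out
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(runif(prod(dims), -bound, bound), dim = dims)
}

# ---- standard convolution --------------------------------------------------

#' 2-D convolution layer with "same" padding
#'
#' Padding is always `dilation * (k - 1) / 2`, so output height and width
#' equal the input's for any odd kernel; this is what makes every layer of
#' the network full-resolution.
#'
#' @param cin,cout input/output channels
#' @param k odd kernel size
#' @param dilation dilation rate (spacing between taps); the effective
#'   receptive field is `k + (k - 1) * (dilation - 1)`
#' @return a module
#' @export
new_conv2d <- function(cin, cout, k, dilation = 1L) {
  if (k %% 2 == 0) stop("conv2d: kernel size must be odd, got ", k)
  new_module("conv2d",
             par = list(w = kaiming_uniform(c(cout, cin, k, k), cin * k * k),
                        b = numeric(cout)),
             extra = list(cin = cin, cout = cout, k = as.integer(k),
                          dilation = as.integer(dilation)))
}

#' @export
fr_forward.fr_conv2d <- function(mod, x, training = FALSE) {
  if (dim(x)[1] != mod$cin) {
    stop(sprintf("conv2d: input has %d channels, layer expects %d",
                 dim(x)[1], mod$cin))
  }
  out <- .conv2d_fwd(x, mod$par$w, mod$par$b, mod$dilation)
  list(out = out, cache = if (training) x)
}

#' @export
fr_backward.fr_conv2d <- function(mod, cache, gy) {
  g <- .conv2d_bwd(cache, mod$par$w, gy, mod$dilation)
  acc_grad(mod, "w", g$gw)
  acc_grad(mod, "b", g$gb)
  g$gx
}

# ---- depthwise convolution -------------------------------------------------

#' Depthwise 2-D convolution layer (one spatial filter per channel)
#' @inheritParams new_conv2d
#' @param channels number of channels (preserved)
#' @export
new_dwconv2d <- function(channels, k, dilation = 1L) {
  if (k %% 2 == 0) stop("dwconv2d: kernel size must be odd, got ", k)
  new_module("dwconv2d",
             par = list(w = kaiming_uniform(c(channels, k, k), k * k),
                        b = numeric(channels)),
             extra = list(channels = channels, k = as.integer(k),
                          dilation = as.integer(dilation)))
}

#' @export
fr_forward.fr_dwconv2d <- function(mod, x, training = FALSE) {
  if (dim(x)[1] != mod$channels) {
    stop(sprintf("dwconv2d: input has %d channels, layer expects %d",
                 dim(x)[1], mod$channels))
  }
  out <- .dwconv2d_fwd(x, mod$par$w, mod$par$b, mod$dilation)
  list(out = out, cache = if (training) x)
}

#' @export
fr_backward.fr_dwconv2d <- function(mod, cache, gy) {
  g <- .dwconv2d_bwd(cache, mod$par$w, gy, mod$dilation)
  acc_grad(mod, "w", g$gw)
  acc_grad(mod, "b", g$gb)
  g$gx
}

# ---- batch normalization ---------------------------------------------------

#' 2-D batch normalization (per channel over batch and space)
#' @param channels number of channels
#' @param momentum running-statistics update rate
#' @param eps variance stabilizer
#' @export
new_bn2d <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_module("bn2d",
             par = list(gamma = rep(1, channels), beta = rep(0, channels)),
             st = list(rm = rep(0, channels), rv = rep(1, channels)),
             extra = list(channels = channels, momentum = momentum, eps = eps))
}

bn_core_fwd <- function(mod, xm, training) {
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    istd <- 1 / sqrt(va + mod$eps)
    xhat <- xc * istd
    mod$st$rm <- (1 - mod$momentum) * mod$st$rm + mod$momentum * mu
    mod$st$rv <- (1 - mod$momentum) * mod$st$rv + mod$momentum * va
    y <- mod$par$gamma * xhat + mod$par$beta
    list(y = y, cache = list(xhat = xhat, istd = istd))
  } else {
    istd <- 1 / sqrt(mod$st$rv + mod$eps)
    y <- mod$par$gamma * istd * (xm - mod$st$rm) + mod$par$beta
    list(y = y, cache = NULL)
  }
}

bn_core_bwd <- function(mod, cache, gym) {
  xhat <- cache$xhat
  m1 <- rowMeans(gym)
  m2 <- rowMeans(gym * xhat)
  acc_grad(mod, "gamma", rowSums(gym * xhat))
  acc_grad(mod, "beta", rowSums(gym))
  (mod$par$gamma * cache$istd) * (gym - m1 - xhat * m2)
}

#' @export
fr_forward.fr_bn2d <- function(mod, x, training = FALSE) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
  r <- bn_core_fwd(mod, xm, training)
  y <- r$y; dim(y) <- d
  list(out = y, cache = if (training) r$cache)
}

#' @export
fr_backward.fr_bn2d <- function(mod, cache, gy) {
  d <- dim(gy)
  gym <- gy; dim(gym) <- c(d[1], prod(d[-1]))
  gx <- bn_core_bwd(mod, cache, gym)
  dim(gx) <- d
  gx
}

#' 1-D batch normalization for `(C, N)` vector features
#' @inheritParams new_bn2d
#' @export
new_bn1d <- function(channels, momentum = 0.1, eps = 1e-5) {
  m <- new_bn2d(channels, momentum, eps)
  m$kind <- "bn1d"
  class(m) <- c("fr_bn1d", "fr_module")
  m
}

#' @export
fr_forward.fr_bn1d <- function(mod, x, training = FALSE) {
  r <- bn_core_fwd(mod, x, training)
  list(out = r$y, cache = if (training) r$cache)
}

#' @export
fr_backward.fr_bn1d <- function(mod, cache, gy) bn_core_bwd(mod, cache, gy)

# ---- channelwise layer norm (ConvNeXt convention) --------------------------

#' Layer normalization over channels at each spatial position
#' @param channels number of channels
#' @param eps variance stabilizer
#' @export
new_ln <- function(channels, eps = 1e-6) {
  new_module("ln",
             par = list(gamma = rep(1, channels), beta = rep(0, channels)),
             extra = list(channels = channels, eps = eps))
}

#' @export
fr_forward.fr_ln <- function(mod, x, training = FALSE) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, prod(d[-1]))
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = C)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + mod$eps)
  xhat <- xc * rep(istd, each = C)
  y <- mod$par$gamma * xhat + mod$par$beta
  dim(y) <- d
  list(out = y, cache = if (training) list(xhat = xhat, istd = istd, d = d))
}

#' @export
fr_backward.fr_ln <- function(mod, cache, gy) {
  d <- cache$d; C <- d[1]
  gym <- gy; dim(gym) <- c(C, prod(d[-1]))
  xhat <- cache$xhat
  gxhat <- gym * mod$par$gamma
  c1 <- colMeans(gxhat)
  c2 <- colMeans(gxhat * xhat)
  gx <- (gxhat - rep(c1, each = C) - xhat * rep(c2, each = C)) *
    rep(cache$istd, each = C)
  acc_grad(mod, "gamma", rowSums(gym * xhat))
  acc_grad(mod, "beta", rowSums(gym))
  dim(gx) <- d
  gx
}

# ---- global response normalization (ConvNeXt V2) ---------------------------

#' Global response normalization layer
#'
#' For each sample, `G_c` is the spatial L2 norm of channel `c`,
#' `N_c = G_c / (mean_c G_c + eps)`, and the output is
#' `gamma * (x * N_c) + beta + x`.  With `gamma = beta = 0` (the
#' initialization) the layer is exactly the identity.  Adds `2 * channels`
#' trainable parameters and has no batch-size dependence.
#'
#' @param channels number of channels
#' @param eps stabilizer added to the cross-channel mean
#' @export
new_grn <- function(channels, eps = 1e-6) {
  new_module("grn",
             par = list(gamma = rep(0, channels), beta = rep(0, channels)),
             extra = list(channels = channels, eps = eps))
}

#' @export
fr_forward.fr_grn <- function(mod, x, training = FALSE) {
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  y <- x
  cache <- if (training) vector("list", N)
  for (n in seq_len(N)) {
    idx <- ((n - 1) * C * HW + 1):(n * C * HW)
    xm <- matrix(x[idx], nrow = C)
    G <- sqrt(rowSums(xm * xm))
    S <- mean(G) + mod$eps
    Nc <- G / S
    y[idx] <- mod$par$gamma * (xm * Nc) + mod$par$beta + xm
    if (training) cache[[n]] <- list(G = G, S = S, Nc = Nc)
  }
  list(out = y, cache = if (training) list(per = cache, d = d, x = x))
}

#' @export
fr_backward.fr_grn <- function(mod, cache, gy) {
  d <- cache$d; C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  gamma <- mod$par$gamma
  gx <- gy
  for (n in seq_len(N)) {
    idx <- ((n - 1) * C * HW + 1):(n * C * HW)
    xm <- matrix(cache$x[idx], nrow = C)
    gym <- matrix(gy[idx], nrow = C)
    pc <- cache$per[[n]]
    gyg <- gym * gamma
    tvec <- rowSums(gyg * xm)
    q <- tvec / pc$S - sum(tvec * pc$G) / (pc$S^2 * C)
    Gsafe <- pmax(pc$G, 1e-12)
    gx[idx] <- gym + gyg * pc$Nc + (q / Gsafe) * xm
    acc_grad(mod, "gamma", rowSums(gym * xm) * pc$Nc)
    acc_grad(mod, "beta", rowSums(gym))
  }
  gx
}

# ---- linear (fully connected) ----------------------------------------------

#' Fully connected layer on `(C, N)` features
#' @param cin,cout input/output width
#' @export
new_linear <- function(cin, cout) {
  new_module("linear",
             par = list(w = kaiming_uniform(c(cout, cin), cin),
                        b = numeric(cout)),
             extra = list(cin = cin, cout = cout))
}

#' @export
fr_forward.fr_linear <- function(mod, x, training = FALSE) {
  x <- as.matrix(x)
  list(out = mod$par$w %*% x + mod$par$b, cache = if (training) x)
}

#' @export
fr_backward.fr_linear <- function(mod, cache, gy) {
  acc_grad(mod, "w", gy %*% t(cache))
  acc_grad(mod, "b", rowSums(gy))
  t(mod$par$w) %*% gy
}

# ---- activations ------------------------------------------------------------

#' Activation layer
#' @param type one of `"relu"`, `"gelu"` (exact, `x * pnorm(x)`), `"sigmoid"`
#' @export
new_act <- function(type = c("relu", "gelu", "sigmoid")) {
  type <- match.arg(type)
  new_module("act", extra = list(type = type))
}

#' @export
fr_forward.fr_act <- function(mod, x, training = FALSE) {
  if (mod$type == "gelu") {
    Phi <- pnorm(x)
    out <- x * Phi
    if (!is.null(dim(x))) dim(out) <- dim(x)
    return(list(out = out, cache = if (training) list(x = x, Phi = Phi)))
  }
  out <- switch(mod$type,
                relu = pmax(x, 0),
                sigmoid = plogis(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  cache <- if (training) switch(mod$type, sigmoid = out, x)
  list(out = out, cache = cache)
}

#' @export
fr_backward.fr_act <- function(mod, cache, gy) {
  switch(mod$type,
         relu = gy * (cache > 0),
         gelu = gy * (cache$Phi + cache$x * dnorm(cache$x)),
         sigmoid = gy * cache * (1 - cache))
}

# ---- containers -------------------------------------------------------------

#' Sequential container
#' @param ... child modules, applied in order (may be named)
#' @export
new_seq <- function(...) {
  kids <- list(...)
  if (is.null(names(kids)) || any(names(kids) == "")) {
    names(kids) <- sprintf("l%d", seq_along(kids))
  }
  new_module("seq", children = kids)
}

#' @export
fr_forward.fr_seq <- function(mod, x, training = FALSE) {
  caches <- if (training) vector("list", length(mod$children))
  for (i in seq_along(mod$children)) {
    r <- fr_forward(mod$children[[i]], x, training)
    x <- r$out
    if (training) caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

#' @export
fr_backward.fr_seq <- function(mod, cache, gy) {
  for (i in rev(seq_along(mod$children))) {
    gy <- fr_backward(mod$children[[i]], cache[[i]], gy)
  }
  gy
}

#' Recursive (weight-shared) application of a channel-preserving module
#'
#' Computes `y_1 = f(x)`, `y_t = f(x + y_(t-1))` for `t = 2..R` and returns
#' `y_R`.  The same weights are used at every iteration, so the trainable
#' parameter count is independent of `R`; gradients from all iterations
#' accumulate on the shared weights.
#'
#' @param inner the wrapped module (must map channels C to C)
#' @param R recursion depth, at least 1
#' @export
new_recursive <- function(inner, R = 2L) {
  if (R < 1) stop("recursive: R must be >= 1, got ", R)
  new_module("recursive", children = list(inner = inner),
             extra = list(R = as.integer(R)))
}

#' @export
fr_forward.fr_recursive <- function(mod, x, training = FALSE) {
  f <- mod$children$inner
  caches <- if (training) vector("list", mod$R)
  r <- fr_forward(f, x, training)
  if (training) caches[[1]] <- r$cache
  y <- r$out
  if (mod$R > 1 && !identical(dim(y), dim(x))) {
    stop("recursive: wrapped module must preserve shape (channels C -> C)")
  }
  for (t in seq_len(mod$R)[-1]) {
    r <- fr_forward(f, x + y, training)
    y <- r$out
    if (training) caches[[t]] <- r$cache
  }
  list(out = y, cache = caches)
}

#' @export
fr_backward.fr_recursive <- function(mod, cache, gy) {
  f <- mod$children$inner
  gx <- 0
  for (t in rev(seq_len(mod$R))) {
    gu <- fr_backward(f, cache[[t]], gy)
    if (t > 1) {
      gx <- gx + gu   # d(x + y_{t-1})/dx
      gy <- gu        # flows into y_{t-1}
    } else {
      gx <- gx + gu
    }
  }
  gx
}

#' Pure-function recursive application
#'
#' Functional counterpart of [new_recursive()] for an arbitrary
#' shape-preserving operator: `y_1 = f(x)`, `y_t = f(x + y_(t-1))`.
#'
#' @param f a function of one array argument
#' @param x input array
#' @param R recursion depth, at least 1
#' @export
recursive_apply <- function(f, x, R = 2L) {
  if (R < 1) stop("recursive_apply: R must be >= 1, got ", R)
  y <- f(x)
  if (R > 1 && !identical(dim(y), dim(x))) {
    stop("recursive_apply: operator must preserve shape")
  }
  for (t in seq_len(R)[-1]) y <- f(x + y)
  y
}
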