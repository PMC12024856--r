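# ---------------------------------------------------------------------------
# Full-resolution trunk blocks.
#
# The trunk never strides, pools or upsamples: every block maps
# (C, H, W, N) -> (C, H, W, N), which preserves the thin, fragile vessel
# detail that encoder-decoder architectures lose to downsampling.
# ---------------------------------------------------------------------------

#' Residual container: `out = post(x + body(x))`
#' @param body a channel-preserving module
#' @param post_act optional activation applied after the residual sum
#' @keywords internal
new_res <- function(body, post_act = NULL) {
  kids <- list(body = body)
  if (!is.null(post_act)) kids$post <- post_act
  new_module("res", children = kids)
}

#' @export
fr_forward.fr_res <- function(mod, x, training = FALSE) {
  r <- fr_forward(mod$children$body, x, training)
  y <- x + r$out
  cache <- list(body = r$cache)
  if (!is.null(mod$children$post)) {
    rp <- fr_forward(mod$children$post, y, training)
    y <- rp$out
    cache$post <- rp$cache
  }
  list(out = y, cache = if (training) cache)
}

#' @export
fr_backward.fr_res <- function(mod, cache, gy) {
  if (!is.null(mod$children$post)) {
    gy <- fr_backward(mod$children$post, cache$post, gy)
  }
  gy + fr_backward(mod$children$body, cache$body, gy)
}

#' Depthwise-separable convolution
#'
#' A `k x k` depthwise convolution (one filter per channel) followed by a
#' `1 x 1` pointwise channel-mixing convolution.  Parameter count is
#' `cin*k^2 + cin + cin*cout + cout`, a fraction of a standard conv's
#' `cout*cin*k^2 + cout`.
#'
#' @inheritParams new_conv2d
#' @param recursion_R if greater than 1 (and `cin == cout`), the whole
#'   depthwise+pointwise unit is applied recursively with shared weights
#' @export
new_ds_conv <- function(cin, cout, k, dilation = 1L, recursion_R = 1L) {
  unit <- new_seq(dw = new_dwconv2d(cin, k, dilation),
                  pw = new_conv2d(cin, cout, 1L))
  if (recursion_R > 1) {
    if (cin != cout) {
      stop("ds_conv: recursion requires cin == cout (channel-preserving)")
    }
    unit <- new_recursive(unit, recursion_R)
  }
  unit
}

#' Improved recursive ConvNeXt V2 block
#'
#' The trunk block: recursive depthwise 7x7 -> channelwise layer norm ->
#' recursive middle pipeline (3x3 conv expanding to `expansion` channels,
#' GeLU, GRN, 3x3 conv projecting back) -> residual add of the block input.
#' The two 3x3 convolutions are standard (full channel mixing).  Recursion
#' (`y_1 = f(x)`, `y_t = f(x + y_(t-1))`) shares weights across iterations,
#' so `recursion_R` never changes the parameter count.  The middle pipeline
#' is recursed as a unit because its endpoints map C -> C while each 3x3
#' conv alone changes channel width.
#'
#' @param channels trunk width (default 32)
#' @param expansion hidden width of the middle convolutions (default 48)
#' @param recursion_R recursion depth (default 2); 1 disables recursion
#' @export
new_convnext_block <- function(channels = 32L, expansion = 48L,
                               recursion_R = 2L) {
  mid <- new_seq(expand = new_conv2d(channels, expansion, 3L),
                 gelu = new_act("gelu"),
                 grn = new_grn(expansion),
                 proj = new_conv2d(expansion, channels, 3L))
  new_res(new_seq(
    dw7 = new_recursive(new_dwconv2d(channels, 7L), recursion_R),
    ln = new_ln(channels),
    mid = new_recursive(mid, recursion_R)
  ))
}

#' Original ConvNeXt V2 block (1x1 middle convolutions, no recursion)
#'
#' Ablation variant: depthwise 7x7 -> layer norm -> 1x1 expand -> GeLU ->
#' GRN -> 1x1 project -> residual add.
#'
#' @inheritParams new_convnext_block
#' @export
new_convnext_block_original <- function(channels = 32L, expansion = 48L) {
  new_res(new_seq(
    dw7 = new_dwconv2d(channels, 7L),
    ln = new_ln(channels),
    expand = new_conv2d(channels, expansion, 1L),
    gelu = new_act("gelu"),
    grn = new_grn(expansion),
    proj = new_conv2d(expansion, channels, 1L)
  ))
}

#' Plain residual block (two standard 3x3 convolutions)
#'
#' Baseline stage: `relu(x + bn(conv(relu(bn(conv(x))))))`.
#'
#' @param channels trunk width
#' @export
new_residual_block <- function(channels = 32L) {
  new_res(new_seq(
    conv1 = new_conv2d(channels, channels, 3L),
    bn1 = new_bn2d(channels),
    relu1 = new_act("relu"),
    conv2 = new_conv2d(channels, channels, 3L),
    bn2 = new_bn2d(channels)
  ), post_act = new_act("relu"))
}

# ---------------------------------------------------------------------------
# Parameter counting
# ---------------------------------------------------------------------------

#' Round half-up to a number of decimal places
#' @keywords internal
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Count trainable parameters of a module tree
#'
#' @param mod a module (layer, block, or assembled model)
#' @return an object of class `fr_param_report`: list with `per_component`
#'   (data frame of top-level component names and exact integer counts),
#'   `total` (integer) and `total_millions_2dp` (total / 1e6, rounded
#'   half-up to 2 decimals, the convention used when quoting model size)
#' @export
count_parameters <- function(mod) {
  stopifnot(inherits(mod, "fr_module"))
  comp_count <- function(m) {
    sum(vapply(fr_walk(m), function(w) length(w$mod$par[[w$name]]), numeric(1)))
  }
  if (length(mod$children)) {
    nms <- names(mod$children)
    counts <- vapply(mod$children, comp_count, numeric(1))
    own <- sum(vapply(mod$par, length, numeric(1)))
    if (own > 0) {
      nms <- c(nms, "(own)")
      counts <- c(counts, own)
    }
    per <- data.frame(component = nms, params = as.integer(counts),
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    per <- data.frame(component = mod$kind,
                      params = as.integer(comp_count(mod)),
                      stringsAsFactors = FALSE)
  }
  total <- sum(per$params)
  structure(list(per_component = per, total = as.integer(total),
                 total_millions_2dp = round_half_up(total / 1e6, 2)),
            class = "fr_param_report")
}

#' @export
print.fr_param_report <- function(x, ...) {
  cat(format_param_report(x), sep = "\n")
  invisible(x)
}

#' Format a parameter report as a plain-text table
#' @param report an `fr_param_report`
#' @return character vector of lines
#' @export
format_param_report <- function(report) {
  per <- report$per_component
  w <- max(nchar(per$component), nchar("component"))
  lines <- c(
    sprintf("%-*s  %12s", w, "component", "params"),
    sprintf("%-*s  %12d", w, per$component, per$params),
    sprintf("%-*s  %12d", w, "total", report$total),
    sprintf("%-*s  %12.2f M", w, "total (M)", report$total_millions_2dp)
  )
  lines
}

#' Write a parameter report to JSON and plain text
#' @param report an `fr_param_report`
#' @param path output path; `.json` and `.txt` files are written with this stem
#' @return invisibly, the paths written
#' @export
write_param_report <- function(report, path) {
  stem <- sub("\\.(json|txt)$", "", path)
  jpath <- paste0(stem, ".json")
  tpath <- paste0(stem, ".txt")
  jsonlite::write_json(
    list(per_component = report$per_component,
         total = report$total,
         total_millions_2dp = report$total_millions_2dp),
    jpath, auto_unbox = TRUE, digits = NA)
  writeLines(format_param_report(report), tpath)
  invisible(c(json = jpath, text = tpath))
}
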