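# ---------------------------------------------------------------------------
# FRNet V2 assembly: stem -> N identical full-resolution stages ->
# DWAM attention + EFF fusion -> segmentation head.
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' @param in_channels input image channels (grayscale angiograms: 1)
#' @param trunk_channels width of every trunk stage (default 32)
#' @param num_stages number of identical full-resolution stages (default 4)
#' @param block_kind stage block: `"convnextv2_3x3_recursive"` (default; the
#'   improved block), `"convnextv2_3x3"` (same but recursion off),
#'   `"convnextv2_original"` (1x1 middle convs), `"residual"` (plain baseline)
#' @param expansion_width hidden width of the ConvNeXt-style middle convs
#'   (default 48, calibrated so the 4-stage backbone totals 0.12 M parameters)
#' @param recursion_R recursion depth for recursive blocks (default 2)
#' @param attention `"dwam_eff"` (default) or `"none"`
#' @param fc_hidden,spatial_mid_channels,eag_width attention-capacity knobs
#'   forwarded to [new_dwam()] and [new_eff()]
#' @param head_kernel kernel of the segmentation head (default 1; 11 is the
#'   documented alternative)
#' @param seed integer seed for weight initialization
#' @return a `frnet_config` list
#' @export
frnet_config <- function(in_channels = 1L, trunk_channels = 32L,
                         num_stages = 4L,
                         block_kind = c("convnextv2_3x3_recursive",
                                        "convnextv2_3x3",
                                        "convnextv2_original", "residual"),
                         expansion_width = 48L, recursion_R = 2L,
                         attention = c("dwam_eff", "none"),
                         fc_hidden = 512L,
                         spatial_mid_channels = 96L, eag_width = 64L,
                         head_kernel = 1L, seed = 42L) {
  block_kind <- match.arg(block_kind)
  attention <- match.arg(attention)
  if (num_stages < 1) stop("frnet_config: num_stages must be >= 1")
  if (head_kernel %% 2 == 0) stop("frnet_config: head_kernel must be odd")
  structure(list(in_channels = as.integer(in_channels),
                 trunk_channels = as.integer(trunk_channels),
                 num_stages = as.integer(num_stages),
                 block_kind = block_kind,
                 expansion_width = as.integer(expansion_width),
                 recursion_R = as.integer(recursion_R),
                 attention = attention,
                 fc_hidden = as.integer(fc_hidden),
                 spatial_mid_channels = as.integer(spatial_mid_channels),
                 eag_width = as.integer(eag_width),
                 head_kernel = as.integer(head_kernel),
                 seed = as.integer(seed)),
            class = "frnet_config")
}

make_stage <- function(cfg) {
  switch(cfg$block_kind,
         convnextv2_3x3_recursive =
           new_convnext_block(cfg$trunk_channels, cfg$expansion_width,
                              cfg$recursion_R),
         convnextv2_3x3 =
           new_convnext_block(cfg$trunk_channels, cfg$expansion_width, 1L),
         convnextv2_original =
           new_convnext_block_original(cfg$trunk_channels,
                                       cfg$expansion_width),
         residual = new_residual_block(cfg$trunk_channels),
         stop("unknown block_kind: ", cfg$block_kind))
}

#' Build an FRNet V2 model
#'
#' Deterministic given `cfg$seed`: two builds with the same configuration
#' produce identical weights.
#'
#' @param cfg a [frnet_config()]
#' @return a model module (class `fr_frnet`)
#' @export
build_model <- function(cfg = frnet_config()) {
  stopifnot(inherits(cfg, "frnet_config"))
  set.seed(cfg$seed)
  C <- cfg$trunk_channels
  kids <- list(
    stem = new_seq(conv = new_conv2d(cfg$in_channels, C, 3L),
                   bn = new_bn2d(C), relu = new_act("relu"))
  )
  for (i in seq_len(cfg$num_stages)) {
    kids[[sprintf("stage%d", i)]] <- make_stage(cfg)
  }
  if (cfg$attention == "dwam_eff") {
    kids$dwam <- new_dwam(dwam_config(
      channels = C, recursion_R = cfg$recursion_R, fc_hidden = cfg$fc_hidden,
      spatial_mid_channels = cfg$spatial_mid_channels))
    kids$eff <- new_eff(C, cfg$eag_width)
  }
  kids$head <- new_conv2d(C, 1L, cfg$head_kernel)
  new_module("frnet", children = kids, extra = list(cfg = cfg))
}

check_finite <- function(x, stage) {
  if (!all(is.finite(x))) {
    stop("non-finite activations first appeared at stage '", stage, "'")
  }
  invisible(NULL)
}

#' @export
fr_forward.fr_frnet <- function(mod, x, training = FALSE) {
  cfg <- mod$cfg
  check_finite(x, "input")
  caches <- list()
  r <- fr_forward(mod$children$stem, x, training)
  caches$stem <- r$cache
  t <- r$out
  check_finite(t, "stem")
  for (i in seq_len(cfg$num_stages)) {
    nm <- sprintf("stage%d", i)
    r <- fr_forward(mod$children[[nm]], t, training)
    caches[[nm]] <- r$cache
    t <- r$out
    check_finite(t, nm)
  }
  if (cfg$attention == "dwam_eff") {
    r <- fr_forward(mod$children$dwam, t, training)
    caches$dwam <- r$cache
    att <- r$out
    check_finite(att, "dwam")
    r <- fr_forward(mod$children$eff, list(att = att, skip = t), training)
    caches$eff <- r$cache
    t <- r$out
    check_finite(t, "eff")
  }
  r <- fr_forward(mod$children$head, t, training)
  caches$head <- r$cache
  list(out = r$out, cache = if (training) caches)
}

#' @export
fr_backward.fr_frnet <- function(mod, cache, gy) {
  cfg <- mod$cfg
  g <- fr_backward(mod$children$head, cache$head, gy)
  if (cfg$attention == "dwam_eff") {
    ge <- fr_backward(mod$children$eff, cache$eff, g)
    gatt <- fr_backward(mod$children$dwam, cache$dwam, ge$att)
    g <- ge$skip + gatt
  }
  for (i in rev(seq_len(cfg$num_stages))) {
    nm <- sprintf("stage%d", i)
    g <- fr_backward(mod$children[[nm]], cache[[nm]], g)
  }
  fr_backward(mod$children$stem, cache$stem, g)
}

#' Run the network on one or more images
#'
#' @param model a model from [build_model()] or [build_variant()]
#' @param image an `H x W` matrix in `[0, 1]`, or a `(1, H, W, N)` array
#' @param logits if `TRUE`, return pre-sigmoid values (numerically preferable
#'   when feeding an external loss); default returns probabilities in `[0, 1]`
#' @return probability (or logit) map with the same spatial size as the input
#' @export
frnet_forward <- function(model, image, logits = FALSE) {
  single <- is.matrix(image)
  if (single) {
    image <- array(image, dim = c(1L, nrow(image), ncol(image), 1L))
  }
  out <- fr_forward(model, image, training = FALSE)$out
  if (!logits) out <- plogis(out)
  if (single) out <- matrix(out, nrow = dim(out)[2])
  out
}

# ---------------------------------------------------------------------------
# Variant registry (the ablation grid)
# ---------------------------------------------------------------------------

#' Names of all registered model variants
#' @export
variant_names <- function() {
  c("frnet_v2", "backbone_recursive", "backbone_3x3",
    "backbone_original_block", "backbone_residual",
    sprintf("layers_%d", 2:6))
}

#' Resolve a variant name to its configuration
#' @param name one of [variant_names()]
#' @param seed weight-initialization seed
#' @export
variant_config <- function(name, seed = 42L) {
  base <- function(...) frnet_config(seed = seed, ...)
  if (grepl("^layers_[2-6]$", name)) {
    k <- as.integer(sub("layers_", "", name))
    return(base(num_stages = k))
  }
  switch(name,
         frnet_v2 = base(),
         backbone_recursive = base(attention = "none"),
         backbone_3x3 = base(attention = "none",
                             block_kind = "convnextv2_3x3"),
         backbone_original_block = base(attention = "none",
                                        block_kind = "convnextv2_original"),
         backbone_residual = base(attention = "none",
                                  block_kind = "residual"),
         stop("unknown variant: ", name))
}

#' Build a registered model variant
#' @inheritParams variant_config
#' @export
build_variant <- function(name, seed = 42L) {
  build_model(variant_config(name, seed))
}

#' Parameter-count table for a set of variants
#'
#' @param names variant names (default: all)
#' @return data frame with columns `variant`, `params`, `millions`
#' @export
report_params <- function(names = variant_names()) {
  rows <- lapply(names, function(nm) {
    rep <- count_parameters(build_variant(nm))
    data.frame(variant = nm, params = rep$total,
               millions = rep$total_millions_2dp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Checkpoints
# ---------------------------------------------------------------------------

#' Extract all weights and normalization statistics as a named list
#' @param model a model module
#' @export
fr_state_dict <- function(model) {
  pars <- list()
  for (w in fr_walk(model)) pars[[w$path]] <- w$mod$par[[w$name]]
  sts <- list()
  walk_st <- function(m, path) {
    for (nm in names(m$st)) sts[[paste(c(path, nm), collapse = ".")]] <<- m$st[[nm]]
    for (nm in names(m$children)) walk_st(m$children[[nm]], c(path, nm))
  }
  walk_st(model, character())
  list(par = pars, st = sts)
}

#' Load a state dict (in place) into a model of the same architecture
#' @param model a model module
#' @param state a list from [fr_state_dict()]
#' @export
fr_load_state <- function(model, state) {
  for (w in fr_walk(model)) {
    v <- state$par[[w$path]]
    if (is.null(v)) stop("state dict is missing tensor ", w$path)
    stopifnot(length(v) == length(w$mod$par[[w$name]]))
    w$mod$par[[w$name]][] <- v
  }
  walk_st <- function(m, path) {
    for (nm in names(m$st)) {
      key <- paste(c(path, nm), collapse = ".")
      if (!is.null(state$st[[key]])) m$st[[nm]][] <- state$st[[key]]
    }
    for (nm in names(m$children)) walk_st(m$children[[nm]], c(path, nm))
  }
  walk_st(model, character())
  invisible(model)
}

#' Save model weights and configuration to a single checkpoint file
#' @param model a model module
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = fr_state_dict(model)), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file
#' @return the rebuilt model with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  fr_load_state(model, ck$state)
  model
}
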