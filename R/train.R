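# ---------------------------------------------------------------------------
# Training: Dice-loss optimization with Adam, early stopping on a monitored
# validation metric, best-epoch checkpointing.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam/SGD step size
#' @param batch_size samples per gradient step
#' @param max_epochs maximum number of epochs
#' @param early_stop_patience stop after this many consecutive epochs without
#'   improvement of the monitored metric (must not exceed `max_epochs`)
#' @param optimizer `"adam"` (default) or `"sgd"`
#' @param monitor validation metric that drives checkpointing and early
#'   stopping: `"val_accuracy"` (default) or `"val_dice"`
#' @param seed seed covering shuffling and augmentation
#' @param device accepted for interface compatibility; only `"cpu"` exists
#' @param augment apply on-the-fly augmentation to training samples
#' @param aug_config an [augmentation_config()]
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         max_epochs = 200L, early_stop_patience = 100L,
                         optimizer = c("adam", "sgd"),
                         monitor = c("val_accuracy", "val_dice"),
                         seed = 1L, device = "cpu", augment = TRUE,
                         aug_config = augmentation_config()) {
  optimizer <- match.arg(optimizer)
  monitor <- match.arg(monitor)
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  if (early_stop_patience > max_epochs) {
    stop("train_config: early_stop_patience must not exceed max_epochs")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 optimizer = optimizer, monitor = monitor,
                 seed = as.integer(seed), device = device,
                 augment = augment, aug_config = aug_config),
            class = "fr_train_config")
}

#' Serialize a training configuration to YAML
#' @param cfg a [train_config()]
#' @param path output file
#' @export
write_train_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path file written by [write_train_config()]
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$aug_config <- do.call(augmentation_config, y$aug_config)
  do.call(train_config, y)
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(walk) {
  lapply(walk, function(w) {
    z <- w$mod$par[[w$name]] * 0
    list(m = z, v = z)
  })
}

adam_step <- function(walk, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(walk)) {
    w <- walk[[i]]
    g <- w$mod$grd[[w$name]]
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    state[[i]] <- st
    w$mod$par[[w$name]] <- w$mod$par[[w$name]] -
      lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
  }
  state
}

sgd_step <- function(walk, lr) {
  for (w in walk) {
    w$mod$par[[w$name]] <- w$mod$par[[w$name]] - lr * w$mod$grd[[w$name]]
  }
}

# stack a list of fr_samples into (1,H,W,B) input and target arrays;
# images are standardized here, just before entering the network
stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, dim = c(1L, H, W, B))
  y <- array(0, dim = c(1L, H, W, B))
  for (b in seq_len(B)) {
    x[1, , , b] <- normalize_image(samples[[b]]$image)
    y[1, , , b] <- samples[[b]]$mask
  }
  list(x = x, y = y)
}

#' Train a model with Dice loss
#'
#' Runs Dice-loss optimization with the configured optimizer, evaluates the
#' validation split after every epoch, keeps the weights of the best
#' monitored epoch ("improvement" means exceeding the best value so far by
#' at least 1e-6) and stops early after `early_stop_patience` epochs without
#' improvement.  Fully seeded: weight initialization by the model config,
#' shuffling and augmentation by `train_cfg$seed`.
#'
#' @param model a model module, or a [frnet_config()] to build one
#' @param manifest an `fr_manifest` with non-empty train and val splits
#' @param train_cfg a [train_config()]
#' @param checkpoint_path optional file to save the best checkpoint to
#' @param verbose print a line per epoch
#' @return list with `model` (best weights restored), `history` (data frame
#'   of per-epoch train loss / val Dice / val Acc), `best_epoch`,
#'   `best_value` and `checkpoint_path`
#' @export
train_model <- function(model, manifest, train_cfg = train_config(),
                        checkpoint_path = NULL, verbose = FALSE) {
  if (inherits(model, "frnet_config")) model <- build_model(model)
  train_set <- load_split(manifest, "train")
  val_set <- load_split(manifest, "val")
  if (length(train_set) == 0) stop("train split is empty")
  if (length(val_set) == 0) stop("val split is empty")

  set.seed(train_cfg$seed)
  walk <- fr_walk(model)
  opt_state <- if (train_cfg$optimizer == "adam") adam_init(walk)
  mcfg <- metric_config()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric(), val_acc = numeric())
  best_value <- -Inf
  best_epoch <- 0L
  best_state <- NULL
  t_opt <- 0L

  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(length(train_set))
    losses <- numeric()
    for (start in seq(1, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1, length(ord))]
      batch <- train_set[idx]
      if (train_cfg$augment) {
        batch <- lapply(batch, augment_sample, cfg = train_cfg$aug_config)
      }
      sb <- stack_batch(batch)
      fr_zero_grads(model)
      fwd <- fr_forward(model, sb$x, training = TRUE)
      prob <- plogis(fwd$out)
      loss <- dice_loss(prob, sb$y, mcfg)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      losses <- c(losses, loss)
      gprob <- dice_loss_grad(prob, sb$y, mcfg)
      glogit <- gprob * prob * (1 - prob)
      fr_backward(model, fwd$cache, glogit)
      t_opt <- t_opt + 1L
      if (train_cfg$optimizer == "adam") {
        opt_state <- adam_step(walk, opt_state, t_opt, train_cfg$learning_rate)
      } else {
        sgd_step(walk, train_cfg$learning_rate)
      }
    }
    val <- evaluate_samples(model, val_set, mcfg)
    agg <- attr(val, "aggregate")
    monitored <- if (train_cfg$monitor == "val_accuracy") {
      agg$mean_acc
    } else {
      agg$mean_dice
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_dice = agg$mean_dice, val_acc = agg$mean_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  val acc %.4f",
                      epoch, mean(losses), agg$mean_dice, agg$mean_acc))
    }
    if (monitored > best_value + 1e-6) {
      best_value <- monitored
      best_epoch <- epoch
      best_state <- fr_state_dict(model)
    }
    if (epoch - best_epoch >= train_cfg$early_stop_patience) break
  }
  if (!is.null(best_state)) fr_load_state(model, best_state)
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, history = history, best_epoch = best_epoch,
       best_value = best_value, checkpoint_path = checkpoint_path)
}

# ---------------------------------------------------------------------------
# Evaluation and prediction
# ---------------------------------------------------------------------------

#' Evaluate a model on a list of samples
#'
#' @param model a model module
#' @param samples list of `fr_sample`s
#' @param cfg a [metric_config()]
#' @return data frame with per-image `id`, `dice`, `acc`; attribute
#'   `aggregate` holds the per-image means (`mean_dice`, `mean_acc`) and the
#'   micro-averaged scores over pooled pixel counts (`micro_dice`,
#'   `micro_acc`)
#' @export
evaluate_samples <- function(model, samples, cfg = metric_config()) {
  if (length(samples) == 0) stop("no samples to evaluate")
  rows <- vector("list", length(samples))
  pooled <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                      class = "fr_confusion")
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    prob <- frnet_forward(model, normalize_image(s$image))
    cc <- confusion_counts(binarize(prob, cfg), s$mask)
    pooled <- confusion_add(pooled, cc)
    d <- if (2 * cc$TP + cc$FP + cc$FN > 0) dice_coefficient(cc) else NA_real_
    rows[[i]] <- data.frame(id = s$id, dice = d, acc = accuracy(cc),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "aggregate") <- list(
    mean_dice = mean(tab$dice, na.rm = TRUE),
    mean_acc = mean(tab$acc),
    micro_dice = dice_coefficient(pooled),
    micro_acc = accuracy(pooled))
  tab
}

#' Evaluate a model on one split of a manifest
#'
#' @param model a model module or a checkpoint path
#' @param manifest an `fr_manifest`
#' @param split `"train"`, `"test"` or `"val"`
#' @param cfg a [metric_config()]
#' @inherit evaluate_samples return
#' @export
evaluate_model <- function(model, manifest, split = "test",
                           cfg = metric_config()) {
  if (is.character(model)) model <- load_checkpoint(model)
  samples <- load_split(manifest, split)
  if (length(samples) == 0) stop("split '", split, "' is empty")
  evaluate_samples(model, samples, cfg)
}

#' Segment one image file and write the binary mask as PNG
#'
#' @param model a model module or checkpoint path
#' @param image_path input image (PNG/TIFF, grayscale-convertible)
#' @param out_path output PNG
#' @param cfg a [metric_config()] (binarization threshold)
#' @return invisibly, a list with the image shape and foreground fraction
#' @export
predict_mask <- function(model, image_path, out_path, cfg = metric_config()) {
  if (is.character(model)) model <- load_checkpoint(model)
  img <- read_gray(image_path)
  prob <- frnet_forward(model, normalize_image(img))
  mask <- binarize(prob, cfg)
  write_mask(mask, out_path)
  info <- list(height = nrow(img), width = ncol(img),
               foreground_fraction = mean(mask))
  message(sprintf("predicted %dx%d mask, foreground fraction %.3f -> %s",
                  info$height, info$width, info$foreground_fraction, out_path))
  invisible(info)
}
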