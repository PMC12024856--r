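# ---------------------------------------------------------------------------
# Image/mask pairs, dataset manifests, normalization, augmentation.
#
# Images are H x W matrices in [0, 1]; masks are strictly binary H x W
# matrices.  Manifests are CSV files (id, image, mask, split) with paths
# relative to a root directory.
# ---------------------------------------------------------------------------

read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unreadable format '", ext, "' (supported: png, tif/tiff): ", path)
  }
  if (length(dim(img)) == 3) {
    # luminance conversion for RGB(A) inputs
    ch <- dim(img)[3]
    if (ch >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

#' Load an image/mask pair as a sample
#'
#' The image is scaled to `[0, 1]`; the mask is binarized at 127/255.
#' BMP is not supported (no reader available); use PNG or TIFF.
#'
#' @param image_path,mask_path readable grayscale-convertible image files
#' @param id sample identifier (default: image file stem)
#' @return a `fr_sample`: list with `image` (H x W in `[0,1]`), `mask`
#'   (H x W binary) and `id`
#' @export
load_sample <- function(image_path, mask_path,
                        id = tools::file_path_sans_ext(basename(image_path))) {
  image <- read_gray(image_path)
  mask <- read_gray(mask_path)
  if (!identical(dim(image), dim(mask))) {
    stop(sprintf("shape mismatch: image %dx%d vs mask %dx%d (%s)",
                 nrow(image), ncol(image), nrow(mask), ncol(mask), id))
  }
  mask <- (mask > 127 / 255) * 1
  structure(list(image = image, mask = mask, id = id), class = "fr_sample")
}

#' Write a binary mask as an 8-bit PNG
#' @param mask binary H x W matrix
#' @param path output path
#' @export
write_mask <- function(mask, path) {
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Per-image standardization
#'
#' Zero mean, unit variance; constant images map to all-zero.  This is the
#' normalization applied to every image before it enters the network (the
#' stored samples stay in `[0, 1]`).
#'
#' @param image H x W matrix
#' @export
normalize_image <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s < 1e-12) return(image * 0)
  (image - mean(image)) / s
}

# ---------------------------------------------------------------------------
# Augmentation
# ---------------------------------------------------------------------------

#' Augmentation configuration
#'
#' @param rotation_degrees rotations are drawn uniformly from
#'   `[-rotation_degrees, rotation_degrees]`
#' @param gaussian_noise_sigma additive noise standard deviation, as a
#'   fraction of the dynamic range
#' @param sharpness_range random sharpness factor range; 1 = identity,
#'   below 1 softens, above 1 sharpens (unsharp masking)
#' @param flip_horizontal,flip_vertical,flip_diagonal flip toggles; the
#'   diagonal flip is a transpose and is only applied to square images
#' @param prob probability of applying each enabled operation
#' @export
augmentation_config <- function(rotation_degrees = 15,
                                gaussian_noise_sigma = 0.02,
                                sharpness_range = c(0.5, 2),
                                flip_horizontal = TRUE, flip_vertical = TRUE,
                                flip_diagonal = TRUE, prob = 0.5) {
  stopifnot(prob >= 0, prob <= 1, rotation_degrees >= 0,
            gaussian_noise_sigma >= 0, length(sharpness_range) == 2)
  list(rotation_degrees = rotation_degrees,
       gaussian_noise_sigma = gaussian_noise_sigma,
       sharpness_range = sharpness_range,
       flip_horizontal = flip_horizontal, flip_vertical = flip_vertical,
       flip_diagonal = flip_diagonal, prob = prob)
}

#' Rotate an image about its center
#'
#' Inverse mapping with zero fill outside the frame.
#'
#' @param img H x W matrix
#' @param degrees rotation angle (counter-clockwise)
#' @param method `"bilinear"` for images, `"nearest"` for masks
#' @export
rotate_image <- function(img, degrees, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  # inverse rotation of target coordinates
  ys <- cos(th) * yy + sin(th) * xx + cy
  xs <- -sin(th) * yy + cos(th) * xx + cx
  if (method == "nearest") {
    yi <- round(ys); xi <- round(xs)
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    out <- matrix(0, H, W)
    out[ok] <- img[cbind(yi[ok], xi[ok])]
  } else {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    gv <- function(yi, xi) {
      ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
      v <- matrix(0, H, W)
      v[ok] <- img[cbind(yi[ok], xi[ok])]
      v
    }
    out <- (1 - fy) * (1 - fx) * gv(y0, x0) +
      (1 - fy) * fx * gv(y0, x0 + 1) +
      fy * (1 - fx) * gv(y0 + 1, x0) +
      fy * fx * gv(y0 + 1, x0 + 1)
  }
  out
}

gaussian_kernel <- function(sigma) {
  k <- max(3L, 2L * ceiling(2.5 * sigma) + 1L)
  g <- dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
  g <- g / sum(g)
  outer(g, g)
}

#' Gaussian blur of a single-channel image
#' @param img H x W matrix
#' @param sigma blur standard deviation in pixels
#' @export
gaussian_blur <- function(img, sigma) {
  ker <- gaussian_kernel(sigma)
  x <- array(img, dim = c(1L, nrow(img), ncol(img), 1L))
  w <- array(ker, dim = c(1L, nrow(ker), ncol(ker)))
  out <- .dwconv2d_fwd(x, w, 0, 1L)
  matrix(out, nrow(img), ncol(img))
}

adjust_sharpness <- function(img, factor, sigma = 1) {
  blur <- gaussian_blur(img, sigma)
  pmin(pmax(blur + factor * (img - blur), 0), 1)
}

#' Augment a sample
#'
#' Geometric operations (rotation, flips) are applied identically to image
#' and mask (mask via nearest-neighbour); photometric operations (Gaussian
#' noise, sharpness) touch the image only.  The mask stays strictly binary
#' and shapes are never changed.  Deterministic given `seed`.
#'
#' @param s an `fr_sample`
#' @param cfg an [augmentation_config()]
#' @param seed integer seed
#' @export
augment_sample <- function(s, cfg = augmentation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- s$image; mask <- s$mask
  if (cfg$rotation_degrees > 0 && runif(1) < cfg$prob) {
    ang <- runif(1, -cfg$rotation_degrees, cfg$rotation_degrees)
    img <- rotate_image(img, ang, "bilinear")
    mask <- rotate_image(mask, ang, "nearest")
  }
  if (cfg$flip_horizontal && runif(1) < cfg$prob) {
    img <- img[, ncol(img):1]; mask <- mask[, ncol(mask):1]
  }
  if (cfg$flip_vertical && runif(1) < cfg$prob) {
    img <- img[nrow(img):1, ]; mask <- mask[nrow(mask):1, ]
  }
  if (cfg$flip_diagonal && nrow(img) == ncol(img) && runif(1) < cfg$prob) {
    img <- t(img); mask <- t(mask)
  }
  if (cfg$gaussian_noise_sigma > 0 && runif(1) < cfg$prob) {
    img <- pmin(pmax(img + rnorm(length(img), 0, cfg$gaussian_noise_sigma), 0), 1)
    dim(img) <- dim(mask)
  }
  if (runif(1) < cfg$prob) {
    f <- runif(1, cfg$sharpness_range[1], cfg$sharpness_range[2])
    img <- adjust_sharpness(img, f)
  }
  structure(list(image = img, mask = mask, id = s$id), class = "fr_sample")
}

# ---------------------------------------------------------------------------
# Manifests
# ---------------------------------------------------------------------------

#' Build a dataset manifest with a deterministic seeded split
#'
#' @param entries data frame with columns `id`, `image`, `mask` (paths
#'   relative to `root`)
#' @param counts integer vector `c(train, test, val)`; must sum to
#'   `nrow(entries)`
#' @param root dataset root directory
#' @param seed split seed
#' @param name dataset name
#' @return a `fr_manifest` data frame with an added `split` column
#' @export
split_manifest <- function(entries, counts, root = ".", seed = 1L,
                           name = "dataset") {
  stopifnot(all(c("id", "image", "mask") %in% names(entries)))
  if (sum(counts) != nrow(entries)) {
    stop(sprintf("split counts (%s) must sum to the %d available entries",
                 paste(counts, collapse = "/"), nrow(entries)))
  }
  set.seed(seed)
  ord <- sample.int(nrow(entries))
  split <- rep(c("train", "test", "val"), times = counts)
  entries$split <- split[order(ord)]
  structure(entries, class = c("fr_manifest", "data.frame"),
            root = root, name = name)
}

#' Write a manifest as CSV
#' @param manifest an `fr_manifest`
#' @param path output CSV
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("id", "image", "mask", "split")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a manifest CSV
#' @param path CSV written by [write_manifest()]
#' @param root dataset root (default: the CSV's directory)
#' @export
read_manifest <- function(path, root = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "image", "mask", "split") %in% names(df)))
  structure(df, class = c("fr_manifest", "data.frame"),
            root = root, name = tools::file_path_sans_ext(basename(path)))
}

#' Load all samples of one split of a manifest
#' @param manifest an `fr_manifest`
#' @param split one of `"train"`, `"test"`, `"val"`
#' @return list of `fr_sample`s
#' @export
load_split <- function(manifest, split) {
  root <- attr(manifest, "root")
  sel <- manifest[manifest$split == split, , drop = FALSE]
  lapply(seq_len(nrow(sel)), function(i) {
    load_sample(file.path(root, sel$image[i]), file.path(root, sel$mask[i]),
                id = sel$id[i])
  })
}
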