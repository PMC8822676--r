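#' Augmentation bounds
#'
#' Maxima for the single random affine transform applied to each training
#' image/label pair as it is passed to the network: up to 10 degrees
#' rotation, 15% translation per axis, 10% zoom and 0.2 degrees shear.
#'
#' @param max_rotation_deg,max_translation_frac,max_zoom_frac,max_shear_deg
#'   nonnegative maxima; each parameter is drawn uniformly from
#'   `[-max, +max]` (zoom from `[1 - max, 1 + max]`).
#' @return list of class `augment_bounds`.
#' @export
augment_bounds <- function(max_rotation_deg = 10, max_translation_frac = 0.15,
                           max_zoom_frac = 0.10, max_shear_deg = 0.2) {
  vals <- c(max_rotation_deg, max_translation_frac, max_zoom_frac, max_shear_deg)
  if (any(vals < 0)) stop("augmentation bounds must be nonnegative")
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_translation_frac = max_translation_frac,
                 max_zoom_frac = max_zoom_frac,
                 max_shear_deg = max_shear_deg), class = "augment_bounds")
}

#' U-Net model and training hyperparameters
#'
#' Defaults follow the training recipe: Adam at an initial learning rate of
#' 5e-5, a 0.25-factor reduction on validation-loss plateau floored at 1e-6,
#' 200 epochs at batch size 32, last-15% validation split, and dropout 0.5
#' at the two deepest levels of a depth-4, base-32 U-Net on 256 x 256 input.
#'
#' @param depth encoder levels (>= 2).
#' @param base_filters filters at the first level, doubling per level.
#' @param input_size input edge length; must be divisible by `2^depth`.
#' @param dropout_rate dropout at the deepest encoder level and bottleneck.
#' @param lr_init,lr_factor,lr_min,plateau_patience learning-rate schedule.
#' @param epochs,batch_size training length and batch size.
#' @param val_fraction validation fraction (patient granularity).
#' @param aug an [augment_bounds()]; `NULL` disables augmentation.
#' @param fg_prior expected foreground fraction; the output bias is
#'   initialized to its logit so untrained predictions start near the organ
#'   prior instead of 0.5 (stabilizes training under extreme class
#'   imbalance).
#' @param seed integer seed controlling initialization, shuffling,
#'   augmentation and dropout.
#' @return list of class `model_params`.
#' @export
model_params <- function(depth = 4, base_filters = 32, input_size = 256,
                         dropout_rate = 0.5, lr_init = 5e-5, lr_factor = 0.25,
                         lr_min = 1e-6, plateau_patience = 10, epochs = 200,
                         batch_size = 32, val_fraction = 0.15,
                         aug = augment_bounds(), fg_prior = 0.01, seed = 1L) {
  stopifnot(depth >= 2, base_filters >= 1, batch_size >= 1,
            lr_min > 0, lr_min <= lr_init, lr_factor > 0, lr_factor < 1,
            epochs >= 1, fg_prior > 0, fg_prior < 1)
  structure(list(depth = depth, base_filters = base_filters,
                 input_size = input_size, dropout_rate = dropout_rate,
                 lr_init = lr_init, lr_factor = lr_factor, lr_min = lr_min,
                 plateau_patience = plateau_patience, epochs = epochs,
                 batch_size = batch_size, val_fraction = val_fraction,
                 aug = aug, fg_prior = fg_prior,
                 seed = as.integer(seed)), class = "model_params")
}

#' Per-organ configuration
#'
#' Window preset, axial-limit behavior and (once fitted) organ height
#' statistics for one organ at risk.  The spinal cord and brachial plexus
#' use the bone window; every other organ the tissue window.  The axial
#' height limit (mean + k standard deviations of training-set organ height)
#' applies only to the parotid glands, submandibular glands, brainstem and
#' larynx.
#'
#' @param name organ name (matched case-insensitively against ROI names).
#' @param window `"tissue"` or `"bone"`.
#' @param axial_k `1` or `2` (SD multiplier), or `NA` for organs without an
#'   axial limit.
#' @param height_mean,height_sd organ height statistics in mm (filled by
#'   [fit_height_stats()] at training time).
#' @return list of class `organ_config`.
#' @export
organ_config <- function(name, window = c("tissue", "bone"), axial_k = NA,
                         height_mean = NA_real_, height_sd = NA_real_) {
  window <- match.arg(window)
  if (!is.na(axial_k) && !axial_k %in% c(1, 2))
    stop("axial_k must be 1, 2 or NA")
  if (!is.na(height_mean) && height_mean < 0) stop("height stats must be nonnegative")
  structure(list(name = name, window = window, axial_k = axial_k,
                 height_mean = height_mean, height_sd = height_sd),
            class = "organ_config")
}

#' Shipped configurations for the 11 organs at risk
#'
#' @return named list of [organ_config()]s: brain, brainstem, both cochleae,
#'   both parotid and submandibular glands, larynx, spinal cord and brachial
#'   plexus.
#' @export
default_organ_configs <- function() {
  bone <- c("spinal_cord", "brachial_plexus")
  limited <- c("parotid_l", "parotid_r", "submandibular_l", "submandibular_r",
               "brainstem", "larynx")
  organs <- c("brain", "brainstem", "cochlea_l", "cochlea_r", "parotid_l",
              "parotid_r", "submandibular_l", "submandibular_r", "larynx",
              "spinal_cord", "brachial_plexus")
  out <- lapply(organs, function(o) organ_config(
    o, window = if (o %in% bone) "bone" else "tissue",
    axial_k = if (o %in% limited) 2 else NA))
  names(out) <- organs
  out
}

# ---------------------------------------------------------------------------
# network construction
# ---------------------------------------------------------------------------

# Weight shapes in the fixed list layout shared with the C++ engine.
unet_weight_shapes <- function(depth, base) {
  ch <- function(l) base * 2^(l - 1)
  shapes <- list()
  add <- function(nm, d) shapes[[nm]] <<- d
  prev <- 1
  for (l in seq_len(depth)) {
    add(sprintf("enc%d_conv1", l), c(ch(l), 9 * prev))
    add(sprintf("enc%d_conv2", l), c(ch(l), 9 * ch(l)))
    prev <- ch(l)
  }
  cb <- base * 2^depth
  add("bot_conv1", c(cb, 9 * prev))
  add("bot_conv2", c(cb, 9 * cb))
  below <- cb
  for (l in rev(seq_len(depth))) {
    add(sprintf("dec%d_up", l), c(ch(l), 4 * below))
    add(sprintf("dec%d_conv1", l), c(ch(l), 9 * 2 * ch(l)))
    add(sprintf("dec%d_conv2", l), c(ch(l), 9 * ch(l)))
    below <- ch(l)
  }
  add("out", c(1, base))
  shapes
}

#' Build a per-organ 2D U-Net
#'
#' Encoder-decoder with skip connections at every level, 3x3 convolutions
#' (ReLU), 2x2 max pooling, 2x2 stride-2 transposed-convolution upsampling,
#' dropout at the two deepest levels, and a single-channel sigmoid output.
#' Initialization is Glorot-uniform from the seed in `params`, so two builds
#' with equal params are identical.
#'
#' @param params a [model_params()].
#' @return object of class `oar_unet` holding the weight list and params.
#' @export
build_unet <- function(params = model_params()) {
  if (params$input_size %% 2^params$depth != 0)
    stop("input_size must be divisible by 2^depth")
  shapes <- unet_weight_shapes(params$depth, params$base_filters)
  set.seed(params$seed)
  weights <- list()
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    limit <- sqrt(6 / (d[2] + d[1]))
    weights[[length(weights) + 1]] <- matrix(runif(prod(d), -limit, limit), d[1], d[2])
    bias <- numeric(d[1])
    # Foreground-prior initialization of the output bias: organs occupy a
    # tiny fraction of a 256x256 field, and starting the sigmoid at ~0.5
    # makes the first epochs slam every logit far negative, saturating the
    # Dice gradient (an all-background local optimum).  Starting at the
    # prior removes that transient.
    if (nm == "out") bias[] <- log(params$fg_prior / (1 - params$fg_prior))
    weights[[length(weights) + 1]] <- bias
  }
  structure(list(weights = weights, params = params, organ = NULL,
                 history = NULL), class = "oar_unet")
}

#' @export
print.oar_unet <- function(x, ...) {
  npar <- sum(vapply(x$weights, length, 0))
  cat(sprintf("<oar_unet> depth %d, base %d filters, %d x %d input, %s parameters\n",
              x$params$depth, x$params$base_filters, x$params$input_size,
              x$params$input_size, format(npar, big.mark = ",")))
  if (!is.null(x$organ)) cat("  organ:", x$organ, "\n")
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final val loss %.4f\n",
                nrow(x$history), x$history$val_loss[nrow(x$history)]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# loss
# ---------------------------------------------------------------------------

#' Combined Dice + binary cross-entropy loss
#'
#' `L = (1 - (2 sum(Y P) + s) / (sum(Y) + sum(P) + s)) + mean(-(Y log Pc +
#' (1-Y) log(1-Pc)))` with smoothing `s = 1e-6` and `Pc` the predictions
#' clipped to `[1e-7, 1 - 1e-7]`.  The Dice term uses raw (unclipped)
#' probabilities so perfect agreement on absence scores ~0; smoothing in
#' numerator and denominator defines the empty-empty case.
#'
#' @param y binary ground-truth array.
#' @param p predicted probabilities in `[0, 1]`, same shape.
#' @return scalar loss with attributes `dice_term` and `bce_term`.
#' @export
combined_loss <- function(y, p) {
  if (!identical(dim(y) %||% length(y), dim(p) %||% length(p)))
    stop("shape mismatch between truth and prediction")
  s <- 1e-6; eps <- 1e-7
  y <- as.numeric(y); p <- as.numeric(p)
  dice <- 1 - (2 * sum(y * p) + s) / (sum(y) + sum(p) + s)
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- mean(-(y * log(pc) + (1 - y) * log(1 - pc)))
  structure(dice + bce, dice_term = dice, bce_term = bce)
}

# ---------------------------------------------------------------------------
# augmentation
# ---------------------------------------------------------------------------

#' Sample one set of augmentation parameters
#'
#' Draws rotation, per-axis translation, zoom and shear uniformly within the
#' bounds, from R's RNG (five draws, in that order).
#'
#' @param bounds an [augment_bounds()].
#' @return list(rotation_deg, trans_row_frac, trans_col_frac, zoom, shear_deg).
#' @export
sample_augment_params <- function(bounds = augment_bounds()) {
  list(rotation_deg = runif(1, -1, 1) * bounds$max_rotation_deg,
       trans_row_frac = runif(1, -1, 1) * bounds$max_translation_frac,
       trans_col_frac = runif(1, -1, 1) * bounds$max_translation_frac,
       zoom = 1 + runif(1, -1, 1) * bounds$max_zoom_frac,
       shear_deg = runif(1, -1, 1) * bounds$max_shear_deg)
}

# Inverse affine (output pixel -> input pixel) for given parameters; the
# forward map is zoom * rotation * shear about the image center plus
# translation in pixels.
augment_affine <- function(par, size) {
  d2r <- pi / 180
  rot <- par$rotation_deg * d2r
  sh <- tan(par$shear_deg * d2r)
  z <- par$zoom
  M <- z * matrix(c(cos(rot), -sin(rot),
                    sin(rot) + sh * cos(rot), cos(rot) - sh * sin(rot)), 2, 2)
  t_fwd <- c(par$trans_row_frac, par$trans_col_frac) * size
  A <- solve(M)
  list(A = A, t = as.numeric(-A %*% t_fwd))
}

#' Apply one random affine augmentation to an image/label pair
#'
#' A single transform (rotation, translation, zoom, shear within `bounds`)
#' is applied identically to both: the image is interpolated bilinearly, the
#' label nearest-neighbor so it stays binary.  All-zero bounds give the
#' identity.
#'
#' @param image,label matching 2D arrays.
#' @param bounds an [augment_bounds()].
#' @param params optional pre-sampled [sample_augment_params()] output.
#' @return list(image, label).
#' @export
augment_pair <- function(image, label, bounds = augment_bounds(), params = NULL) {
  stopifnot(identical(dim(image), dim(label) %||% dim(image)))
  if (is.null(params)) params <- sample_augment_params(bounds)
  aff <- augment_affine(params, nrow(image))
  out <- .cpp_warp_pair(image, matrix(as.integer(label), nrow(image)),
                        aff$A, aff$t)
  out$label <- out$label > 0
  dim(out$label) <- dim(image)
  out
}

# ---------------------------------------------------------------------------
# learning-rate plateau schedule
# ---------------------------------------------------------------------------

# One scheduler step: strict-improvement criterion, patience epochs of no
# improvement multiply lr by `factor`, floored at `lr_min`.
plateau_step <- function(state, val_loss, factor, patience, lr_min) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- max(state$lr * factor, lr_min)
      state$wait <- 0L
    }
  }
  state
}

#' Learning rate per epoch for a validation-loss series
#'
#' Replays the reduce-on-plateau rule over a recorded series: the learning
#' rate used *at* epoch i, starting from `lr_init`, multiplied by `factor`
#' after each run of `patience` epochs without validation improvement,
#' never below `lr_min`.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param lr_init,factor,patience,lr_min schedule parameters.
#' @return numeric vector of learning rates, one per epoch.
#' @export
plateau_lr_sequence <- function(val_losses, lr_init = 5e-5, factor = 0.25,
                                patience = 10, lr_min = 1e-6) {
  state <- list(lr = lr_init, best = Inf, wait = 0L)
  out <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    out[i] <- state$lr
    state <- plateau_step(state, val_losses[i], factor, patience, lr_min)
  }
  out
}

# ---------------------------------------------------------------------------
# training and inference
# ---------------------------------------------------------------------------

samples_to_arrays <- function(samples, size) {
  n <- length(samples)
  images <- array(0, c(size, size, n))
  labels <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    images[, , i] <- samples[[i]]$image
    labels[, , i] <- samples[[i]]$label
  }
  list(images = images, labels = labels)
}

#' Train a U-Net on preprocessed samples
#'
#' Adam optimization of [combined_loss()] with on-the-fly augmentation and
#' the reduce-on-plateau learning-rate schedule.  With a fixed seed the run
#' is reproducible on a fixed BLAS.
#'
#' @param train_samples,val_samples nonempty sample lists from
#'   [build_dataset()].
#' @param params a [model_params()].
#' @param model optionally, an existing [build_unet()] model to continue.
#' @param organ organ name recorded on the model.
#' @param verbose print per-epoch progress.
#' @return an `oar_unet` with trained weights and a `history` tibble
#'   (epoch, train_loss, val_loss, lr).
#' @export
train_unet <- function(train_samples, val_samples, params = model_params(),
                       model = NULL, organ = NULL, verbose = FALSE) {
  if (length(train_samples) == 0 || length(val_samples) == 0)
    stop("training and validation partitions must be nonempty")
  if (is.null(model)) model <- build_unet(params)
  size <- params$input_size
  tr <- samples_to_arrays(train_samples, size)
  va <- samples_to_arrays(val_samples, size)
  state <- list(
    m = lapply(model$weights, function(w) w * 0),
    v = lapply(model$weights, function(w) w * 0),
    t = 0L)
  sched <- list(lr = params$lr_init, best = Inf, wait = 0L)
  aug <- params$aug
  use_aug <- !is.null(aug) && any(unlist(aug) > 0)
  history <- vector("list", params$epochs)
  weights <- model$weights
  set.seed(params$seed + 1L)
  for (epoch in seq_len(params$epochs)) {
    ord <- sample.int(length(train_samples))
    res <- .cpp_unet_epoch(weights, state, tr$images, tr$labels, ord,
                           params$batch_size, sched$lr, params$depth,
                           params$base_filters, params$dropout_rate,
                           use_aug,
                           if (use_aug) aug$max_rotation_deg else 0,
                           if (use_aug) aug$max_translation_frac else 0,
                           if (use_aug) aug$max_zoom_frac else 0,
                           if (use_aug) aug$max_shear_deg else 0)
    weights <- res$weights
    state <- res$state
    vp <- .cpp_unet_predict(weights, va$images, params$depth,
                            params$base_filters, params$batch_size)
    val_loss <- mean(vapply(seq_len(dim(va$images)[3]), function(i)
      as.numeric(combined_loss(va$labels[, , i], vp[, , i])), 0))
    history[[epoch]] <- c(epoch = epoch, train_loss = res$loss,
                          val_loss = val_loss, lr = sched$lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.3g",
                      epoch, res$loss, val_loss, sched$lr))
    sched <- plateau_step(sched, val_loss, params$lr_factor,
                          params$plateau_patience, params$lr_min)
  }
  model$weights <- weights
  model$params <- params
  model$organ <- organ
  model$history <- tibble::as_tibble(do.call(rbind, history))
  model
}

#' Run a trained network over a CT volume
#'
#' Each slice is preprocessed (resample to 1 mm, center crop, the organ's
#' window), inferred independently, and the probability map is mapped back
#' onto the native CT grid (inverse crop, then inverse resample; the region
#' outside the crop gets probability 0).
#'
#' @param model a trained `oar_unet`.
#' @param volume a [ct_volume].
#' @param organ an [organ_config()] naming the window preset.
#' @return object of class `prediction_volume`: list(probs, organ, ct_ref).
#' @export
predict_volume <- function(model, volume, organ) {
  size <- model$params$input_size
  prep <- preprocess_volume(volume, window_preset(organ$window), size)
  probs256 <- .cpp_unet_predict(model$weights, prep$images, model$params$depth,
                                model$params$base_filters,
                                model$params$batch_size)
  d <- dim(volume$voxels)
  sp <- volume$pixel_spacing
  probs <- array(0, d)
  # native pixel (r, c) center -> resampled coords (r*sp_r, c*sp_c) ->
  # cropped coords minus offsets
  rows <- (seq_len(d[1]) - 1) * sp[1] - prep$offsets["row"]
  cols <- (seq_len(d[2]) - 1) * sp[2] - prep$offsets["col"]
  for (s in seq_len(d[3]))
    probs[, , s] <- .cpp_sample_bilinear(probs256[, , s], rows, cols)
  structure(list(probs = probs, organ = organ$name,
                 ct_ref = list(series_uid = volume$series_uid,
                               dim = d)),
            class = "prediction_volume")
}

#' @export
print.prediction_volume <- function(x, ...) {
  cat(sprintf("<prediction_volume> organ '%s', %s grid, prob mass %.1f voxels\n",
              x$organ, paste(x$ct_ref$dim, collapse = " x "), sum(x$probs)))
  invisible(x)
}

#' Tidy per-epoch training history
#'
#' @param x a trained `oar_unet`.
#' @param ... unused.
#' @return tibble with epoch, train_loss, val_loss, lr.
#' @export
tidy.oar_unet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  x$history
}

#' One-row training summary
#'
#' @param x a trained `oar_unet`.
#' @param ... unused.
#' @return tibble with epochs trained, final/best losses and final lr.
#' @export
glance.oar_unet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  tibble::tibble(epochs = nrow(h),
                 final_train_loss = h$train_loss[nrow(h)],
                 final_val_loss = h$val_loss[nrow(h)],
                 best_val_loss = min(h$val_loss),
                 final_lr = h$lr[nrow(h)])
}
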