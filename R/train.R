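#' Training configuration
#'
#' Houses the adversarial training hyper-parameters: Adam with learning rate
#' 0.0002 and beta1 0.5 for both models, binary cross-entropy adversarial
#' loss, and the combined generator objective
#' `adversarial + lambda * L1` with `lambda = 100` by default. Batch size is
#' 1.
#'
#' @param lambda weight of the L1 term in the generator objective (>= 0).
#' @param learning_rate Adam learning rate (> 0).
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param steps total optimization steps; if `NULL`, derived from `epochs`.
#' @param epochs passes over the training set (used when `steps` is `NULL`).
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @param real_label,fake_label target labels for the discriminator.
#' @param checkpoint_every write a checkpoint every this many steps (`Inf`
#'   disables intermediate checkpoints).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lambda = 100, learning_rate = 2e-4,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         steps = NULL, epochs = 1L, seed = 1L,
                         real_label = 1, fake_label = 0,
                         checkpoint_every = Inf) {
  if (lambda < 0) stop("train.lambda must be >= 0")
  if (learning_rate <= 0) stop("train.learning_rate must be > 0")
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = 1L, steps = steps, epochs = epochs,
                 seed = as.integer(seed), real_label = real_label,
                 fake_label = fake_label, checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Mean absolute (L1) loss
#'
#' @param generated,target numeric arrays of identical shape.
#' @return Mean absolute difference over all pixels and channels.
#' @export
l1_loss <- function(generated, target) {
  stopifnot(all(dim(generated) == dim(target)))
  mean(abs(generated - target))
}

#' Mean binary cross-entropy of a patch grid against a constant label
#'
#' Predictions are clipped to `(eps, 1 - eps)` before the log.
#'
#' @param patch_predictions array of probabilities in `(0, 1)`.
#' @param label constant target label (typically 0 or 1).
#' @param eps clipping constant.
#' @return Non-negative scalar loss.
#' @export
adversarial_loss <- function(patch_predictions, label, eps = 1e-7) {
  p <- pmin(pmax(patch_predictions, eps), 1 - eps)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

# target image the generator regresses to: the binary mask replicated to the
# generator's output channels, in model range [-1, 1]
mask_to_target <- function(mask, channels = 3L) {
  to_model_range(array(rep(mask, channels), c(dim(mask), channels)))
}

#' Initialize a cGAN trainer
#'
#' Builds generator and discriminator from their specs (seeded from
#' `config$seed`) together with one Adam state per model. The returned
#' trainer is threaded functionally through [discriminator_step()] and
#' [generator_step()].
#'
#' @param gen_spec a [generator_spec()].
#' @param disc_spec a [discriminator_spec()].
#' @param config a [train_config()].
#' @return An object of class `cgan_trainer`.
#' @export
cgan_trainer <- function(gen_spec = generator_spec(),
                         disc_spec = discriminator_spec(),
                         config = train_config()) {
  set.seed(config$seed)
  G <- build_generator(gen_spec)
  D <- build_discriminator(disc_spec)
  structure(list(G = G, D = D, config = config,
                 opt_G = adam_init(G$params), opt_D = adam_init(D$params),
                 step = 0L),
            class = "cgan_trainer")
}

prepare_tensors <- function(trainer, pair) {
  list(src = to_model_range(pair$image),
       tgt = mask_to_target(pair$mask, trainer$G$spec$output_channels))
}

#' One discriminator update
#'
#' Trains D on the real pair `(source, target) -> real_label` and on the
#' generated pair `(source, G(source)) -> fake_label` with mean binary
#' cross-entropy, applying a single Adam update to D only; G is untouched.
#'
#' @param trainer a [cgan_trainer()].
#' @param pair an [image_pair()].
#' @return List with the updated `trainer` and `losses = c(real, fake)`.
#' @export
discriminator_step <- function(trainer, pair) {
  cfg <- trainer$config
  tens <- prepare_tensors(trainer, pair)
  fake <- gen_forward(trainer$G, tens$src, training = TRUE)$out

  fw_r <- disc_forward(trainer$D, tens$src, tens$tgt, want_cache = TRUE)
  loss_real <- adversarial_loss(fw_r$patch, cfg$real_label)
  dz_r <- (fw_r$patch - cfg$real_label) / length(fw_r$patch)
  g_r <- disc_backward(trainer$D, fw_r$cache, dz_r)$grads

  fw_f <- disc_forward(trainer$D, tens$src, fake, want_cache = TRUE)
  loss_fake <- adversarial_loss(fw_f$patch, cfg$fake_label)
  dz_f <- (fw_f$patch - cfg$fake_label) / length(fw_f$patch)
  g_f <- disc_backward(trainer$D, fw_f$cache, dz_f)$grads

  # combined objective (loss_real + loss_fake) / 2 -> average the gradients
  grads <- param_map2(g_r, g_f, function(a, b) (a + b) / 2)
  upd <- adam_update(trainer$D$params, grads, trainer$opt_D,
                     cfg$learning_rate, cfg$adam_beta1, cfg$adam_beta2)
  trainer$D$params <- upd$params
  trainer$opt_D <- upd$state
  list(trainer = trainer, losses = c(real = loss_real, fake = loss_fake))
}

#' One generator update
#'
#' Updates G through the stacked model: minimizes
#' `BCE(D(source, G(source)), real_label) + lambda * L1(G(source), target)`
#' with a single Adam update to G only; D's weights are unchanged.
#'
#' @param trainer a [cgan_trainer()].
#' @param pair an [image_pair()].
#' @return List with the updated `trainer` and `losses = c(adv, l1)`.
#' @export
generator_step <- function(trainer, pair) {
  cfg <- trainer$config
  tens <- prepare_tensors(trainer, pair)
  fw_g <- gen_forward(trainer$G, tens$src, training = TRUE, want_cache = TRUE)
  fake <- fw_g$out

  fw_d <- disc_forward(trainer$D, tens$src, fake, want_cache = TRUE)
  adv <- adversarial_loss(fw_d$patch, cfg$real_label)
  dz <- (fw_d$patch - cfg$real_label) / length(fw_d$patch)
  g_fake_adv <- disc_backward(trainer$D, fw_d$cache, dz,
                              want_input_grad = TRUE)$g_target

  l1 <- l1_loss(fake, tens$tgt)
  g_fake_l1 <- sign(fake - tens$tgt) / length(fake)

  g_fake <- g_fake_adv + cfg$lambda * g_fake_l1
  grads <- gen_backward(trainer$G, fw_g$cache, g_fake)
  upd <- adam_update(trainer$G$params, grads, trainer$opt_G,
                     cfg$learning_rate, cfg$adam_beta1, cfg$adam_beta2)
  trainer$G$params <- upd$params
  trainer$opt_G <- upd$state
  list(trainer = trainer, losses = c(adv = adv, l1 = l1))
}

#' Train the conditional GAN
#'
#' Alternates [discriminator_step()] and [generator_step()] over seeded
#' shuffles of the training pairs, logging the per-step losses. Fully
#' reproducible given `config$seed` on one device.
#'
#' @param pairs a list of [image_pair()] objects, or a [dataset_manifest()]
#'   (loaded at the generator's input size).
#' @param gen_spec a [generator_spec()].
#' @param disc_spec a [discriminator_spec()].
#' @param config a [train_config()]; `steps` (or `epochs`) sets the length
#'   of the run.
#' @param out_dir if non-`NULL`, checkpoints (per `config$checkpoint_every`
#'   and at the end) and `history.csv` are written here.
#' @param verbose print a progress line every 100 steps.
#' @return List with `trainer` (final models and optimizer states) and
#'   `history` (data frame: step, epoch, g_loss, g_adv, g_l1, d_loss_real,
#'   d_loss_fake).
#' @export
fit_cgan <- function(pairs, gen_spec = tiny_generator_spec(),
                     disc_spec = tiny_discriminator_spec(),
                     config = train_config(), out_dir = NULL,
                     verbose = FALSE) {
  if (inherits(pairs, "dataset_manifest")) {
    sz <- gen_spec$input_size
    pairs <- load_manifest_pairs(pairs, target_size = c(sz, sz))
  }
  n <- length(pairs)
  if (n == 0L) stop("cannot train on an empty dataset")
  trainer <- cgan_trainer(gen_spec, disc_spec, config)
  steps <- if (!is.null(config$steps)) config$steps else config$epochs * n

  hist <- vector("list", steps)
  order <- integer(0)
  epoch <- 0L
  for (s in seq_len(steps)) {
    if (length(order) == 0L) {
      epoch <- epoch + 1L
      order <- sample.int(n)
    }
    idx <- order[1L]
    order <- order[-1L]
    pair <- pairs[[idx]]
    d <- discriminator_step(trainer, pair)
    trainer <- d$trainer
    g <- generator_step(trainer, pair)
    trainer <- g$trainer
    trainer$step <- s
    hist[[s]] <- data.frame(
      step = s, epoch = epoch,
      g_loss = g$losses[["adv"]] + config$lambda * g$losses[["l1"]],
      g_adv = g$losses[["adv"]], g_l1 = g$losses[["l1"]],
      d_loss_real = d$losses[["real"]], d_loss_fake = d$losses[["fake"]])
    if (verbose && s %% 100L == 0L)
      message(sprintf("step %d/%d  g_l1 %.4f  d_real %.4f  d_fake %.4f",
                      s, steps, g$losses[["l1"]], d$losses[["real"]],
                      d$losses[["fake"]]))
    if (!is.null(out_dir) && is.finite(config$checkpoint_every) &&
        s %% config$checkpoint_every == 0L)
      save_checkpoint(list(G = trainer$G, D = trainer$D),
                      file.path(out_dir, sprintf("checkpoint_%06d", s)),
                      meta = list(seed = config$seed, step = s))
  }
  history <- do.call(rbind, hist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(list(G = trainer$G, D = trainer$D),
                    file.path(out_dir, "checkpoint_final"),
                    meta = list(seed = config$seed, step = steps))
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(trainer = trainer, history = history)
}

#' Predict a segmentation image for one dermoscopic image
#'
#' Runs the generator on a `[-1, 1]`-scaled copy of the image and maps the
#' tanh output back to `[0, 1]`. By default the pass is deterministic
#' (dropout off). `deterministic = FALSE` keeps dropout active — the
#' model's noise source — in which case a seed is required so results stay
#' reproducible.
#'
#' @param G a `cgan_generator`.
#' @param image array `H x W x 3` in `[0, 1]`.
#' @param deterministic disable dropout for the forward pass.
#' @param seed integer seed for the dropout draw (stochastic mode only).
#' @return Generated image, `H x W x output_channels` in `[0, 1]`.
#' @export
predict_mask <- function(G, image, deterministic = TRUE, seed = NULL) {
  if (!deterministic) {
    if (is.null(seed)) stop("stochastic prediction requires a seed")
    set.seed(seed)
  }
  x <- to_model_range(image)
  out <- gen_forward(G, x, training = !deterministic)$out
  from_model_range(out)
}
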