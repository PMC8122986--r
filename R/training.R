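# Two-stage training (L1 pretraining, then relativistic GAN fine-tuning)
# and the two-pass volume reconstruction pipeline.

#' Training configuration
#'
#' @param stage `"pretrain_l1"` or `"gan_finetune"`.
#' @param batch_size patches per step (default 16).
#' @param lr Adam learning rate (defaults: 1e-4 for stage 1, 1e-5 for the
#'   GAN stage).
#' @param iters optimisation steps.
#' @param seed RNG seed threading data shuffling, weight init and noise.
#' @param generator_spec a [generator_spec()].
#' @param weights a [loss_weights()] (GAN stage).
#' @param extractor perceptual feature extractor (GAN stage; default
#'   identity).
#' @param checkpoint_dir directory for checkpoints, or `NULL` to skip
#'   writing.
#' @return a `train_config` list.
#' @export
train_config <- function(stage = c("pretrain_l1", "gan_finetune"),
                         batch_size = 16, lr = NULL, iters = 200, seed = 1,
                         generator_spec = mrisr::generator_spec(),
                         weights = loss_weights(),
                         extractor = identity_extractor(),
                         checkpoint_dir = NULL) {
  stage <- match.arg(stage)
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (is.null(lr)) lr <- if (stage == "pretrain_l1") 1e-4 else 1e-5
  structure(list(stage = stage, batch_size = as.integer(batch_size), lr = lr,
                 iters = as.integer(iters), seed = as.integer(seed),
                 generator_spec = generator_spec, weights = weights,
                 extractor = extractor, checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# stack a list of patch pairs into (H, W, N, 1) input/target batches
batch_arrays <- function(pairs, idx) {
  lr1 <- pairs[[idx[1]]]$lr
  hr1 <- pairs[[idx[1]]]$hr
  x <- array(0, c(dim(lr1), length(idx), 1))
  y <- array(0, c(dim(hr1), length(idx), 1))
  for (j in seq_along(idx)) {
    x[, , j, 1] <- pairs[[idx[j]]]$lr
    y[, , j, 1] <- pairs[[idx[j]]]$hr
  }
  list(x = x, y = y)
}

maybe_checkpoint <- function(gen, dir, step) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_checkpoint(gen, file.path(dir, sprintf("ckpt_%06d.rds", step)))
}

#' Stage-1 pretraining: pixel L1 only
#'
#' Initialises (or resumes) a generator and minimises the mean absolute
#' error between its output and the HR patches with Adam. Deterministic
#' under `cfg$seed`.
#'
#' @param pairs list of `patch_pair`s (from [make_patch_pairs()]).
#' @param cfg a [train_config()].
#' @param generator optional existing `sr_generator` to resume from.
#' @return list with `generator`, `losses` (per-step L1 curve) and
#'   `checkpoint` (path or `NULL`).
#' @export
train_stage1 <- function(pairs, cfg = train_config("pretrain_l1"),
                         generator = NULL) {
  if (length(pairs) < 1) stop("empty patch dataset")
  gen <- if (is.null(generator))
    build_generator(cfg$generator_spec, seed = cfg$seed) else generator
  opt <- adam_init(gen, lr = cfg$lr)
  losses <- numeric(cfg$iters)
  if (cfg$iters > 0) with_seed(cfg$seed + 1L, {
    for (it in seq_len(cfg$iters)) {
      idx <- sample.int(length(pairs), min(cfg$batch_size, length(pairs)))
      b <- batch_arrays(pairs, idx)
      out <- gen$fwd(b$x, train = TRUE)
      losses[it] <- pixel_l1(out, b$y)
      zero_grads(gen)
      gen$bwd(array(pixel_l1_grad(out, b$y), dim(out)))
      opt <- adam_step(opt)
    }
  })
  ck <- maybe_checkpoint(gen, cfg$checkpoint_dir, cfg$iters)
  list(generator = gen, losses = losses, checkpoint = ck)
}

#' Stage-2 GAN fine-tuning
#'
#' Starts from a stage-1 generator (checkpoint path or object) and a fresh
#' discriminator, alternating discriminator and generator steps. The
#' discriminator minimises the relativistic-average loss on (real, fake)
#' logit batches; the generator minimises
#' `L_percep + lambda * L_adv + eta * L1`. Per-step term breakdowns are
#' returned.
#'
#' @param pairs list of `patch_pair`s.
#' @param cfg a [train_config()] with `stage = "gan_finetune"`.
#' @param stage1 stage-1 checkpoint path or `sr_generator`; required.
#' @param d_spec [discriminator_spec()] sized to the HR patches.
#' @param d_only train only the discriminator against the fixed generator.
#' @return list with `generator`, `discriminator`, `g_losses` (data.frame of
#'   per-term values) and `d_losses`.
#' @export
train_gan <- function(pairs, cfg = train_config("gan_finetune"),
                      stage1, d_spec = NULL, d_only = FALSE) {
  if (length(pairs) < 1) stop("empty patch dataset")
  if (missing(stage1) || is.null(stage1))
    stop("GAN fine-tuning requires a stage-1 generator or checkpoint")
  gen <- if (inherits(stage1, "sr_generator")) stage1
         else load_checkpoint(stage1)
  hr_side <- nrow(pairs[[1]]$hr)
  if (is.null(d_spec))
    d_spec <- discriminator_spec(feature_widths = c(16, 32, 64, 128),
                                 input_size = hr_side, fc_width = 32)
  disc <- build_discriminator(d_spec, seed = cfg$seed + 7L)
  opt_g <- adam_init(gen, lr = cfg$lr)
  opt_d <- adam_init(disc, lr = cfg$lr)
  g_log <- vector("list", cfg$iters)
  d_losses <- numeric(cfg$iters)
  with_seed(cfg$seed + 2L, {
    for (it in seq_len(cfg$iters)) {
      idx <- sample.int(length(pairs), min(cfg$batch_size, length(pairs)))
      b <- batch_arrays(pairs, idx)
      n <- dim(b$x)[3]

      # --- discriminator step (generator fixed) ---
      fake <- gen$fwd(b$x, train = FALSE)
      both <- array(0, c(dim(b$y)[1:2], 2 * n, 1))
      both[, , seq_len(n), ] <- b$y
      both[, , n + seq_len(n), ] <- fake
      logits <- disc$fwd(both, train = TRUE)
      lr_ <- logits[seq_len(n)]; lf_ <- logits[n + seq_len(n)]
      d_losses[it] <- adversarial_d_loss(lr_, lf_)
      gd <- adversarial_d_grad(lr_, lf_)
      zero_grads(disc)
      disc$bwd(c(gd$real, gd$fake))
      opt_d <- adam_step(opt_d)

      # --- generator step (discriminator fixed) ---
      if (!d_only) {
        fake <- gen$fwd(b$x, train = TRUE)
        both[, , n + seq_len(n), ] <- fake
        logits <- disc$fwd(both, train = TRUE)
        lr_ <- logits[seq_len(n)]; lf_ <- logits[n + seq_len(n)]
        gl <- generator_total(fake, b$y, lr_, lf_, cfg$weights,
                              cfg$extractor)
        g_log[[it]] <- data.frame(step = it, total = gl$total,
                                  percep = gl$terms$percep,
                                  adv = gl$terms$adv,
                                  pixel = gl$terms$pixel)
        gg <- adversarial_g_grad(lr_, lf_)
        zero_grads(disc)
        dboth <- disc$bwd(c(numeric(n), cfg$weights$lambda_adv * gg$fake))
        dfake_adv <- dboth[, , n + seq_len(n), , drop = FALSE]
        feat_sr <- cfg$extractor$forward(fake)
        feat_hr <- cfg$extractor$forward(b$y)
        dfake <- cfg$extractor$backward(fake,
                                        pixel_l1_grad(feat_sr, feat_hr)) +
          cfg$weights$eta_pix * pixel_l1_grad(fake, b$y) + dfake_adv
        zero_grads(gen)
        gen$bwd(array(dfake, dim(fake)))
        opt_g <- adam_step(opt_g)
        zero_grads(disc)
      }
    }
  })
  ck <- maybe_checkpoint(gen, cfg$checkpoint_dir, cfg$iters)
  list(generator = gen, discriminator = disc,
       g_losses = if (d_only) NULL else do.call(rbind, g_log),
       d_losses = d_losses, checkpoint = ck)
}

# run a generator over every slice of a stack
sr_stack <- function(stack, gen, stochastic = FALSE) {
  lapply(stack$slices, function(s) gen$predict(s, stochastic = stochastic))
}

#' Apply the same-size restoration generator on selected planes
#'
#' Runs the stage-2 generator over every slice of each selected plane of the
#' rebuilt volume and merges the per-plane outputs with the rebuild merge
#' rule (mean by default). Full stacks are used, so no voxel is missing in
#' the result.
#'
#' @param rebuilt an `mri_volume` (or 3D array), typically the pass-1
#'   rebuild.
#' @param g2 a scale-1 `sr_generator`.
#' @param planes non-empty subset of the three planes.
#' @param merge `"mean"` or `"priority"`.
#' @param stochastic sample the noise injections (default `FALSE`:
#'   deterministic restoration).
#' @return restored `mri_volume`.
#' @export
second_pass_plane_policy <- function(rebuilt, g2,
                                     planes = PLANES,
                                     merge = "mean", stochastic = FALSE) {
  if (length(planes) < 1) stop("at least one plane must be selected")
  planes <- match.arg(planes, PLANES, several.ok = TRUE)
  vox <- if (inherits(rebuilt, "mri_volume")) rebuilt$voxels else rebuilt
  stacks <- lapply(planes, function(pl) {
    st <- extract_slices(vox, pl)
    st$slices <- sr_stack(st, g2, stochastic)
    st
  })
  rv <- rebuild(stacks, dim(vox), merge = merge)
  as_volume(rv$voxels, normalize = FALSE)
}

#' Two-pass volume reconstruction
#'
#' Pass 1: slice the half-resolution volume on all three planes, upscale
#' every slice x2 with the stage-1 generator, and rebuild at twice the shape
#' -- slices land on alternating indices, so 1/8 of the voxels (all-even
#' coordinates) are missing. Pass 2: run the stage-2 same-size generator
#' over every slice of the rebuilt volume on the selected planes and merge,
#' which fills the missing voxels and restores texture.
#'
#' @param lr_vol half-resolution `mri_volume` (e.g. 128x128x75).
#' @param g1 stage-1 `sr_generator` (scale 2).
#' @param g2 stage-2 `sr_generator` (scale 1), or `NULL` to fall back to the
#'   interpolation repair baseline for pass 2.
#' @param planes planes fed to pass 2 (default all three).
#' @param merge overlap merge rule.
#' @param return_intermediate also return the pass-1 `reassembled_volume`.
#' @return reconstructed `mri_volume` of shape `2 * dim(lr_vol)` (a list
#'   with `volume` and `pass1` if `return_intermediate`).
#' @export
reconstruct_volume <- function(lr_vol, g1, g2, planes = PLANES,
                               merge = "mean", return_intermediate = FALSE) {
  stopifnot(inherits(lr_vol, "mri_volume"))
  if (g1$spec$scale != 2)
    stop("pass-1 generator must have scale 2, got ", g1$spec$scale)
  if (!is.null(g2) && g2$spec$scale != 1)
    stop("pass-2 generator must have scale 1, got ", g2$spec$scale)
  target <- 2L * dim(lr_vol)
  stacks <- lapply(PLANES, function(pl) {
    st <- extract_slices(lr_vol, pl)
    sr <- sr_stack(st, g1)
    new_slice_stack(pl, sr, 2L * st$source_indices - 1L, target)
  })
  rv <- rebuild(stacks, target, merge = merge)
  out <- if (is.null(g2)) interpolation_repair(rv)
         else second_pass_plane_policy(rv$voxels, g2, planes, merge)
  if (return_intermediate) list(volume = out, pass1 = rv) else out
}
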