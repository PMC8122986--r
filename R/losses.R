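# Composite generator objective L_G = L_percep + lambda * L_adv + eta * L1
# with relativistic-average adversarial terms. All expectations are batch
# means; log arguments are clamped to [1e-8, 1] for numerical safety.

LOG_EPS <- 1e-8
clamp_log <- function(p) log(pmin(pmax(p, LOG_EPS), 1))

#' Loss term weights
#'
#' @param lambda_adv coefficient on the adversarial term (default 5e-3, the
#'   ESRGAN-lineage convention; the source text leaves it unstated).
#' @param eta_pix coefficient on the pixel L1 term (default 1e-2).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_adv = 5e-3, eta_pix = 1e-2) {
  if (lambda_adv < 0 || eta_pix < 0) stop("loss weights must be >= 0")
  structure(list(lambda_adv = lambda_adv, eta_pix = eta_pix),
            class = "loss_weights")
}

check_pair <- function(lr, lf) {
  if (length(lr) == 0 || length(lf) == 0) stop("empty logit batch")
  if (length(lr) != length(lf)) stop("real/fake batches differ in length")
  if (any(!is.finite(lr)) || any(!is.finite(lf))) stop("non-finite logits")
}

#' Mean absolute (L1) pixel loss
#' @param sr,hr arrays of identical shape.
#' @return scalar mean |sr - hr|.
#' @export
pixel_l1 <- function(sr, hr) {
  if (!identical(dim(sr) %||% length(sr), dim(hr) %||% length(hr)))
    stop("shape mismatch between sr and hr")
  mean(abs(sr - hr))
}

# gradient of pixel_l1 w.r.t. sr (subgradient 0 at ties)
pixel_l1_grad <- function(sr, hr) sign(sr - hr) / length(sr)

#' Identity feature extractor
#'
#' Makes the perceptual loss equal the pixel L1, for fully offline use. A
#' pretrained deep extractor (e.g. VGG-19 pre-activation features) can be
#' plugged in as any object with the same `$forward` / `$backward` contract.
#'
#' @return extractor with `$forward(x)` and `$backward(x, dfeat)`.
#' @export
identity_extractor <- function() {
  structure(list(forward = function(x) x,
                 backward = function(x, dfeat) dfeat,
                 name = "identity"),
            class = "feature_extractor")
}

#' Perceptual (feature-space L1) loss
#'
#' L1 distance between extractor features of the two images. The reference
#' configuration is pre-activation VGG-19 features; pretrained weights are a
#' pluggable dependency, never shipped -- without one, pass
#' [identity_extractor()] or train stage-1 (L1) only.
#'
#' @param sr,hr image arrays of identical shape.
#' @param extractor a feature extractor; `NULL` raises an explicit error.
#' @return scalar loss.
#' @export
perceptual_loss <- function(sr, hr, extractor = identity_extractor()) {
  if (is.null(extractor))
    stop("no feature extractor supplied: plug one in, use ",
         "identity_extractor(), or train stage-1 (L1) only")
  pixel_l1(extractor$forward(sr), extractor$forward(hr))
}

#' Relativistic-average adversarial losses
#'
#' With pre-sigmoid discriminator outputs `C(x)`, define
#' `D_rel(a | B) = sigmoid(C(a) - mean C(B))`. The generator loss is
#' `-E[log(1 - D_rel(real | fake))] - E[log(D_rel(fake | real))]`; the
#' discriminator loss swaps the roles. Both equal `2 log 2` when all logits
#' are equal, and only logit differences matter.
#'
#' @param logits_real,logits_fake numeric vectors of pre-sigmoid scores,
#'   equal length.
#' @return scalar loss.
#' @export
adversarial_g_loss <- function(logits_real, logits_fake) {
  check_pair(logits_real, logits_fake)
  d_real <- stats::plogis(logits_real - mean(logits_fake))
  d_fake <- stats::plogis(logits_fake - mean(logits_real))
  -mean(clamp_log(1 - d_real)) - mean(clamp_log(d_fake))
}

#' @rdname adversarial_g_loss
#' @export
adversarial_d_loss <- function(logits_real, logits_fake) {
  check_pair(logits_real, logits_fake)
  d_real <- stats::plogis(logits_real - mean(logits_fake))
  d_fake <- stats::plogis(logits_fake - mean(logits_real))
  -mean(clamp_log(d_real)) - mean(clamp_log(1 - d_fake))
}

# Analytic gradients of the relativistic losses w.r.t. both logit vectors.
# Derivation: with a_i = Cr_i - mean(Cf), b_j = Cf_j - mean(Cr),
#   L_G = -mean(log(1 - s(a))) - mean(log(s(b)))
#   dL/da_i = s(a_i)/n,  dL/db_j = -(1 - s(b_j))/n
# and the means couple the two vectors:
#   dL/dCr_i = s(a_i)/n + mean(1 - s(b))/n
#   dL/dCf_j = -(1 - s(b_j))/n - mean(s(a))/n
adversarial_g_grad <- function(logits_real, logits_fake) {
  n <- length(logits_real)
  sa <- stats::plogis(logits_real - mean(logits_fake))
  sb <- stats::plogis(logits_fake - mean(logits_real))
  list(real = sa / n + mean(1 - sb) / n,
       fake = -(1 - sb) / n - mean(sa) / n)
}

adversarial_d_grad <- function(logits_real, logits_fake) {
  n <- length(logits_real)
  sa <- stats::plogis(logits_real - mean(logits_fake))
  sb <- stats::plogis(logits_fake - mean(logits_real))
  # L_D = -mean(log(s(a))) - mean(log(1 - s(b)))
  list(real = -(1 - sa) / n - mean(sb) / n,
       fake = sb / n + mean(1 - sa) / n)
}

#' Composite generator loss with per-term breakdown
#'
#' `L = L_percep + lambda * L_adv + eta * L1`. In stage-1 mode
#' (`stage1 = TRUE`) the perceptual and adversarial terms are excluded and
#' the loss is the plain pixel L1 used for pretraining.
#'
#' @param sr,hr image arrays of identical shape.
#' @param logits_real,logits_fake discriminator logits (ignored in stage 1).
#' @param weights a [loss_weights()].
#' @param extractor feature extractor for the perceptual term.
#' @param stage1 if `TRUE`, return the pure L1 pretraining loss.
#' @return list with `total` and a `terms` breakdown.
#' @export
generator_total <- function(sr, hr, logits_real = NULL, logits_fake = NULL,
                            weights = loss_weights(),
                            extractor = identity_extractor(),
                            stage1 = FALSE) {
  l1 <- pixel_l1(sr, hr)
  if (stage1)
    return(list(total = l1,
                terms = list(percep = 0, adv = 0, pixel = l1)))
  lp <- perceptual_loss(sr, hr, extractor)
  la <- if (weights$lambda_adv > 0)
    adversarial_g_loss(logits_real, logits_fake) else 0
  list(total = lp + weights$lambda_adv * la + weights$eta_pix * l1,
       terms = list(percep = lp, adv = la, pixel = l1))
}
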