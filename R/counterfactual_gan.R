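# Unpaired translation between the COVID-negative domain X and the
# COVID-positive domain Y as dataset-level interpretability: two residual
# generators G: X -> Y and F: Y -> X trained against patch discriminators
# with the adversarial log losses plus an L1 cycle-consistency term
# (total = adversarial_G + adversarial_F + cycle, a plain unweighted sum).
# What the generators change — the difference map |G(x) - x| — reveals
# which image features separate the domains; feeding the counterfactuals
# back to the audited classifier gives the flip rate.

# Generators read the image plus two coordinate channels: a purely
# convolutional map is translation-invariant and could never place a
# glyph on featureless background, while the discriminator only needs to
# detect glyph texture anywhere, so coordinates go to the generator only.
new_generator <- function(image_size, n_filters = 8L, scale = 1) {
  g <- new.env(parent = emptyenv())
  g$net <- nn_network(list(
    nn_conv(3L, n_filters), nn_relu(),
    nn_conv(n_filters, n_filters), nn_relu(),
    nn_conv(n_filters, 1L), nn_tanh()
  ), c(image_size, image_size, 3L))
  # zero-init the residual head so the untrained map is exactly identity
  out_conv <- g$net$layers[[5L]]
  out_conv$W[] <- 0; out_conv$b[] <- 0
  g$scale <- scale
  s <- image_size
  g$coords <- array(c(matrix(seq_len(s) / s, s, s),
                      matrix(seq_len(s) / s, s, s, byrow = TRUE)),
                    c(s, s, 2L))
  g
}

# Discriminators also read coordinate channels: realism of a radiograph
# is position-dependent (a glyph is real only where that source prints
# it), and a translation-invariant patch critic could never punish
# features painted at the wrong position.
new_discriminator <- function(image_size, n_filters = 8L) {
  d <- new.env(parent = emptyenv())
  d$net <- nn_network(list(
    nn_conv(3L, n_filters), nn_relu(), nn_avgpool(),
    nn_conv(n_filters, 2L * n_filters), nn_relu(), nn_avgpool(),
    nn_conv(2L * n_filters, 1L)
  ), c(image_size, image_size, 3L))
  s <- image_size
  d$coords <- array(c(matrix(seq_len(s) / s, s, s),
                      matrix(seq_len(s) / s, s, s, byrow = TRUE)),
                    c(s, s, 2L))
  d
}

disc_forward <- function(d, img) {
  nn_forward(d$net, array(c(img, d$coords), c(nrow(img), ncol(img), 3L)))
}

# backward through a discriminator, optionally returning the image-channel
# input gradient
disc_backward <- function(d, caches, dlogits, accumulate = TRUE) {
  dx <- nn_backward(d$net, caches, dlogits, accumulate)
  dx[, , 1L]
}

gen_forward <- function(g, x) {
  xin <- array(c(x, g$coords), c(nrow(x), ncol(x), 3L))
  fw <- nn_forward(g$net, xin)
  list(out = matrix(x, nrow(x), ncol(x)) + g$scale * matrix(fw$out, nrow(x)),
       caches = fw$caches)
}

gen_backward <- function(g, caches, dy, accumulate = TRUE) {
  dnet <- array(dy * g$scale, c(dim(dy), 1L))
  dx <- nn_backward(g$net, caches, dnet, accumulate)
  dx[, , 1L] + dy  # coordinate channels carry no input gradient
}

#' Create an untrained cycle-translation system
#'
#' Residual generators (`G(x) = x + tanh(convnet(x, coords))`, a range
#' wide enough to paint or erase a radiopaque glyph over background, so
#' the untrained map starts near the identity; the conv stack sees two
#' extra coordinate channels so it can act position-specifically) and two
#' patch discriminators
#' whose conv stacks score overlapping receptive fields; `D(img)` is the
#' per-patch sigmoid probability map.
#'
#' @param image_size square image side.
#' @param n_filters channel width of the conv stacks.
#' @param seed integer seed for weight initialisation.
#' @param residual_scale amplitude of the generators' tanh residual.
#' @return object of class `gan_system` with `G`, `F_`, `D_X`, `D_Y`.
#' @export
gan_system <- function(image_size, n_filters = 8L, seed = 1L,
                       residual_scale = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(list(
    G = new_generator(image_size, n_filters, residual_scale),
    F_ = new_generator(image_size, n_filters, residual_scale),
    D_X = new_discriminator(image_size, n_filters),
    D_Y = new_discriminator(image_size, n_filters),
    image_size = as.integer(image_size), seed = as.integer(seed)
  ), class = "gan_system")
}

#' Translate an image across domains
#' @param system a `gan_system`.
#' @param image numeric matrix.
#' @param direction "neg2pos" applies G (X to Y); "pos2neg" applies F.
#' @return the translated image (same shape; not re-clipped).
#' @export
translate <- function(system, image, direction = c("neg2pos", "pos2neg")) {
  direction <- match.arg(direction)
  g <- if (direction == "neg2pos") system$G else system$F_
  gen_forward(g, image)$out
}

disc_prob <- function(dnet, image, clamp_warn = TRUE) {
  p <- sigmoid(disc_forward(dnet, image)$out)
  eps <- 1e-7
  if (any(p <= 0 | p >= 1)) {
    if (clamp_warn) warning("discriminator output clamped away from {0,1}")
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Evaluate the adversarial and cycle losses on fixed batches
#'
#' `l_gan_G = mean log D_Y(y) + mean log(1 - D_Y(G(x)))`,
#' `l_gan_F` symmetrically with F and D_X,
#' `l_cyc = mean |F(G(x)) - x|_1 + mean |G(F(y)) - y|_1` (per-image mean
#' absolute error), and `total` is exactly their sum. Discriminator
#' probabilities are clamped to (eps, 1-eps) before the log, with a
#' warning if clamping was needed.
#'
#' @param system a `gan_system`.
#' @param batch_x,batch_y nonempty lists of images from each domain.
#' @return object of class `gan_loss_report`:
#'   list(l_gan_G, l_gan_F, l_cyc, total).
#' @export
cyclegan_losses <- function(system, batch_x, batch_y) {
  if (!length(batch_x) || !length(batch_y)) stop("batches must be nonempty")
  gx <- lapply(batch_x, function(x) gen_forward(system$G, x)$out)
  fy <- lapply(batch_y, function(y) gen_forward(system$F_, y)$out)
  l_gan_G <- mean(vapply(batch_y, function(y)
               mean(log(disc_prob(system$D_Y, y))), numeric(1))) +
             mean(vapply(gx, function(g)
               mean(log(1 - disc_prob(system$D_Y, g))), numeric(1)))
  l_gan_F <- mean(vapply(batch_x, function(x)
               mean(log(disc_prob(system$D_X, x))), numeric(1))) +
             mean(vapply(fy, function(f)
               mean(log(1 - disc_prob(system$D_X, f))), numeric(1)))
  l_cyc <- mean(mapply(function(g, x)
             mean(abs(gen_forward(system$F_, g)$out - x)), gx, batch_x)) +
           mean(mapply(function(f, y)
             mean(abs(gen_forward(system$G, f)$out - y)), fy, batch_y))
  structure(list(l_gan_G = l_gan_G, l_gan_F = l_gan_F, l_cyc = l_cyc,
                 total = l_gan_G + l_gan_F + l_cyc),
            class = "gan_loss_report")
}

#' @export
print.gan_loss_report <- function(x, ...) {
  cat(sprintf(
    "<gan_loss_report> adv_G %.4f adv_F %.4f cyc %.4f total %.4f\n",
    x$l_gan_G, x$l_gan_F, x$l_cyc, x$total))
  invisible(x)
}

# gradient of per-patch BCE-with-logits w.r.t. the logits, scaled so the
# batch loop accumulates a mean
bce_logit_grad <- function(logits, target, n_batch) {
  (sigmoid(logits) - target) / (length(logits) * n_batch)
}

#' Train the cycle-translation system
#'
#' Alternating minimax optimisation with Adam: each iteration takes
#' `d_steps` discriminator updates (real versus translated images), then
#' one generator update with the non-saturating adversarial surrogate plus
#' the L1 cycle term. Loss
#' values (in the exact printed form, see [cyclegan_losses()]) are logged
#' per epoch on a fixed held-out evaluation batch. A constant-output
#' generator triggers a mode-collapse warning.
#'
#' @param images_x,images_y nonempty lists of images (the negative and
#'   positive domain).
#' @param epochs training epochs.
#' @param seed integer seed (initialisation and batch order).
#' @param n_filters conv width of generators/discriminators.
#' @param batch_size images per domain per iteration.
#' @param lr_d,lr_g Adam learning rates for the discriminators and the
#'   generators (beta1 = 0.5, the adversarial-training convention). Adam's
#'   per-parameter rescaling lets the spatially concentrated gradients of a
#'   small domain difference (a marker-sized region among hundreds of
#'   patches) survive the patchwise averaging.
#' @param cycle_weight weight on the cycle gradient during generator
#'   updates (the reported loss stays the unweighted sum).
#' @param d_steps discriminator updates per generator update; keeping the
#'   discriminators slightly ahead sharpens the location signal they give
#'   the generators.
#' @param adversarial "log" (the printed loss) or "lsgan" (least-squares
#'   surrogate for the training gradients only).
#' @return the trained `gan_system`, with `$loss_log` (one
#'   `gan_loss_report` per epoch) attached.
#' @export
train_cyclegan <- function(images_x, images_y, epochs = 30L, seed = 1L,
                           n_filters = 8L, batch_size = 4L, lr_d = 2e-3,
                           lr_g = 2e-3, cycle_weight = 1, d_steps = 2L,
                           adversarial = c("log", "lsgan")) {
  adversarial <- match.arg(adversarial)
  if (!length(images_x) || !length(images_y))
    stop("both domains must be nonempty")
  s <- nrow(images_x[[1]])
  system <- gan_system(s, n_filters, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  eval_x <- images_x[seq_len(min(8L, length(images_x)))]
  eval_y <- images_y[seq_len(min(8L, length(images_y)))]
  nets_g <- list(system$G$net, system$F_$net)
  nets_d <- list(system$D_X$net, system$D_Y$net)
  loss_log <- vector("list", epochs)

  n_iter <- max(1L, floor(min(length(images_x), length(images_y)) /
                            batch_size))
  d_logit_grad <- function(logits, target, nb) {
    if (adversarial == "log") bce_logit_grad(logits, target, nb)
    else 2 * (sigmoid(logits) - target) / (length(logits) * nb)
  }
  for (epoch in seq_len(epochs)) {
    for (it in seq_len(n_iter)) {
      bx <- images_x[sample.int(length(images_x), batch_size)]
      by <- images_y[sample.int(length(images_y), batch_size)]
      nb <- batch_size

      gx <- lapply(bx, function(x) gen_forward(system$G, x))
      fy <- lapply(by, function(y) gen_forward(system$F_, y))

      # discriminator steps: real -> 1, translated -> 0
      for (k in seq_len(d_steps)) {
        if (k > 1L) {
          bx2 <- images_x[sample.int(length(images_x), batch_size)]
          by2 <- images_y[sample.int(length(images_y), batch_size)]
          gx2 <- lapply(bx2, function(x) gen_forward(system$G, x))
          fy2 <- lapply(by2, function(y) gen_forward(system$F_, y))
        } else {
          bx2 <- bx; by2 <- by; gx2 <- gx; fy2 <- fy
        }
        for (dn in nets_d) nn_zero_grad(dn)
        for (i in seq_len(nb)) {
          fw <- disc_forward(system$D_Y, by2[[i]])
          disc_backward(system$D_Y, fw$caches, d_logit_grad(fw$out, 1, nb))
          fw <- disc_forward(system$D_Y, gx2[[i]]$out)
          disc_backward(system$D_Y, fw$caches, d_logit_grad(fw$out, 0, nb))
          fw <- disc_forward(system$D_X, bx2[[i]])
          disc_backward(system$D_X, fw$caches, d_logit_grad(fw$out, 1, nb))
          fw <- disc_forward(system$D_X, fy2[[i]]$out)
          disc_backward(system$D_X, fw$caches, d_logit_grad(fw$out, 0, nb))
        }
        for (dn in nets_d) nn_adam_step(dn, lr_d)
      }

      # generator step: fool the discriminators + cycle consistency
      for (gn in nets_g) nn_zero_grad(gn)
      for (i in seq_len(nb)) {
        x <- bx[[i]]; y <- by[[i]]
        # X -> Y -> X
        fw_d <- disc_forward(system$D_Y, gx[[i]]$out)
        dyf <- disc_backward(system$D_Y, fw_d$caches,
                             d_logit_grad(fw_d$out, 1, nb),
                             accumulate = FALSE)
        rec <- gen_forward(system$F_, gx[[i]]$out)
        drec <- cycle_weight * sign(rec$out - x) / (length(x) * nb)
        dyf <- dyf + gen_backward(system$F_, rec$caches, drec)
        gen_backward(system$G, gx[[i]]$caches, dyf)
        # Y -> X -> Y
        fw_d <- disc_forward(system$D_X, fy[[i]]$out)
        dxf <- disc_backward(system$D_X, fw_d$caches,
                             d_logit_grad(fw_d$out, 1, nb),
                             accumulate = FALSE)
        rec <- gen_forward(system$G, fy[[i]]$out)
        drec <- cycle_weight * sign(rec$out - y) / (length(y) * nb)
        dxf <- dxf + gen_backward(system$G, rec$caches, drec)
        gen_backward(system$F_, fy[[i]]$caches, dxf)
      }
      for (gn in nets_g) nn_adam_step(gn, lr_g)
    }
    loss_log[[epoch]] <- cyclegan_losses(system, eval_x, eval_y)
  }
  tx <- lapply(eval_x, function(x) translate(system, x, "neg2pos"))
  if (stats::sd(vapply(tx, mean, numeric(1))) < 1e-10 && length(tx) > 1L)
    warning("possible mode collapse: generator output is constant")
  system$loss_log <- loss_log
  system
}

#' Counterfactual difference map
#' @param system a `gan_system`.
#' @param image numeric matrix.
#' @param direction as in [translate()].
#' @return signed difference `translated - original`.
#' @export
difference_map <- function(system, image, direction = "neg2pos") {
  translate(system, image, direction) - image
}

#' Fraction of counterfactuals the classifier assigns to the target class
#'
#' Each image is translated to the opposite domain and scored by the
#' audited classifier; a flip means the COVID-node log-odds crossed zero
#' toward the target class (positive for "neg2pos", negative for
#' "pos2neg").
#'
#' @param classifier a `trained_model`.
#' @param images nonempty list of images from the starting domain.
#' @param direction "neg2pos" or "pos2neg".
#' @param system a `gan_system`; ignored when `transform` is given.
#' @param transform optional function(image) -> image used instead of the
#'   learned generator (e.g. an oracle feature edit).
#' @return list(flip_rate, mean_delta_log_odds, deltas).
#' @export
classifier_flip_rate <- function(classifier, images,
                                 direction = c("neg2pos", "pos2neg"),
                                 system = NULL, transform = NULL) {
  direction <- match.arg(direction)
  if (!length(images)) stop("image set must be nonempty")
  if (is.null(transform)) {
    if (is.null(system)) stop("either a gan_system or a transform is needed")
    transform <- function(im) translate(system, im, direction)
  }
  z0 <- predict_scores(classifier, images)
  z1 <- predict_scores(classifier, lapply(images, transform))
  flips <- if (direction == "neg2pos") z1 > 0 else z1 < 0
  list(flip_rate = mean(flips), mean_delta_log_odds = mean(z1 - z0),
       deltas = z1 - z0)
}
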