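# Path attributions: Expected Gradients and its single-reference special
# case, Integrated Gradients. Attributions are taken with respect to the
# pre-sigmoid (log-odds) output of the requested node, the same scale the
# behavioral tests use, so attribution sums are additive with measured
# output changes.

#' A background distribution of reference images
#'
#' @param images nonempty list of same-shape numeric matrices (e.g. the
#'   training COVID-negatives, the reference choice used throughout).
#' @param id short token describing the set.
#' @return object of class `background_set`.
#' @export
background_set <- function(images, id = "background") {
  if (length(images) == 0L) stop("background set must be nonempty")
  d <- dim(images[[1]])
  ok <- vapply(images, function(im) identical(dim(im), d), logical(1))
  if (!all(ok)) stop("background images must share one shape")
  structure(list(images = images, id = id), class = "background_set")
}

# Models are either `trained_model`s (a $net) or analytic toys supplying
# $value_fn(image, node) and $grad_fn(image, node) closures.
model_value <- function(model, image, node) {
  if (!is.null(model$value_fn)) return(model$value_fn(image, node))
  nn_forward(model$net, image)$out[node]
}

model_input_grad <- function(model, image, node) {
  if (!is.null(model$grad_fn)) return(model$grad_fn(image, node))
  fw <- nn_forward(model$net, image)
  dout <- numeric(length(fw$out))
  dout[node] <- 1
  g <- nn_backward(model$net, fw$caches, dout, accumulate = FALSE)
  matrix(g, nrow(image), ncol(image))
}

new_attribution_map <- function(phi, model, image, node, n_references,
                                n_samples, seed, f_x, f_bg_mean) {
  structure(list(phi = phi, node = node, n_references = n_references,
                 n_samples = n_samples, seed = seed,
                 f_x = f_x, f_bg_mean = f_bg_mean,
                 completeness_gap = abs(sum(phi) - (f_x - f_bg_mean))),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf(
    "<attribution_map> node %d, %d samples over %d references, sum(phi)=%.4f, completeness gap %.4g\n",
    x$node, x$n_samples, x$n_references, sum(x$phi), x$completeness_gap))
  invisible(x)
}

#' Expected Gradients attribution
#'
#' Monte-Carlo estimate of the path attribution
#' `phi_i = E_{x' ~ D, alpha ~ U(0,1)} [(x_i - x'_i) * df/dx_i at
#' x' + alpha (x - x')]`: per sample one reference is drawn from the
#' background, one alpha uniformly (or from `alphas` if supplied, for
#' deterministic quadrature), and one gradient of the node's log-odds is
#' evaluated at the interpolated image. The estimator is unbiased, so the
#' completeness gap `|sum(phi) - (f(x) - mean f(x'))|` shrinks as
#' 1/sqrt(n_samples); it is recorded on every map.
#'
#' @param model a `trained_model` (or any object with a `$net`).
#' @param image input image matrix.
#' @param background a [background_set()].
#' @param n_samples number of (reference, alpha) draws (>= 1).
#' @param seed integer seed for the draws.
#' @param node output node; defaults to the model's COVID node.
#' @param alphas optional fixed alpha values recycled over samples,
#'   replacing the U(0,1) draw.
#' @return an `attribution_map` with per-pixel `phi`.
#' @export
expected_gradients <- function(model, image, background, n_samples = 200L,
                               seed = 1L, node = model$covid_node %||% 1L,
                               alphas = NULL) {
  stopifnot(inherits(background, "background_set"))
  if (n_samples < 1L) stop("n_samples must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nb <- length(background$images)
  ref_idx <- sample.int(nb, n_samples, replace = TRUE)
  a <- if (is.null(alphas)) stats::runif(n_samples)
       else rep_len(alphas, n_samples)
  phi <- image * 0
  for (k in seq_len(n_samples)) {
    xr <- background$images[[ref_idx[k]]]
    xi <- xr + a[k] * (image - xr)
    g <- model_input_grad(model, xi, node)
    if (any(!is.finite(g))) stop("non-finite gradient at sample ", k)
    phi <- phi + (image - xr) * g
  }
  phi <- phi / n_samples
  f_bg <- mean(vapply(background$images,
                      function(im) model_value(model, im, node), numeric(1)))
  new_attribution_map(phi, model, image, node, nb, n_samples, seed,
                      model_value(model, image, node), f_bg)
}

#' Integrated Gradients attribution
#'
#' The single-reference special case: gradients are averaged over a
#' deterministic midpoint alpha grid along the straight path from
#' `reference` to `image`, then scaled by `(x - x')`. Completeness holds to
#' quadrature error.
#'
#' @param model a `trained_model`.
#' @param image input image matrix.
#' @param reference single reference image (same shape).
#' @param n_alpha number of quadrature points.
#' @param node output node; defaults to the model's COVID node.
#' @return an `attribution_map`.
#' @export
integrated_gradients <- function(model, image, reference, n_alpha = 50L,
                                 node = model$covid_node %||% 1L) {
  if (!identical(dim(image), dim(reference)))
    stop("reference shape must match the image")
  a <- (seq_len(n_alpha) - 0.5) / n_alpha
  gsum <- image * 0
  for (k in seq_len(n_alpha)) {
    xi <- reference + a[k] * (image - reference)
    g <- model_input_grad(model, xi, node)
    if (any(!is.finite(g))) stop("non-finite gradient at alpha ", a[k])
    gsum <- gsum + g
  }
  phi <- (image - reference) * gsum / n_alpha
  new_attribution_map(phi, model, image, node, 1L, n_alpha, NA_integer_,
                      model_value(model, image, node),
                      model_value(model, reference, node))
}

#' Percentile-transformed saliency display
#'
#' Rank-transforms attribution magnitudes (or signed values) to [0, 100]:
#' a pixel's percentile is its rank among all pixels times 100/n, so the
#' attribution order is preserved exactly. An all-equal map returns the
#' 50th percentile everywhere by convention.
#'
#' @param map an `attribution_map`.
#' @param signed rank signed phi instead of |phi|.
#' @return numeric matrix of percentiles in (0, 100].
#' @export
percentile_saliency <- function(map, signed = FALSE) {
  phi <- map$phi
  if (any(!is.finite(phi))) stop("attribution map contains non-finite values")
  v <- if (signed) phi else abs(phi)
  n <- length(v)
  if (max(v) == min(v)) return(matrix(50, nrow(phi), ncol(phi)))
  matrix(rank(v, ties.method = "average") / n * 100, nrow(phi), ncol(phi))
}

#' Sensitivity of attributions to the background choice
#'
#' Computes Expected Gradients under two different background sets (same
#' seed and sample count) and returns the Spearman rank correlation of the
#' two maps along with both maps.
#'
#' @param model a `trained_model`.
#' @param image input image matrix.
#' @param background_a,background_b two [background_set()]s.
#' @param n_samples,seed,node as in [expected_gradients()].
#' @return list(correlation, map_a, map_b).
#' @export
background_sensitivity <- function(model, image, background_a, background_b,
                                   n_samples = 200L, seed = 1L,
                                   node = model$covid_node %||% 1L) {
  ma <- expected_gradients(model, image, background_a, n_samples, seed, node)
  mb <- expected_gradients(model, image, background_b, n_samples, seed, node)
  if (stats::sd(ma$phi) == 0 || stats::sd(mb$phi) == 0) {
    warning("constant attribution map: correlation undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(as.numeric(ma$phi), as.numeric(mb$phi),
                      method = "spearman")
  }
  list(correlation = rho, map_a = ma, map_b = mb)
}

#' Fraction of attribution mass inside a region
#'
#' The localization statistic of the audit: `sum(|phi[mask]|) / sum(|phi|)`.
#'
#' @param map an `attribution_map` (or a plain numeric matrix).
#' @param mask logical matrix of the same shape.
#' @return fraction in [0, 1].
#' @export
attribution_mass_fraction <- function(map, mask) {
  phi <- if (inherits(map, "attribution_map")) map$phi else map
  stopifnot(identical(dim(phi), dim(mask)))
  tot <- sum(abs(phi))
  if (tot == 0) return(0)
  sum(abs(phi[mask])) / tot
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' Saves the percentile-transformed map (see [percentile_saliency()]) with
#' white = 100th percentile. The raw `phi` values stay in the
#' `attribution_map` object; this is the display artifact.
#'
#' @param map an `attribution_map`.
#' @param path output PNG path.
#' @param signed rank signed phi instead of |phi|.
#' @return invisibly, the path.
#' @export
write_saliency_png <- function(map, path, signed = FALSE) {
  png::writePNG(percentile_saliency(map, signed) / 100, path)
  invisible(path)
}
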