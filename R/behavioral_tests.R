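# Behavioral validation of candidate shortcuts: swap the suspected feature
# (laterality marker) between a positive and a negative image, or relocate
# the shoulder region to the top corners, and compare the induced change in
# COVID-node log-odds against a Monte-Carlo null of random same-size patch
# modifications, scored by the empirical p-value (r + 1) / (n + 1).

#' A rectangular image patch
#'
#' @param top,left 1-based top-left corner.
#' @param height,width extents in px (>= 1).
#' @return object of class `patch_region`.
#' @export
patch_region <- function(top, left, height, width) {
  if (height < 1 || width < 1) stop("patch height and width must be >= 1")
  if (top < 1 || left < 1) stop("patch corner must be within the image")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "patch_region")
}

region_rows <- function(r) r$top:(r$top + r$height - 1L)
region_cols <- function(r) r$left:(r$left + r$width - 1L)

check_region_fits <- function(region, image) {
  if (region$top + region$height - 1L > nrow(image) ||
      region$left + region$width - 1L > ncol(image))
    stop("patch region exceeds the image bounds")
  invisible(TRUE)
}

#' Swap patch contents between two images
#'
#' `modified_a` carries `image_b`'s patch content at `region_a` and vice
#' versa; all other pixels are untouched. Applying the same swap twice
#' recovers the originals.
#'
#' @param image_a,image_b numeric matrices.
#' @param region_a,region_b [patch_region()]s of equal dimensions.
#' @return list(a, b) of modified images.
#' @export
swap_patches <- function(image_a, image_b, region_a, region_b) {
  if (region_a$height != region_b$height || region_a$width != region_b$width)
    stop("patch regions must have equal dimensions")
  check_region_fits(region_a, image_a)
  check_region_fits(region_b, image_b)
  pa <- image_a[region_rows(region_a), region_cols(region_a), drop = FALSE]
  pb <- image_b[region_rows(region_b), region_cols(region_b), drop = FALSE]
  image_a[region_rows(region_a), region_cols(region_a)] <- pb
  image_b[region_rows(region_b), region_cols(region_b)] <- pa
  list(a = image_a, b = image_b)
}

#' Empirical p-value of a targeted modification
#'
#' `p = (r + 1) / (n + 1)`, where `r` counts null modifications whose
#' effect strictly exceeds the observed one in the stated direction (ties
#' are not counted) and `n` is the null size, so `1/(n+1) <= p <= 1`.
#'
#' @param delta_observed observed log-odds change.
#' @param null_deltas numeric vector of null log-odds changes.
#' @param direction "increase" (null deltas greater than observed count
#'   toward r) or "decrease" (more-negative null deltas count).
#' @return the empirical p-value.
#' @export
empirical_p_value <- function(delta_observed, null_deltas,
                              direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(null_deltas) == 0L) stop("null_deltas must be nonempty")
  if (!is.finite(delta_observed) || any(!is.finite(null_deltas)))
    stop("deltas must be finite")
  r <- if (direction == "increase") sum(null_deltas > delta_observed)
       else sum(null_deltas < delta_observed)
  (r + 1) / (length(null_deltas) + 1)
}

new_swap_test_result <- function(delta_observed, null_deltas, direction,
                                 region, seed) {
  r <- if (direction == "increase") sum(null_deltas > delta_observed)
       else sum(null_deltas < delta_observed)
  structure(list(delta_observed = delta_observed, null_deltas = null_deltas,
                 r = r, p = empirical_p_value(delta_observed, null_deltas,
                                              direction),
                 n = length(null_deltas), direction = direction,
                 region = region, seed = seed),
            class = "swap_test_result")
}

#' @export
print.swap_test_result <- function(x, ...) {
  cat(sprintf(
    "<swap_test_result> delta = %+.3f log-odds (%s), r = %d of n = %d, p = %.4g\n",
    x$delta_observed, x$direction, x$r, x$n, x$p))
  invisible(x)
}

random_region <- function(image, height, width) {
  patch_region(sample.int(nrow(image) - height + 1L, 1L),
               sample.int(ncol(image) - width + 1L, 1L), height, width)
}

# exchange content between two images at one or two fixed sites (the same
# coordinates in both images); a repeated site is swapped once
site_exchange <- function(image_a, image_b, site1, site2) {
  out <- swap_patches(image_a, image_b, site1, site1)
  if (!identical(unclass(site1), unclass(site2)))
    out <- swap_patches(out$a, out$b, site2, site2)
  out
}

#' Marker-swap behavioral test
#'
#' Exchanges the two images' marker configurations: the content at both
#' marker sites (`region_pos`, the positive source's canonical glyph
#' footprint, and `region_neg`, the negative source's) is swapped between
#' the images in place, so each image ends up carrying the other's marker.
#' The change in COVID-node log-odds per image is compared against a null
#' of `n` modifications that exchange two uniformly-placed random sites of
#' the same dimensions (fresh positions each draw; they may overlap the
#' true marker sites). The negative image is expected to *increase* (it
#' received the positive source's marker) and the positive image to
#' *decrease*.
#'
#' @param model a `trained_model`.
#' @param image_pos,image_neg matrices at the training resolution.
#' @param region_pos,region_neg [patch_region()]s locating the two marker
#'   sites (applied at the same coordinates in both images).
#' @param n null size (>= 1; default 1000).
#' @param seed integer seed for the null placements.
#' @return list(pos, neg) of `swap_test_result`s; `pos` is tested for a
#'   decrease and `neg` for an increase.
#' @export
run_swap_test <- function(model, image_pos, image_neg, region_pos,
                          region_neg, n = 1000L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  check_region_fits(region_pos, image_pos)
  check_region_fits(region_neg, image_neg)
  base_pos <- predict_log_odds(model, image_pos)
  base_neg <- predict_log_odds(model, image_neg)
  obs <- site_exchange(image_pos, image_neg, region_pos, region_neg)
  d_pos <- predict_log_odds(model, obs$a) - base_pos
  d_neg <- predict_log_odds(model, obs$b) - base_neg

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_pos <- numeric(n); null_neg <- numeric(n)
  for (j in seq_len(n)) {
    r1 <- random_region(image_pos, region_pos$height, region_pos$width)
    r2 <- random_region(image_pos, region_neg$height, region_neg$width)
    sw <- site_exchange(image_pos, image_neg, r1, r2)
    null_pos[j] <- predict_log_odds(model, sw$a) - base_pos
    null_neg[j] <- predict_log_odds(model, sw$b) - base_neg
  }
  list(pos = new_swap_test_result(d_pos, null_pos, "decrease", region_pos,
                                  seed),
       neg = new_swap_test_result(d_neg, null_neg, "increase", region_neg,
                                  seed))
}

#' Shoulder-relocation behavioral test
#'
#' Copies the content of `source_region` (the shoulder/clavicle band) to
#' each target position (default: the two top corners) and measures the
#' change in COVID-node log-odds; the null relocates `n` random same-size
#' patches (content always read from the unmodified image) to the same
#' targets. The source region keeps its original content — the observed
#' modification duplicates rather than cuts.
#'
#' @param model a `trained_model`.
#' @param image matrix at the training resolution.
#' @param source_region a [patch_region()].
#' @param target_positions list of c(row, col) top-left corners; default
#'   the two top corners of the image.
#' @param n null size (>= 1).
#' @param seed integer seed.
#' @param direction expected effect direction (default "increase").
#' @return a `swap_test_result`.
#' @export
run_reposition_test <- function(model, image, source_region,
                                target_positions = NULL, n = 1000L,
                                seed = 1L, direction = "increase") {
  if (n < 1L) stop("n must be >= 1")
  check_region_fits(source_region, image)
  h <- source_region$height; w <- source_region$width
  if (is.null(target_positions))
    target_positions <- list(c(1L, 1L), c(1L, ncol(image) - w + 1L))
  place <- function(region) {
    src <- image[region_rows(region), region_cols(region), drop = FALSE]
    out <- image
    for (t in target_positions) {
      tr <- patch_region(t[1], t[2], h, w)
      check_region_fits(tr, image)
      out[region_rows(tr), region_cols(tr)] <- src
    }
    out
  }
  base <- predict_log_odds(model, image)
  d_obs <- predict_log_odds(model, place(source_region)) - base

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_d <- numeric(n)
  for (j in seq_len(n)) {
    null_d[j] <- predict_log_odds(model, place(random_region(image, h, w))) -
      base
  }
  new_swap_test_result(d_obs, null_d, direction, source_region, seed)
}
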