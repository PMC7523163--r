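# Per-source pixel-wise mean images: systematic acquisition differences
# (marker styles, border radiopacity) survive averaging while per-patient
# anatomy washes out, so the mean image of each source exposes what a
# classifier could exploit.

#' Pixel-wise mean image of one source
#'
#' @param ds an `sc_dataset` (or list with `manifest` and `images`).
#' @param source_id which source to average; NULL averages every record.
#' @param target_size optional c(rows, cols) (or single side); images are
#'   bilinearly resized to it before averaging.
#' @return object of class `mean_image_report`: list(source_id, mean,
#'   n_images, resize).
#' @export
mean_image <- function(ds, source_id = NULL, target_size = NULL) {
  m <- ds$manifest
  keep <- if (is.null(source_id)) rep(TRUE, nrow(m))
          else m$source_id == source_id
  if (!any(keep)) stop("no records for source ", source_id)
  imgs <- ds$images[keep]
  if (!is.null(target_size))
    imgs <- lapply(imgs, resize_bilinear, target_size = target_size)
  acc <- imgs[[1]] * 0
  for (im in imgs) acc <- acc + im
  structure(list(source_id = source_id %||% "all", mean = acc / length(imgs),
                 n_images = length(imgs),
                 resize = if (is.null(target_size)) "none" else "bilinear"),
            class = "mean_image_report")
}

#' @export
print.mean_image_report <- function(x, ...) {
  cat(sprintf("<mean_image_report> source %s, n = %d, %dx%d (resize: %s)\n",
              x$source_id, x$n_images, nrow(x$mean), ncol(x$mean), x$resize))
  invisible(x)
}

#' Contrast of a mask region in a mean image
#'
#' Mean intensity inside the mask minus mean intensity outside it —
#' the statistic used to assert that a planted per-source feature (marker
#' glyph, border band) is visible in the source's average image.
#'
#' @param report a `mean_image_report` (or plain matrix).
#' @param mask logical matrix of the same shape.
#' @return scalar contrast.
#' @export
mean_image_contrast <- function(report, mask) {
  img <- if (inherits(report, "mean_image_report")) report$mean else report
  stopifnot(identical(dim(img), dim(mask)))
  mean(img[mask]) - mean(img[!mask])
}
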