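# Disk round-trip: 8-bit grayscale PNGs plus a CSV manifest.

#' Write a dataset to disk
#'
#' Images go to `<dir>/images/<record_id>.png` (8-bit grayscale); the
#' manifest, with a `path` column prepended, to `<dir>/manifest.csv`.
#'
#' @param ds an `sc_dataset` (or any list with `manifest` and `images`).
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest with the `path` column.
#' @export
write_dataset <- function(ds, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  m <- ds$manifest
  paths <- file.path("images", paste0(m$record_id, ".png"))
  for (i in seq_len(nrow(m))) {
    png::writePNG(ds$images[[i]], file.path(dir, paths[i]))
  }
  out <- cbind(data.frame(path = paths, stringsAsFactors = FALSE), m)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv` and `images/`.
#' @return a list with `manifest` and `images` (matrices in [0, 1]).
#' @export
read_dataset <- function(dir) {
  m <- utils::read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  images <- lapply(m$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  m$path <- NULL
  structure(list(manifest = m, images = images), class = "sc_dataset")
}

#' Bilinear image resize
#'
#' Used before pixel-wise averaging when image sizes differ.
#'
#' @param img numeric matrix.
#' @param target_size c(rows, cols) or a single side for square output.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, target_size) {
  if (length(target_size) == 1L) target_size <- c(target_size, target_size)
  H <- nrow(img); W <- ncol(img)
  h <- target_size[1]; w <- target_size[2]
  if (h == H && w == W) return(img)
  # map output pixel centres into input coordinates
  rs <- (seq_len(h) - 0.5) * H / h + 0.5
  cs <- (seq_len(w) - 0.5) * W / w + 0.5
  r0 <- pmin(pmax(floor(rs), 1L), H); r1 <- pmin(r0 + 1L, H)
  c0 <- pmin(pmax(floor(cs), 1L), W); c1 <- pmin(c0 + 1L, W)
  fr <- pmin(pmax(rs - r0, 0), 1); fc <- pmin(pmax(cs - c0, 0), 1)
  top <- img[r0, c0, drop = FALSE] * (1 - fc)[col(matrix(0, h, w))] +
         img[r0, c1, drop = FALSE] * fc[col(matrix(0, h, w))]
  bot <- img[r1, c0, drop = FALSE] * (1 - fc)[col(matrix(0, h, w))] +
         img[r1, c1, drop = FALSE] * fc[col(matrix(0, h, w))]
  top * (1 - fr)[row(matrix(0, h, w))] + bot * fr[row(matrix(0, h, w))]
}
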