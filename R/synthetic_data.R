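# Two-source confounded synthetic radiograph generator.
#
# Emulates the statistical structure that makes shortcut learning possible
# when COVID-positive and COVID-negative images are pooled from different
# repositories: source identity correlates with the label (up to perfectly,
# the worst case), and each source carries its own spurious visual
# signature — laterality-marker glyph style and position, border
# radiopacity, shoulder height (a patient-positioning proxy) and occasional
# annotation stamps — while genuine disease is a diffuse bilateral increase
# in lung-field radiopacity carried only by truly positive cases.

AUX_LABEL_COUNT <- 14L
PROJECTION_LEVELS <- c("PA", "AP", "lateral", "AP-supine", "unknown")

# -- glyphs --------------------------------------------------------------

#' Binary laterality-marker glyphs
#'
#' Block-letter "L" and "R" pixel masks (7x5 at scale 1), the radiopaque
#' side tokens whose style and placement differ between hospitals.
#'
#' @param letter "L" or "R".
#' @param scale integer upscaling factor.
#' @return a binary matrix (1 = radiopaque).
#' @export
glyph_letter <- function(letter = c("R", "L"), scale = 2L) {
  letter <- match.arg(letter)
  rows <- if (letter == "L") {
    c("10000", "10000", "10000", "10000", "10000", "10000", "11111")
  } else {
    c("11110", "10001", "10001", "11110", "10100", "10010", "10001")
  }
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  if (scale > 1L) m <- m[rep(seq_len(nrow(m)), each = scale),
                         rep(seq_len(ncol(m)), each = scale)]
  m
}

# -- configuration objects ----------------------------------------------

#' Describe one image source (hospital/repository analogue)
#'
#' @param source_id character token, unique per source.
#' @param marker_glyph binary matrix stamped as the laterality marker.
#' @param marker_pos c(row, col) canonical top-left corner of the glyph.
#' @param marker_jitter nonnegative integer; uniform position jitter in px.
#' @param border_band_intensity additive gray value in [-1, 1] applied in a
#'   frame at the image edges (radiopaque borders from cropping/processing).
#' @param border_band_width frame width in px (>= 0).
#' @param shoulder_offset vertical shift of the shoulder band in px;
#'   positive moves shoulders toward the top edge (supine/portable proxy).
#' @param annotation_rate probability in [0, 1] of an extra arrow stamp
#'   (publication-figure style annotations).
#' @param base_noise_sd nonnegative Gaussian pixel noise sd.
#' @param projection_probs named probabilities over
#'   PA/AP/lateral/AP-supine/unknown.
#' @param sex_probs named probabilities over the two sex-analogue levels A/B.
#' @param ap_cue how an AP projection is rendered: "border" (extra border
#'   radiopacity, the same in every source), "tag" (a source-specific
#'   bright interior tag, spatially disjoint from the border) or "none".
#'   Used by the confound-transfer audit.
#' @param sex_cue "width" renders sex level B as a wider body silhouette
#'   (a domain-invariant anatomical cue) or "none".
#' @return an object of class `source_profile`.
#' @export
source_profile <- function(source_id,
                           marker_glyph = glyph_letter("R"),
                           marker_pos = c(5L, 52L),
                           marker_jitter = 2L,
                           border_band_intensity = 0,
                           border_band_width = 6L,
                           shoulder_offset = 0L,
                           annotation_rate = 0,
                           base_noise_sd = 0.05,
                           projection_probs = c(PA = 0.85, AP = 0.15,
                                                lateral = 0, `AP-supine` = 0,
                                                unknown = 0),
                           sex_probs = c(A = 0.5, B = 0.5),
                           ap_cue = c("border", "tag", "none"),
                           sex_cue = c("width", "none")) {
  ap_cue <- match.arg(ap_cue)
  sex_cue <- match.arg(sex_cue)
  if (marker_jitter < 0 || border_band_width < 0)
    stop("marker_jitter and border_band_width must be >= 0")
  if (annotation_rate < 0 || annotation_rate > 1)
    stop("annotation_rate must lie in [0, 1]")
  if (base_noise_sd < 0) stop("base_noise_sd must be nonnegative")
  if (!is.matrix(marker_glyph) || sum(marker_glyph) == 0)
    stop("marker_glyph must be a nonempty binary matrix")
  if (abs(border_band_intensity) > 1)
    stop("border_band_intensity must lie in [-1, 1]")
  pp <- projection_probs[PROJECTION_LEVELS]
  pp[is.na(pp)] <- 0
  structure(list(
    source_id = as.character(source_id),
    marker_glyph = marker_glyph,
    marker_pos = as.integer(marker_pos),
    marker_jitter = as.integer(marker_jitter),
    border_band_intensity = border_band_intensity,
    border_band_width = as.integer(border_band_width),
    shoulder_offset = as.integer(shoulder_offset),
    annotation_rate = annotation_rate,
    base_noise_sd = base_noise_sd,
    projection_probs = pp / sum(pp),
    sex_probs = sex_probs / sum(sex_probs),
    ap_cue = ap_cue,
    sex_cue = sex_cue
  ), class = "source_profile")
}

#' Describe the genuine pathology signal
#'
#' Disease is rendered as smooth radiopaque blobs confined to the
#' lung-field masks, bilaterally by default — a diffuse airspace-opacity
#' analogue, the only label-related feature that is not a shortcut.
#'
#' @param opacity_effect additive gray amplitude per blob (>= 0).
#' @param blob_count number of blobs (> 0).
#' @param blob_scale Gaussian radius of each blob in px (> 0).
#' @param bilateral alternate blobs between the two lungs.
#' @return an object of class `pathology_spec`.
#' @export
pathology_spec <- function(opacity_effect = 0.25, blob_count = 4L,
                           blob_scale = 4, bilateral = TRUE) {
  if (opacity_effect < 0) stop("opacity_effect must be >= 0")
  if (blob_count < 1 || blob_scale <= 0)
    stop("blob_count and blob_scale must be positive")
  structure(list(opacity_effect = opacity_effect,
                 blob_count = as.integer(blob_count),
                 blob_scale = blob_scale, bilateral = isTRUE(bilateral)),
            class = "pathology_spec")
}

#' Dataset-level generation settings
#'
#' @param image_size square image side in px (>= 32).
#' @param n_per_source records generated per source.
#' @param confound_correlation rho in [0, 1]: strength of the source-label
#'   association. A record's source matches its label-determined source
#'   (positives to source B, negatives to source A) with probability
#'   (1 + rho)/2, so rho = 0 makes source independent of label and rho = 1
#'   reproduces worst-case confounding (an exclusively negative source and
#'   an exclusively positive source).
#' @param pathology_penetrance probability in [0, 1] that a truly positive
#'   case actually shows the radiographic signal; < 1 creates the
#'   concept-shift scenario where clinical status and visible evidence
#'   disagree.
#' @param labeling_rule "latent_status" labels by true disease status;
#'   "radiographic_evidence" labels positive only when the signal was
#'   rendered (a radiologist-report labelling analogue).
#' @param images_per_patient consecutive records grouped under one patient.
#' @param seed integer master seed; all randomness derives from it.
#' @return an object of class `generation_config`.
#' @export
generation_config <- function(image_size = 64L, n_per_source = 100L,
                              confound_correlation = 1,
                              pathology_penetrance = 1,
                              labeling_rule = c("latent_status",
                                                "radiographic_evidence"),
                              images_per_patient = 1L,
                              seed = 1L) {
  labeling_rule <- match.arg(labeling_rule)
  if (confound_correlation < 0 || confound_correlation > 1)
    stop("confound_correlation must lie in [0, 1]")
  if (pathology_penetrance < 0 || pathology_penetrance > 1)
    stop("pathology_penetrance must lie in [0, 1]")
  if (image_size < 32) stop("image_size must be >= 32")
  structure(list(image_size = as.integer(image_size),
                 n_per_source = as.integer(n_per_source),
                 confound_correlation = confound_correlation,
                 pathology_penetrance = pathology_penetrance,
                 labeling_rule = labeling_rule,
                 images_per_patient = as.integer(images_per_patient),
                 seed = as.integer(seed)),
            class = "generation_config")
}

# -- geometry ------------------------------------------------------------

ellipse_mask <- function(size, c_row, c_col, r_row, r_col) {
  r <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((r - c_row) / r_row)^2 + ((cc - c_col) / r_col)^2 <= 1
}

#' Lung-field mask used by the generator and the localization audits
#'
#' @param image_size square image side.
#' @param side "both", "left" or "right" (image left = reader's left).
#' @return logical matrix, TRUE inside the lung field(s).
#' @export
lung_field_mask <- function(image_size, side = c("both", "left", "right")) {
  side <- match.arg(side)
  s <- image_size
  left <- ellipse_mask(s, 0.54 * s, 0.32 * s, 0.27 * s, 0.14 * s)
  right <- ellipse_mask(s, 0.54 * s, 0.68 * s, 0.27 * s, 0.14 * s)
  switch(side, both = left | right, left = left, right = right)
}

shoulder_band_rows <- function(profile, image_size) {
  s <- image_size
  top <- round(0.22 * s) - profile$shoulder_offset
  h <- max(2L, round(0.07 * s))
  rows <- top:(top + h - 1L)
  rows[rows >= 1L & rows <= s]
}

#' Marker-glyph region of a source profile
#'
#' The canonical glyph footprint, grown by the position jitter plus an
#' optional extra dilation — the ground-truth region the localization and
#' behavioral audits test against.
#'
#' @param profile a [source_profile()].
#' @param image_size square image side.
#' @param dilate extra margin in px beyond the jitter.
#' @return logical matrix, TRUE on the (dilated) marker footprint.
#' @export
marker_mask <- function(profile, image_size, dilate = 0L) {
  g <- dim(profile$marker_glyph)
  m <- profile$marker_jitter + as.integer(dilate)
  r0 <- max(1L, profile$marker_pos[1] - m)
  r1 <- min(image_size, profile$marker_pos[1] + g[1] - 1L + m)
  c0 <- max(1L, profile$marker_pos[2] - m)
  c1 <- min(image_size, profile$marker_pos[2] + g[2] - 1L + m)
  out <- matrix(FALSE, image_size, image_size)
  out[r0:r1, c0:c1] <- TRUE
  out
}

#' Marker region as a patch rectangle
#'
#' Convenience for the swap tests: the canonical glyph bounding box of a
#' profile as a [patch_region()].
#' @inheritParams marker_mask
#' @export
marker_region <- function(profile, image_size) {
  g <- dim(profile$marker_glyph)
  patch_region(profile$marker_pos[1], profile$marker_pos[2], g[1], g[2])
}

stamp <- function(img, mask, top, left, value) {
  s <- nrow(img)
  g <- dim(mask)
  rr <- top:(top + g[1] - 1L)
  cc <- left:(left + g[2] - 1L)
  keep_r <- rr >= 1L & rr <= s
  keep_c <- cc >= 1L & cc <= s
  sub <- img[rr[keep_r], cc[keep_c], drop = FALSE]
  msub <- mask[keep_r, keep_c, drop = FALSE] > 0
  sub[msub] <- pmax(sub[msub], value)
  img[rr[keep_r], cc[keep_c]] <- sub
  img
}

annotation_glyph <- function() {
  rows <- c("000100", "001100", "111111", "001100", "000100")
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
}

# -- rendering -----------------------------------------------------------

#' Render one synthetic radiograph
#'
#' Deterministic given `params$seed`. Layers, in order: uniform background;
#' body silhouette (wider when the sex cue says so); dark lung fields;
#' diaphragm and cardiac shading; shoulder band whose top edge sits at the
#' canonical row minus the profile's `shoulder_offset`; pathology blobs
#' inside the lung masks iff `params$has_signal`; the profile's marker
#' glyph at its canonical position plus jitter (clamped at the borders);
#' optional annotation stamp; border radiopacity band; AP projection cue;
#' Gaussian noise; clip to [0, 1].
#'
#' @param params list with fields `has_signal` (0/1), `projection`,
#'   `sex_analogue` ("A"/"B") and `seed` (the per-record stream).
#' @param profile a [source_profile()].
#' @param pathology a [pathology_spec()].
#' @param image_size square image side.
#' @return numeric matrix in [0, 1].
#' @export
render_image <- function(params, profile, pathology, image_size = 64L) {
  s <- as.integer(image_size)
  g <- dim(profile$marker_glyph)
  if (g[1] > s || g[2] > s)
    stop("marker glyph larger than the image")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  img <- matrix(0.25, s, s)
  wide <- identical(profile$sex_cue, "width") &&
    identical(params$sex_analogue, "B")
  body_rc <- (0.38 + if (wide) 0.04 else 0) * s
  body <- ellipse_mask(s, 0.55 * s, 0.5 * s, 0.46 * s, body_rc)
  img[body] <- img[body] + 0.20

  lungL <- lung_field_mask(s, "left")
  lungR <- lung_field_mask(s, "right")
  img[lungL | lungR] <- img[lungL | lungR] - 0.22

  diaphragm <- body & (matrix(seq_len(s), s, s) > 0.80 * s)
  img[diaphragm] <- img[diaphragm] + 0.15
  cardiac <- ellipse_mask(s, 0.66 * s, 0.57 * s, 0.14 * s, 0.11 * s)
  img[cardiac] <- img[cardiac] + 0.12

  rows <- shoulder_band_rows(profile, s)
  cols <- round(0.18 * s):round(0.82 * s)
  img[rows, cols] <- img[rows, cols] + 0.30

  if (isTRUE(params$has_signal == 1) && pathology$opacity_effect > 0) {
    rmat <- matrix(seq_len(s), s, s)
    cmat <- matrix(seq_len(s), s, s, byrow = TRUE)
    lungs <- list(lungL, lungR)
    for (b in seq_len(pathology$blob_count)) {
      m <- if (pathology$bilateral) lungs[[(b - 1L) %% 2L + 1L]] else lungL
      idx <- which(m)
      ctr <- idx[sample.int(length(idx), 1L)]
      cr <- (ctr - 1L) %% s + 1L
      cl <- (ctr - 1L) %/% s + 1L
      bump <- pathology$opacity_effect *
        exp(-((rmat - cr)^2 + (cmat - cl)^2) / (2 * pathology$blob_scale^2))
      img <- img + bump * (lungL | lungR)
    }
  }

  jit <- if (profile$marker_jitter > 0)
    sample(-profile$marker_jitter:profile$marker_jitter, 2L, replace = TRUE)
  else c(0L, 0L)
  top <- min(max(1L, profile$marker_pos[1] + jit[1]), s - g[1] + 1L)
  left <- min(max(1L, profile$marker_pos[2] + jit[2]), s - g[2] + 1L)
  img <- stamp(img, profile$marker_glyph, top, left, 0.95)

  if (profile$annotation_rate > 0 &&
      stats::runif(1) < profile$annotation_rate) {
    a <- annotation_glyph()
    at <- sample.int(s - nrow(a) + 1L, 1L)
    al <- sample.int(s - ncol(a) + 1L, 1L)
    img <- stamp(img, a, at, al, 0.9)
  }

  w <- profile$border_band_width
  if (w > 0 && profile$border_band_intensity != 0) {
    frame <- matrix(FALSE, s, s)
    frame[c(seq_len(w), s - seq_len(w) + 1L), ] <- TRUE
    frame[, c(seq_len(w), s - seq_len(w) + 1L)] <- TRUE
    img[frame] <- img[frame] + profile$border_band_intensity
  }

  if (identical(params$projection, "AP")) {
    if (profile$ap_cue == "border") {
      wc <- max(2L, round(0.06 * s))
      frame <- matrix(FALSE, s, s)
      frame[c(seq_len(wc), s - seq_len(wc) + 1L), ] <- TRUE
      frame[, c(seq_len(wc), s - seq_len(wc) + 1L)] <- TRUE
      img[frame] <- img[frame] + 0.15
    } else if (profile$ap_cue == "tag") {
      sz <- max(4L, round(0.09 * s))
      r0 <- round(0.66 * s); c0 <- round(0.08 * s)
      img[r0:(r0 + sz - 1L), c0:(c0 + sz - 1L)] <-
        pmax(img[r0:(r0 + sz - 1L), c0:(c0 + sz - 1L)], 0.9)
    }
  }

  if (profile$base_noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, sd = profile$base_noise_sd), s, s)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# -- dataset generation --------------------------------------------------

#' Generate a two-source confounded dataset
#'
#' Produces `2 * n_per_source` records. Each source contributes exactly
#' `n_per_source` images; within source B a record is truly positive with
#' probability (1 + rho)/2 and within source A with probability
#' (1 - rho)/2, so at rho = 1 source B is exclusively positive and source A
#' exclusively negative, and at rho = 0 the label is independent of the
#' source. Truly positive cases receive the rendered pathology signal with
#' probability `pathology_penetrance`; the recorded `covid` label follows
#' `labeling_rule`. All randomness flows from `config$seed`; each record
#' renders from its own derived substream, so regeneration is byte-exact.
#'
#' @param config a [generation_config()].
#' @param profile_a,profile_b [source_profile()]s with distinct ids;
#'   negatives gravitate to A, positives to B.
#' @param pathology a [pathology_spec()].
#' @return an object of class `sc_dataset`: list with `manifest`
#'   (data.frame: record_id, patient_id, source_id, covid, aux_01..aux_14,
#'   projection, sex_analogue, has_signal), `images` (list of matrices,
#'   parallel to the manifest), `profiles`, `pathology`, `config`.
#' @export
generate_dataset <- function(config, profile_a, profile_b,
                             pathology = pathology_spec()) {
  stopifnot(inherits(config, "generation_config"),
            inherits(profile_a, "source_profile"),
            inherits(profile_b, "source_profile"),
            inherits(pathology, "pathology_spec"))
  if (identical(profile_a$source_id, profile_b$source_id))
    stop("profiles must have distinct source_ids")
  s <- config$image_size
  for (p in list(profile_a, profile_b)) {
    g <- dim(p$marker_glyph)
    if (g[1] + p$marker_jitter > s || g[2] + p$marker_jitter > s)
      stop("marker glyph plus jitter exceeds the image for source ",
           p$source_id)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_per_source
  rho <- config$confound_correlation
  profiles <- list(profile_a, profile_b)
  p_pos <- c((1 - rho) / 2, (1 + rho) / 2)

  rows <- vector("list", 2L * n)
  images <- vector("list", 2L * n)
  idx <- 0L
  for (si in 1:2) {
    prof <- profiles[[si]]
    latent <- stats::rbinom(n, 1L, p_pos[si])
    signal <- latent * stats::rbinom(n, 1L, config$pathology_penetrance)
    proj <- sample(PROJECTION_LEVELS, n, replace = TRUE,
                   prob = prof$projection_probs)
    sex <- sample(names(prof$sex_probs), n, replace = TRUE,
                  prob = prof$sex_probs)
    aux <- matrix(stats::rbinom(n * AUX_LABEL_COUNT, 1L, 0.05), n,
                  AUX_LABEL_COUNT)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    pat_group <- (seq_len(n) - 1L) %/% config$images_per_patient
    for (i in seq_len(n)) {
      idx <- idx + 1L
      covid <- if (config$labeling_rule == "latent_status") latent[i]
               else signal[i]
      params <- list(has_signal = signal[i], projection = proj[i],
                     sex_analogue = sex[i], seed = seeds[i])
      images[[idx]] <- render_image(params, prof, pathology, s)
      row <- data.frame(
        record_id = sprintf("%s_r%04d", prof$source_id, i),
        patient_id = sprintf("%s_p%04d", prof$source_id, pat_group[i]),
        source_id = prof$source_id,
        covid = covid,
        stringsAsFactors = FALSE
      )
      auxdf <- as.data.frame(as.list(aux[i, ]))
      names(auxdf) <- sprintf("aux_%02d", seq_len(AUX_LABEL_COUNT))
      row <- cbind(row, auxdf)
      row$projection <- proj[i]
      row$sex_analogue <- sex[i]
      row$has_signal <- signal[i]
      rows[[idx]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, images = images,
                 profiles = list(A = profile_a, B = profile_b),
                 pathology = pathology, config = config),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<sc_dataset> %d images (%dx%d), sources: %s | positives: %d | signal: %d\n",
    nrow(m), x$config$image_size, x$config$image_size,
    paste(unique(m$source_id), collapse = ", "),
    sum(m$covid), sum(m$has_signal)))
  invisible(x)
}

#' Canonical source-profile pairs for audits
#'
#' `marker_only_profiles()` returns two sources identical in every respect
#' except the laterality-marker style and position (source A: "L" at the
#' top-left; source B: "R" at the top-right) — the cleanest planted
#' shortcut. `default_profiles()` additionally gives the sources opposed
#' border radiopacity, a shoulder-height offset and annotation stamps for
#' source B, emulating the full between-repository feature taxonomy.
#' Positions scale with `image_size`.
#'
#' @param image_size square image side the profiles will render at.
#' @return list(A = source_profile, B = source_profile).
#' @export
marker_only_profiles <- function(image_size = 64L) {
  s <- image_size
  list(
    A = source_profile("A", marker_glyph = glyph_letter("L"),
                       marker_pos = c(round(0.08 * s), round(0.06 * s)),
                       border_band_intensity = 0),
    B = source_profile("B", marker_glyph = glyph_letter("R"),
                       marker_pos = c(round(0.08 * s), round(0.81 * s)),
                       border_band_intensity = 0)
  )
}

#' @rdname marker_only_profiles
#' @export
default_profiles <- function(image_size = 64L) {
  p <- marker_only_profiles(image_size)
  p$A$border_band_intensity <- 0.12
  p$B$border_band_intensity <- -0.08
  p$B$shoulder_offset <- 6L
  p$B$annotation_rate <- 0.1
  p$B$projection_probs <- stats::setNames(c(0.15, 0.85, 0, 0, 0),
                                          PROJECTION_LEVELS)
  p
}

#' Subset a dataset by manifest rows
#' @param ds an `sc_dataset`.
#' @param i integer or logical index into the manifest rows.
#' @return the subsetted `sc_dataset`.
#' @export
subset_dataset <- function(ds, i) {
  if (is.logical(i)) i <- which(i)
  ds$manifest <- ds$manifest[i, , drop = FALSE]
  rownames(ds$manifest) <- NULL
  ds$images <- ds$images[i]
  ds
}
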