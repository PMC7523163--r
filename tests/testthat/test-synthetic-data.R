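# Generator contracts: confound structure, determinism, and the rendered
# feature geometry (border band, shoulder height, marker glyph).

test_that("worst-case confounding puts every positive in source B", {
  p <- marker_only_profiles()
  ds <- generate_dataset(generation_config(n_per_source = 50, seed = 7),
                         p$A, p$B, pathology_spec(opacity_effect = 0))
  m <- ds$manifest
  expect_equal(nrow(m), 100L)
  expect_true(all(m$source_id[m$covid == 1] == "B"))
  expect_true(all(m$source_id[m$covid == 0] == "A"))
  # source B's glyph region is bright in every positive, dark in negatives
  mask <- marker_mask(p$B, 64)
  pos_hit <- vapply(which(m$covid == 1),
                    function(i) mean(ds$images[[i]][mask]), numeric(1))
  neg_hit <- vapply(which(m$covid == 0),
                    function(i) mean(ds$images[[i]][mask]), numeric(1))
  expect_true(all(pos_hit > 0.42))
  expect_true(all(neg_hit < 0.36))
})

test_that("generation is byte-identical under a repeated seed", {
  p <- default_profiles()
  cfg <- generation_config(n_per_source = 12, seed = 42,
                           confound_correlation = 0.7,
                           pathology_penetrance = 0.8)
  d1 <- generate_dataset(cfg, p$A, p$B)
  d2 <- generate_dataset(cfg, p$A, p$B)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$images, d2$images)
})

test_that("zero confound correlation decouples source from label", {
  p <- marker_only_profiles()
  ds <- generate_dataset(
    generation_config(n_per_source = 200, seed = 1, confound_correlation = 0),
    p$A, p$B, pathology_spec(opacity_effect = 0))
  m <- ds$manifest
  # positives from source B ~ Binomial(n_pos, 0.5): check within 99% bounds
  n_pos <- sum(m$covid == 1)
  frac_b <- mean(m$source_id[m$covid == 1] == "B")
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / n_pos)
  expect_lt(abs(frac_b - 0.5), half_width)
  # a marker-presence classifier is at chance: score = brightness in B's
  # glyph region
  mask <- marker_mask(p$B, 64)
  score <- vapply(ds$images, function(im) max(im[mask]), numeric(1))
  auc <- compute_auroc(score, m$covid)
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("at rho = 1 marker presence predicts the label perfectly", {
  p <- marker_only_profiles()
  ds <- generate_dataset(generation_config(n_per_source = 60, seed = 5),
                         p$A, p$B, pathology_spec(opacity_effect = 0))
  mask <- marker_mask(p$B, 64)
  score <- vapply(ds$images, function(im) max(im[mask]), numeric(1))
  expect_equal(compute_auroc(score, ds$manifest$covid), 1.0)
  # mutual information between marker-source and label equals label entropy
  joint <- table(ds$manifest$source_id, ds$manifest$covid) / nrow(ds$manifest)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- sum(joint[joint > 0] *
              log(joint[joint > 0] / outer(px, py)[joint > 0]))
  h <- -sum(py[py > 0] * log(py[py > 0]))
  expect_equal(mi, h, tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  expect_error(generation_config(confound_correlation = 1.2), "confound")
  expect_error(generation_config(pathology_penetrance = -0.1), "penetrance")
  expect_error(generation_config(image_size = 16), "image_size")
  expect_error(pathology_spec(opacity_effect = -1), "opacity_effect")
  expect_error(source_profile("A", annotation_rate = 2), "annotation_rate")
  p <- marker_only_profiles()
  expect_error(generate_dataset(generation_config(), p$A, p$A), "distinct")
  big <- source_profile("C", marker_glyph = matrix(1, 70, 70))
  expect_error(
    generate_dataset(generation_config(n_per_source = 2), p$A, big),
    "glyph")
})

test_that("radiographic-evidence labelling follows rendered signal", {
  p <- marker_only_profiles()
  cfg <- generation_config(n_per_source = 120, seed = 9,
                           pathology_penetrance = 0.6,
                           labeling_rule = "radiographic_evidence")
  ds <- generate_dataset(cfg, p$A, p$B)
  m <- ds$manifest
  expect_true(all(m$covid[m$has_signal == 1] == 1))
  expect_true(all(m$has_signal[m$covid == 1] == 1))
  # penetrance < 1 leaves some latent positives unlabelled under this rule
  cfg2 <- generation_config(n_per_source = 120, seed = 9,
                            pathology_penetrance = 0.6,
                            labeling_rule = "latent_status")
  ds2 <- generate_dataset(cfg2, p$A, p$B)
  expect_gt(sum(ds2$manifest$covid) , sum(ds2$manifest$has_signal))
})

test_that("border band raises the frame by its intensity", {
  base <- source_profile("A", border_band_intensity = 0, base_noise_sd = 0)
  band <- source_profile("A", border_band_intensity = 0.5,
                         border_band_width = 8L, base_noise_sd = 0)
  params <- list(has_signal = 0, projection = "PA", sex_analogue = "A",
                 seed = 11)
  im0 <- render_image(params, base, pathology_spec(), 64)
  im1 <- render_image(params, band, pathology_spec(), 64)
  frame <- matrix(FALSE, 64, 64)
  frame[c(1:8, 57:64), ] <- TRUE; frame[, c(1:8, 57:64)] <- TRUE
  # identical except in the frame; frame mean up by ~0.5 (clipping only
  # affects the few marker pixels inside the frame)
  expect_equal(im0[!frame], im1[!frame])
  expect_equal(mean(im1[frame]) - mean(im0[frame]), 0.5, tolerance = 0.06)
})

test_that("shoulder offset moves the strongest top-region edge by as much", {
  mean_profile <- function(off) {
    prof <- source_profile("A", shoulder_offset = off, base_noise_sd = 0)
    im <- render_image(list(has_signal = 0, projection = "PA",
                            sex_analogue = "A", seed = 3),
                       prof, pathology_spec(), 64)
    colMeans(t(im[1:30, 15:50]))  # column-averaged vertical profile
  }
  edge_row <- function(v) which.max(diff(v))  # the rising top edge
  expect_equal(edge_row(mean_profile(0L)) - edge_row(mean_profile(10L)), 10L)
})

test_that("identical profiles and zero opacity leave no class difference", {
  pa <- source_profile("A", base_noise_sd = 0.05)
  pb <- source_profile("B", base_noise_sd = 0.05)
  ds <- generate_dataset(generation_config(n_per_source = 80, seed = 2),
                         pa, pb, pathology_spec(opacity_effect = 0))
  m <- ds$manifest
  avg <- function(cls) {
    idx <- which(m$covid == cls)
    Reduce(`+`, ds$images[idx]) / length(idx)
  }
  expect_lt(mean(abs(avg(1) - avg(0))), 0.01)
})

test_that("lung opacity signal is separable by a lung-mean threshold", {
  p <- marker_only_profiles()
  cfg <- generation_config(n_per_source = 80, seed = 4,
                           confound_correlation = 0,
                           labeling_rule = "radiographic_evidence")
  ds <- generate_dataset(cfg, p$A, p$B,
                         pathology_spec(opacity_effect = 0.3))
  mask <- lung_field_mask(64)
  score <- vapply(ds$images, function(im) mean(im[mask]), numeric(1))
  expect_gt(compute_auroc(score, ds$manifest$covid), 0.95)
})

test_that("datasets round-trip through PNG and CSV", {
  p <- marker_only_profiles()
  ds <- generate_dataset(generation_config(n_per_source = 3, seed = 8),
                         p$A, p$B)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$manifest$record_id, ds$manifest$record_id)
  expect_equal(back$manifest$covid, ds$manifest$covid)
  for (i in seq_along(ds$images)) {
    expect_lt(max(abs(back$images[[i]] - ds$images[[i]])), 1 / 255)
  }
})
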