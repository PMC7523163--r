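# Path-attribution oracles: closed forms for linear models, an analytic
# one-pixel path integral, the single-reference special case, completeness
# on a smooth network, and the percentile display transform.

test_that("a constant model attributes zero everywhere", {
  m <- list(covid_node = 1L,
            value_fn = function(image, node) 3.2,
            grad_fn = function(image, node) image * 0)
  bg <- background_set(list(matrix(0, 4, 4), matrix(1, 4, 4)))
  map <- expected_gradients(m, matrix(runif(16), 4, 4), bg,
                            n_samples = 50, seed = 1)
  expect_true(all(map$phi == 0))
  expect_equal(map$completeness_gap, 0)
})

test_that("linear-model attributions match w_i (x_i - mean x'_i)", {
  set.seed(51)
  w <- matrix(rnorm(16), 4, 4)
  m <- linear_toy_model(w, b = 0.3)
  bg_imgs <- lapply(1:6, function(i) matrix(runif(16), 4, 4))
  bg <- background_set(bg_imgs)
  x <- matrix(runif(16), 4, 4)
  map <- expected_gradients(m, x, bg, n_samples = 4000, seed = 2)
  closed <- w * (x - Reduce(`+`, bg_imgs) / 6)
  # Monte-Carlo CI: reference sampling noise ~ sd/sqrt(n)
  expect_equal(as.numeric(map$phi), as.numeric(closed), tolerance = 0.05)
  # for a linear model completeness is near-exact up to reference sampling
  expect_lt(map$completeness_gap, 0.05)
})

test_that("one-pixel quadratic matches the analytic path integral", {
  m <- list(covid_node = 1L,
            value_fn = function(image, node) sum(image^2),
            grad_fn = function(image, node) 2 * image)
  x <- matrix(0.8, 1, 1)
  bg <- background_set(list(matrix(0, 1, 1)))
  # IG with midpoint quadrature is exact for a quadratic: phi = x^2
  ig <- integrated_gradients(m, x, matrix(0, 1, 1), n_alpha = 10)
  expect_equal(ig$phi[1, 1], 0.64, tolerance = 1e-12)
  eg <- expected_gradients(m, x, bg, n_samples = 10000, seed = 3)
  expect_equal(eg$phi[1, 1], 0.64, tolerance = 0.01)
})

test_that("integrated gradients with reference = image vanishes", {
  set.seed(52)
  net <- build_arch("simple-cnn", "single1", 32L)
  model <- structure(list(net = net, covid_node = 1L,
                          head_scheme = "single1"), class = "trained_model")
  x <- matrix(runif(1024), 32, 32)
  map <- integrated_gradients(model, x, x, n_alpha = 8)
  expect_true(all(map$phi == 0))
})

test_that("integrated gradients is exact for linear models", {
  set.seed(53)
  w <- matrix(rnorm(25), 5, 5)
  m <- linear_toy_model(w)
  x <- matrix(runif(25), 5, 5)
  ref <- matrix(runif(25), 5, 5)
  map <- integrated_gradients(m, x, ref, n_alpha = 4)
  expect_equal(map$phi, w * (x - ref), tolerance = 1e-12)
  expect_lt(map$completeness_gap, 1e-12)
})

test_that("expected gradients with a singleton background equals IG", {
  set.seed(54)
  net <- nn_network(list(nn_dense(16L, 8L), nn_tanh(), nn_dense(8L, 1L)),
                    c(4L, 4L, 1L))
  model <- structure(list(net = net, covid_node = 1L,
                          head_scheme = "single1"), class = "trained_model")
  x <- matrix(runif(16), 4, 4)
  ref <- matrix(runif(16), 4, 4)
  n <- 32L
  mid <- (seq_len(n) - 0.5) / n
  eg <- expected_gradients(model, x, background_set(list(ref)),
                           n_samples = n, seed = 1, alphas = mid)
  ig <- integrated_gradients(model, x, ref, n_alpha = n)
  expect_equal(eg$phi, ig$phi, tolerance = 1e-12)
})

test_that("completeness holds on a smooth model and improves with samples", {
  set.seed(55)
  net <- nn_network(list(nn_dense(16L, 8L), nn_tanh(), nn_dense(8L, 1L)),
                    c(4L, 4L, 1L))
  model <- structure(list(net = net, covid_node = 1L,
                          head_scheme = "single1"), class = "trained_model")
  x <- matrix(runif(16), 4, 4)
  bg <- background_set(lapply(1:5, function(i) matrix(runif(16), 4, 4)))
  # IG completeness to quadrature tolerance
  ig <- integrated_gradients(model, x, bg$images[[1]], n_alpha = 200)
  expect_lt(ig$completeness_gap, 1e-5)
  gap_at <- function(n) mean(vapply(1:6, function(s)
    expected_gradients(model, x, bg, n_samples = n, seed = s)$completeness_gap,
    numeric(1)))
  g_small <- gap_at(40); g_big <- gap_at(2500)
  expect_lt(g_big, g_small)
  expect_lt(g_big, 0.02)
})

test_that("percentile saliency is the rank transform", {
  set.seed(56)
  phi <- matrix(rnorm(64), 8, 8)
  while (anyDuplicated(abs(phi))) phi <- matrix(rnorm(64), 8, 8)
  map <- structure(list(phi = phi), class = "attribution_map")
  ps <- percentile_saliency(map)
  ord <- order(abs(phi))
  oracle <- numeric(64); oracle[ord] <- seq_len(64) / 64 * 100
  expect_equal(as.numeric(ps), oracle)
  # one huge pixel tops out at the 100th percentile
  phi2 <- matrix(0.01, 3, 3); phi2[2, 2] <- 100
  ps2 <- percentile_saliency(structure(list(phi = phi2),
                                       class = "attribution_map"))
  expect_equal(ps2[2, 2], 100)
  # monotone over strictly increasing values
  ps3 <- percentile_saliency(structure(list(phi = matrix(1:5, 1)),
                                       class = "attribution_map"))
  expect_true(all(diff(as.numeric(ps3)) > 0))
  # all-equal maps collapse to the 50th percentile by convention
  ps4 <- percentile_saliency(structure(list(phi = matrix(1, 2, 2)),
                                       class = "attribution_map"))
  expect_true(all(ps4 == 50))
})

test_that("identical backgrounds give correlation 1; equal-mean backgrounds
           agree for linear models", {
  set.seed(57)
  w <- matrix(rnorm(16), 4, 4)
  m <- linear_toy_model(w)
  x <- matrix(runif(16), 4, 4)
  bg_a <- background_set(lapply(1:4, function(i) matrix(runif(16), 4, 4)), "a")
  out <- background_sensitivity(m, x, bg_a, bg_a, n_samples = 100, seed = 5)
  expect_equal(out$correlation, 1.0)
  # second background: same mean, different members
  mu <- Reduce(`+`, bg_a$images) / 4
  bg_b <- background_set(list(mu + 0.1, mu - 0.1), "b")
  out2 <- background_sensitivity(m, x, bg_a, bg_b, n_samples = 3000, seed = 5)
  expect_gt(out2$correlation, 0.95)
})

test_that("consistent permutation of pixels permutes attributions", {
  set.seed(58)
  w <- matrix(rnorm(16), 4, 4)
  x <- matrix(runif(16), 4, 4)
  bg_imgs <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  perm <- sample(16)
  pm <- function(mat) matrix(as.numeric(mat)[perm], 4, 4)
  m1 <- linear_toy_model(w)
  m2 <- linear_toy_model(pm(w))
  map1 <- expected_gradients(m1, x, background_set(bg_imgs),
                             n_samples = 200, seed = 9)
  map2 <- expected_gradients(m2, pm(x), background_set(lapply(bg_imgs, pm)),
                             n_samples = 200, seed = 9)
  expect_equal(pm(map1$phi), map2$phi, tolerance = 1e-12)
})

test_that("saliency PNGs round-trip the percentile map", {
  set.seed(59)
  map <- structure(list(phi = matrix(rnorm(64), 8, 8)),
                   class = "attribution_map")
  path <- withr::local_tempfile(fileext = ".png")
  write_saliency_png(map, path)
  back <- png::readPNG(path)
  expect_equal(back * 100, percentile_saliency(map), tolerance = 100 / 255)
})
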