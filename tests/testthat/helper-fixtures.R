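# Shared fixtures, built once per test run and memoised. Heavy objects
# (trained models, the translation system) are only constructed when a test
# first asks for them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small worst-case marker-only dataset for fast unit tests
cached_marker_dataset <- function() cached("marker_ds", {
  p <- marker_only_profiles()
  generate_dataset(generation_config(n_per_source = 60, seed = 101),
                   p$A, p$B, pathology_spec(opacity_effect = 0))
})

# an analytic linear "model": f(x) = sum(w * x) + b
linear_toy_model <- function(w, b = 0) {
  list(covid_node = 1L,
       value_fn = function(image, node) sum(w * image) + b,
       grad_fn = function(image, node) w)
}

# ---- audit-scale fixtures (the study conditions; shared across the
# acceptance-property tests so each is trained/generated once) ----

# worst-case confounded, marker-only, 64x64, 400 images per source
audit_marker_data <- function() cached("audit_marker", {
  p <- marker_only_profiles()
  ds <- generate_dataset(generation_config(n_per_source = 400, seed = 2024),
                         p$A, p$B, pathology_spec(opacity_effect = 0))
  split <- assign_folds(ds, 0.1, 0.1, seed = 2024)
  list(ds = ds, split = split, profiles = p)
})

audit_marker_model <- function() cached("audit_marker_model", {
  d <- audit_marker_data()
  train_classifier(d$ds, d$split, arch = "dense-cnn",
                   hp = train_hyperparams(max_epochs = 3), seed = 7)
})

# identical sources, genuine lung-opacity signal only
audit_signal_data <- function() cached("audit_signal", {
  pa <- source_profile("A")
  pb <- source_profile("B")
  ds <- generate_dataset(
    generation_config(n_per_source = 200, seed = 2025,
                      confound_correlation = 0,
                      labeling_rule = "radiographic_evidence"),
    pa, pb, pathology_spec(opacity_effect = 0.3))
  split <- assign_folds(ds, 0.1, 0.1, seed = 2025)
  list(ds = ds, split = split)
})

audit_signal_model <- function() cached("audit_signal_model", {
  d <- audit_signal_data()
  train_classifier(d$ds, d$split, arch = "dense-cnn",
                   hp = train_hyperparams(max_epochs = 5), seed = 7)
})

# translation system between the two marker-only domains
audit_gan <- function() cached("audit_gan", {
  d <- audit_marker_data()
  tr <- fold_records(d$ds, d$split, "train")
  m <- tr$manifest
  train_cyclegan(tr$images[m$covid == 0][1:40],
                 tr$images[m$covid == 1][1:40],
                 epochs = 30, seed = 11)
})
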