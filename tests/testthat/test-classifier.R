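# AUROC contract, log-odds head, epoch selection and the trainability of
# each architecture variant.

test_that("AUROC handles perfect, inverted and tied rankings", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(compute_auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(compute_auroc(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("AUROC equals the pairwise counting oracle and pROC", {
  set.seed(41)
  for (rep in 1:5) {
    scores <- round(runif(20), 1)  # coarse grid forces ties
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    oracle <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(compute_auroc(scores, labels), oracle)
    expect_equal(compute_auroc(scores, labels),
                 as.numeric(suppressMessages(
                   pROC::auc(labels, scores, direction = "<"))))
  }
})

test_that("log-odds output inverts the sigmoid probability", {
  set.seed(42)
  net <- build_arch("simple-cnn", "single1", 32L)
  model <- structure(list(net = net, covid_node = 1L,
                          head_scheme = "single1", image_size = 32L),
                     class = "trained_model")
  for (rep in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    z <- predict_log_odds(model, img)
    p <- 1 / (1 + exp(-z))
    expect_equal(log(p / (1 - p)), z, tolerance = 1e-9)
  }
  expect_error(predict_log_odds(model, img, node = 2L), "node index")
})

test_that("a zero-weight model returns only its bias", {
  net <- build_arch("simple-cnn", "single1", 32L)
  for (l in net$layers) if (!is.null(l$W)) { l$W[] <- 0; l$b[] <- 0 }
  net$layers[[length(net$layers)]]$b <- 0.7
  model <- structure(list(net = net, covid_node = 1L,
                          head_scheme = "single1"), class = "trained_model")
  expect_equal(predict_log_odds(model, matrix(runif(1024), 32, 32)), 0.7)
})

test_that("hyperparameter defaults match the reference scheme", {
  hp <- train_hyperparams()
  expect_equal(hp$batch_size, 16L)
  expect_equal(hp$momentum, 0.9)
  expect_equal(hp$weight_decay, 1e-4)
  expect_equal(hp$lr, 0.01)
  expect_equal(hp$lr_decay_factor, 10)
  expect_equal(hp$lr_decay_every, 5L)
  expect_equal(hp$max_epochs, 30L)
  expect_error(train_hyperparams(lr = -1), "positive")
})

test_that("the selected epoch maximizes the validation AUROC trace", {
  ds <- cached_marker_dataset()
  sp <- assign_folds(ds, 0.2, 0.2, seed = 2)
  m <- train_classifier(ds, sp, arch = "simple-cnn",
                        hp = train_hyperparams(max_epochs = 3), seed = 5)
  expect_equal(m$selected_epoch, which.max(m$val_auroc_history))
  expect_length(m$val_auroc_history, 3L)
})

test_that("training refuses a single-class validation fold", {
  p <- marker_only_profiles(32)
  ds <- generate_dataset(generation_config(32, n_per_source = 10, seed = 1),
                         p$A, p$B, pathology_spec(opacity_effect = 0))
  sp <- assign_folds(ds, 0.2, 0.2, seed = 1)
  # force a single-class val fold by relabelling
  ds$manifest$covid[sp$fold[ds$manifest$record_id] == "val"] <- 0L
  ds$manifest$covid[sp$fold[ds$manifest$record_id] == "train"] <-
    rep_len(c(0L, 1L), sum(sp$fold == "train"))
  expect_error(train_classifier(ds, sp), "single class")
})

test_that("identical sources with no signal train to chance", {
  pa <- source_profile("A"); pb <- source_profile("B")
  ds <- generate_dataset(generation_config(n_per_source = 40, seed = 6),
                         pa, pb, pathology_spec(opacity_effect = 0))
  sp <- assign_folds(ds, 0.25, 0.25, seed = 1)
  m <- train_classifier(ds, sp, arch = "simple-cnn",
                        hp = train_hyperparams(max_epochs = 2), seed = 1)
  it <- fold_records(ds, sp, "test")
  auc <- compute_auroc(predict_scores(m, it$images), it$manifest$covid)
  # binomial-style bound at n = 20 test images
  expect_lt(abs(auc - 0.5), 0.35)
})

test_that("the logistic-embedding variant separates separable toy images", {
  # class decided by mean brightness: linearly separable in any monotone
  # embedding of intensity
  set.seed(44)
  n <- 24
  imgs <- lapply(seq_len(n), function(i) {
    lvl <- if (i %% 2 == 0) 0.8 else 0.2
    matrix(lvl + rnorm(1024, sd = 0.02), 32, 32)
  })
  man <- data.frame(record_id = sprintf("r%d", 1:n),
                    patient_id = sprintf("p%d", 1:n),
                    source_id = "A", covid = as.integer(seq_len(n) %% 2 == 0),
                    stringsAsFactors = FALSE)
  aux <- matrix(0L, n, 14, dimnames = list(NULL, sprintf("aux_%02d", 1:14)))
  man <- cbind(man, as.data.frame(aux))
  man$projection <- "PA"; man$sex_analogue <- "A"; man$has_signal <- man$covid
  ds <- structure(list(manifest = man, images = imgs,
                       config = list(image_size = 32L)), class = "sc_dataset")
  sp <- assign_folds(ds, 0.25, 0.25, seed = 2)
  m <- train_classifier(ds, sp, arch = "logistic-embedding",
                        hp = train_hyperparams(max_epochs = 4), seed = 1)
  tr <- fold_records(ds, sp, "train")
  expect_equal(compute_auroc(predict_scores(m, tr$images), tr$manifest$covid),
               1.0)
})

test_that("multi-label and single-label heads reach comparable COVID AUROC", {
  ds <- cached_marker_dataset()
  sp <- assign_folds(ds, 0.2, 0.2, seed = 3)
  p <- marker_only_profiles()
  eval_ds <- generate_dataset(generation_config(n_per_source = 150,
                                                seed = 777),
                              p$A, p$B, pathology_spec(opacity_effect = 0))
  aucs <- vapply(c("multi15", "single1"), function(h) {
    m <- train_classifier(ds, sp, arch = "simple-cnn", head_scheme = h,
                          hp = train_hyperparams(max_epochs = 5), seed = 2)
    compute_auroc(predict_scores(m, eval_ds$images), eval_ds$manifest$covid)
  }, numeric(1))
  expect_lt(abs(aucs[["multi15"]] - aucs[["single1"]]), 0.1)
})
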