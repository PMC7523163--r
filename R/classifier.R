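# The audited classifier family: a higher-capacity conv net, a simple conv
# net, and a logistic regression on a frozen conv embedding, each with a
# multi-label 15-node head (14 auxiliary pathologies + COVID) or a
# single-label head. Optimisation follows the reference scheme: mini-batch
# SGD, batch 16, momentum 0.9, weight decay 1e-4, lr 0.01 decayed 10x every
# 5 epochs, per-node binary cross entropy, and the final model is the epoch
# with the highest validation AUROC on the COVID node.

#' Training hyperparameters
#'
#' Defaults are the reference optimisation scheme and are not tuned per
#' dataset; only `max_epochs` is commonly lowered for small problems.
#'
#' @param batch_size mini-batch size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param lr initial learning rate.
#' @param lr_decay_factor divide lr by this every `lr_decay_every` epochs.
#' @param lr_decay_every epochs between decays.
#' @param max_epochs training epochs; epoch selection may pick any of them.
#' @return object of class `train_hyperparams`.
#' @export
train_hyperparams <- function(batch_size = 16L, momentum = 0.9,
                              weight_decay = 1e-4, lr = 0.01,
                              lr_decay_factor = 10, lr_decay_every = 5L,
                              max_epochs = 30L) {
  vals <- c(batch_size, momentum, weight_decay, lr, lr_decay_factor,
            lr_decay_every, max_epochs)
  if (any(vals <= 0)) stop("all hyperparameters must be positive")
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 max_epochs = as.integer(max_epochs)),
            class = "train_hyperparams")
}

build_arch <- function(arch, head_scheme, image_size) {
  n_out <- if (head_scheme == "multi15") 15L else 1L
  s <- as.integer(image_size)
  layers <- switch(arch,
    "dense-cnn" = list(
      nn_conv(1L, 8L), nn_relu(), nn_avgpool(),
      nn_conv(8L, 16L), nn_relu(), nn_avgpool(),
      nn_conv(16L, 16L), nn_relu(), nn_avgpool(),
      nn_dense((s %/% 8L)^2 * 16L, n_out)),
    "simple-cnn" = list(
      nn_conv(1L, 8L), nn_relu(), nn_avgpool(), nn_avgpool(),
      nn_dense((s %/% 4L)^2 * 8L, n_out)),
    "logistic-embedding" = list(
      nn_conv(1L, 16L, frozen = TRUE), nn_relu(), nn_avgpool(),
      nn_conv(16L, 32L, frozen = TRUE), nn_relu(), nn_avgpool(),
      nn_gap(), nn_dense(32L, n_out)),
    stop("unknown architecture: ", arch)
  )
  # classification heads start at zero (the no-information model): the
  # fit then grows weights only along label-relevant feature directions,
  # so input gradients — and hence attributions — reflect learned
  # structure rather than leftover random initialisation
  head <- layers[[length(layers)]]
  head$W[] <- 0; head$b[] <- 0
  nn_network(layers, c(s, s, 1L))
}

label_matrix <- function(manifest, head_scheme) {
  if (head_scheme == "multi15") {
    aux <- as.matrix(manifest[, sprintf("aux_%02d", 1:14)])
    cbind(aux, COVID = manifest$covid)
  } else {
    matrix(manifest$covid, ncol = 1L, dimnames = list(NULL, "COVID"))
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the normalized count of
#' positive-negative pairs ranked correctly, ties counted one half.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels 0/1 class labels.
#' @return AUROC in [0, 1].
#' @export
compute_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Train a classifier on a dataset split
#'
#' Mini-batch SGD with the scheme in [train_hyperparams()]; after each
#' epoch the COVID-node validation AUROC is recorded, and the returned
#' model carries the weights of the epoch that maximised it.
#'
#' @param ds an `sc_dataset`.
#' @param split a `split_spec` over `ds` (train and val folds used here).
#' @param arch "dense-cnn", "simple-cnn" or "logistic-embedding".
#' @param head_scheme "multi15" (14 auxiliary nodes + COVID) or "single1".
#' @param hp a [train_hyperparams()].
#' @param seed integer; controls initialisation and batch order.
#' @return object of class `trained_model` with fields `net`, `arch`,
#'   `head_scheme`, `covid_node`, `selected_epoch`, `val_auroc_history`,
#'   `train_loss_history`, `image_size`, `seed`.
#' @export
train_classifier <- function(ds, split, arch = "dense-cnn",
                             head_scheme = c("multi15", "single1"),
                             hp = train_hyperparams(), seed = 1L) {
  head_scheme <- match.arg(head_scheme)
  tr <- fold_records(ds, split, "train")
  va <- fold_records(ds, split, "val")
  if (nrow(tr$manifest) == 0L || nrow(va$manifest) == 0L)
    stop("train and val folds must be nonempty")
  if (length(unique(va$manifest$covid)) < 2L)
    stop("model selection impossible: validation fold has a single class")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  s <- ds$config$image_size %||% nrow(tr$images[[1]])
  net <- build_arch(arch, head_scheme, s)
  y_tr <- label_matrix(tr$manifest, head_scheme)
  n_nodes <- ncol(y_tr)
  covid_node <- n_nodes
  n_tr <- nrow(tr$manifest)

  val_hist <- numeric(hp$max_epochs)
  loss_hist <- numeric(hp$max_epochs)
  best <- NULL; best_auc <- -Inf; best_epoch <- NA_integer_
  for (epoch in seq_len(hp$max_epochs)) {
    lr <- hp$lr / hp$lr_decay_factor^((epoch - 1L) %/% hp$lr_decay_every)
    ord <- sample.int(n_tr)
    epoch_loss <- 0
    for (b0 in seq(1L, n_tr, hp$batch_size)) {
      idx <- ord[b0:min(b0 + hp$batch_size - 1L, n_tr)]
      nn_zero_grad(net)
      for (i in idx) {
        fw <- nn_forward(net, tr$images[[i]])
        z <- fw$out
        p <- sigmoid(z)
        y <- y_tr[i, ]
        eps <- 1e-12
        epoch_loss <- epoch_loss -
          sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) / n_nodes
        dz <- (p - y) / (n_nodes * length(idx))
        nn_backward(net, fw$caches, dz)
      }
      nn_sgd_step(net, lr, hp$momentum, hp$weight_decay)
    }
    loss_hist[epoch] <- epoch_loss / n_tr
    val_scores <- vapply(va$images,
                         function(im) nn_forward(net, im)$out[covid_node],
                         numeric(1))
    val_hist[epoch] <- compute_auroc(val_scores, va$manifest$covid)
    if (val_hist[epoch] > best_auc) {
      best_auc <- val_hist[epoch]
      best_epoch <- epoch
      best <- nn_get_params(net)
    }
  }
  nn_set_params(net, best)
  structure(list(net = net, arch = arch, head_scheme = head_scheme,
                 covid_node = covid_node, selected_epoch = best_epoch,
                 val_auroc_history = val_hist,
                 train_loss_history = loss_hist,
                 image_size = s, hp = hp, seed = as.integer(seed)),
            class = "trained_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s/%s, epoch %d/%d, val AUROC %.3f\n",
              x$arch, x$head_scheme, x$selected_epoch,
              length(x$val_auroc_history),
              x$val_auroc_history[x$selected_epoch]))
  invisible(x)
}

#' Pre-sigmoid log-odds of one output node
#'
#' The raw activation of the requested node under the per-node BCE head,
#' i.e. the log-odds `log(p / (1-p))` of that node's sigmoid probability —
#' the scale on which the behavioral tests measure output changes.
#'
#' @param model a `trained_model`.
#' @param image numeric matrix at the training resolution.
#' @param node node index; defaults to the COVID node.
#' @return scalar log-odds.
#' @export
predict_log_odds <- function(model, image, node = model$covid_node) {
  if (!is.null(model$value_fn)) return(model$value_fn(image, node))
  n_out <- if (model$head_scheme == "multi15") 15L else 1L
  if (node < 1L || node > n_out)
    stop("node index outside the head scheme")
  nn_forward(model$net, image)$out[node]
}

#' Log-odds scores for a list of images
#' @param model a `trained_model`.
#' @param images list of matrices.
#' @param node node index; defaults to the COVID node.
#' @return numeric vector of log-odds.
#' @export
predict_scores <- function(model, images, node = model$covid_node) {
  vapply(images, function(im) predict_log_odds(model, im, node), numeric(1))
}
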