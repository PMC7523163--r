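# Internal-vs-external evaluation: the generalization gap quantifies how
# much of a model's apparent performance rides on source-specific
# confounds, and the confound-transfer audit asks whether a candidate
# shortcut attribute (projection, sex analogue) is itself predictable
# across domains — a shortcut that transfers does NOT open a gap, which is
# why external validation alone can miss it.

#' Internal vs external test performance of a trained model
#'
#' @param model a `trained_model`.
#' @param internal_test `sc_dataset` of held-out records from the training
#'   distribution (must be disjoint from training by the split).
#' @param external_test `sc_dataset` from a different source composition.
#' @param node output node scored; defaults to the COVID node.
#' @return object of class `gap_report`: auroc_internal, auroc_external,
#'   gap (internal - external), n_internal, n_external.
#' @export
evaluate_generalization <- function(model, internal_test, external_test,
                                    node = model$covid_node) {
  for (d in list(internal_test, external_test)) {
    if (length(unique(d$manifest$covid)) < 2L)
      stop("test set has a single class; AUROC undefined")
  }
  ai <- compute_auroc(predict_scores(model, internal_test$images, node),
                      internal_test$manifest$covid)
  ae <- compute_auroc(predict_scores(model, external_test$images, node),
                      external_test$manifest$covid)
  structure(list(auroc_internal = ai, auroc_external = ae, gap = ai - ae,
                 n_internal = nrow(internal_test$manifest),
                 n_external = nrow(external_test$manifest)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(
    "<gap_report> internal AUROC %.3f (n=%d), external %.3f (n=%d), gap %.3f\n",
    x$auroc_internal, x$n_internal, x$auroc_external, x$n_external, x$gap))
  invisible(x)
}

#' Fraction of above-chance performance retained externally
#'
#' AUROC has a chance floor of 0.5, so "performance lost" is measured on
#' the above-chance scale: `(auroc_external - 0.5) / (auroc_internal - 0.5)`.
#'
#' @param report a `gap_report`.
#' @return scalar ratio (can be negative if external AUROC < 0.5).
#' @export
above_chance_retention <- function(report) {
  (report$auroc_external - 0.5) / (report$auroc_internal - 0.5)
}

#' Cross-domain predictability of a candidate confound attribute
#'
#' Trains fresh classifiers (default 5 replicates, seeds `seed + 0:4`) to
#' predict the attribute itself — radiographic projection (AP vs PA) or
#' the sex analogue — from the internal data, then scores each replicate
#' on internal held-out and external records. High external AUROC means the
#' attribute's visual cue transfers across domains and could silently
#' shortcut a disease classifier there.
#'
#' @param attribute "projection" (AP = 1 vs PA = 0) or "sex_analogue"
#'   (B = 1 vs A = 0).
#' @param internal_data,external_data `sc_dataset`s carrying the attribute.
#' @param n_replicates replicate count.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @param arch classifier architecture (default "simple-cnn").
#' @param hp a [train_hyperparams()].
#' @param test_frac,val_frac split fractions for the internal data.
#' @return object of class `confound_audit_report`: per-replicate internal
#'   and external AUROCs plus their means and sds.
#' @export
confound_transfer_audit <- function(attribute = c("projection",
                                                  "sex_analogue"),
                                    internal_data, external_data,
                                    n_replicates = 5L, seed = 1L,
                                    arch = "simple-cnn",
                                    hp = train_hyperparams(max_epochs = 5L),
                                    test_frac = 0.2, val_frac = 0.2) {
  attribute <- match.arg(attribute)
  as_label <- function(m) {
    if (attribute == "projection") {
      if (!all(m$projection %in% c("AP", "PA")))
        stop("projection audit needs PA/AP-filtered data")
      as.integer(m$projection == "AP")
    } else as.integer(m$sex_analogue == "B")
  }
  relabel <- function(ds) { ds$manifest$covid <- as_label(ds$manifest); ds }
  internal <- relabel(internal_data)
  external <- relabel(external_data)
  for (d in list(internal, external)) {
    if (length(unique(d$manifest$covid)) < 2L)
      stop("attribute '", attribute, "' is constant in one domain")
  }
  int_auc <- numeric(n_replicates); ext_auc <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sr <- seed + r - 1L
    split <- assign_folds(internal$manifest, test_frac, val_frac, seed = sr)
    model <- train_classifier(internal, split, arch = arch,
                              head_scheme = "single1", hp = hp, seed = sr)
    internal_test <- fold_records(internal, split, "test")
    rep_eval <- evaluate_generalization(model, internal_test, external)
    int_auc[r] <- rep_eval$auroc_internal
    ext_auc[r] <- rep_eval$auroc_external
  }
  structure(list(attribute = attribute,
                 auroc_internal = int_auc, auroc_external = ext_auc,
                 internal_mean = mean(int_auc), internal_sd = stats::sd(int_auc),
                 external_mean = mean(ext_auc), external_sd = stats::sd(ext_auc),
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "confound_audit_report")
}

#' @export
print.confound_audit_report <- function(x, ...) {
  cat(sprintf(
    "<confound_audit_report> %s: internal %.3f +/- %.3f, external %.3f +/- %.3f (n=%d)\n",
    x$attribute, x$internal_mean, x$internal_sd, x$external_mean,
    x$external_sd, x$n_replicates))
  invisible(x)
}
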