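# Manifest -> training structure: view filtering, label-scheme mapping and
# patient-grouped fold assignment.

#' Keep only PA and upright AP radiographs
#'
#' Lateral, supine-AP and unknown projections are removed; a message logs
#' the count dropped per category.
#'
#' @param manifest data.frame with a `projection` column (an `sc_dataset`
#'   is also accepted and subsetted in place).
#' @return the filtered object, same class as the input.
#' @export
filter_views <- function(manifest) {
  is_ds <- inherits(manifest, "sc_dataset") || !is.data.frame(manifest)
  m <- if (is_ds) manifest$manifest else manifest
  if (is.null(m$projection)) stop("manifest has no projection column")
  keep <- m$projection %in% c("PA", "AP")
  dropped <- table(m$projection[!keep])
  if (length(dropped))
    message("filter_views dropped: ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "))
  if (!any(keep)) warning("no PA/AP records remain after view filtering")
  if (is_ds) subset_dataset(manifest, keep)
  else { out <- m[keep, , drop = FALSE]; rownames(out) <- NULL; out }
}

#' Canonical 14 auxiliary pathology categories
#' @export
chest14_categories <- function() {
  c("atelectasis", "cardiomegaly", "effusion", "infiltration", "mass",
    "nodule", "pneumonia", "pneumothorax", "consolidation", "edema",
    "emphysema", "fibrosis", "pleural_thickening", "hernia")
}

#' Map free-vocabulary labels to the 15-node scheme
#'
#' Maps a record's source-vocabulary label set to the 14 canonical
#' auxiliary pathology categories plus a 15th COVID node. Terms absent
#' from the scheme are dropped and logged.
#'
#' @param source_labels character vector of labels for one record.
#' @param scheme named character vector mapping source terms to canonical
#'   category names (among [chest14_categories()]) or `"COVID"`.
#' @return integer 0/1 vector of length 15; names are the 14 categories
#'   then "COVID".
#' @export
map_labels <- function(source_labels, scheme) {
  if (!is.character(scheme) || is.null(names(scheme)))
    stop("scheme must be a named character vector")
  cats <- c(chest14_categories(), "COVID")
  bad_targets <- setdiff(unique(scheme), cats)
  if (length(bad_targets))
    stop("scheme maps to unknown categories: ",
         paste(bad_targets, collapse = ", "))
  out <- stats::setNames(integer(15L), cats)
  known <- source_labels %in% names(scheme)
  if (any(!known))
    message("map_labels dropped unmapped terms: ",
            paste(unique(source_labels[!known]), collapse = ", "))
  out[scheme[source_labels[known]]] <- 1L
  out
}

#' Patient-grouped train/val/test fold assignment
#'
#' Patients are atomic: every record of a patient lands in one fold.
#' Patients are shuffled under `seed`, then accumulated into the test fold
#' until its record quota (`test_frac` of all records) is met, then into
#' validation likewise; the remainder trains. Records named in
#' `fixed_test_ids` are pinned to the test fold first (a fixed test
#' partition analogue); if any patient has records both inside and outside
#' that set the assignment aborts, since honouring it would split the
#' patient.
#'
#' @param manifest data.frame with `record_id` and `patient_id` columns
#'   (or an `sc_dataset`).
#' @param test_frac,val_frac target record fractions in (0, 1).
#' @param seed integer seed for the patient shuffle.
#' @param fixed_test_ids optional character vector of record ids that must
#'   be in the test fold.
#' @return an object of class `split_spec`: list with `fold` (named factor
#'   over record ids, levels train/val/test), `fractions`, `seed`,
#'   `fixed_test_ids`.
#' @export
assign_folds <- function(manifest, test_frac = 0.05, val_frac = 0.05,
                         seed = 1L, fixed_test_ids = NULL) {
  m <- if (inherits(manifest, "sc_dataset")) manifest$manifest else manifest
  if (!all(c("record_id", "patient_id") %in% names(m)))
    stop("manifest needs record_id and patient_id columns")
  if (test_frac <= 0 || test_frac >= 1 || val_frac <= 0 || val_frac >= 1)
    stop("fractions must lie in (0, 1)")
  n <- nrow(m)
  fold <- stats::setNames(rep("train", n), m$record_id)

  fixed_patients <- character(0)
  if (length(fixed_test_ids)) {
    sel <- m$record_id %in% fixed_test_ids
    fixed_patients <- unique(m$patient_id[sel])
    outside <- m$patient_id %in% fixed_patients & !sel
    if (any(outside))
      stop("fixed_test_ids would split patient(s): ",
           paste(unique(m$patient_id[outside]), collapse = ", "))
    fold[sel] <- "test"
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  patients <- setdiff(unique(m$patient_id), fixed_patients)
  patients <- sample(patients)
  recs_per_patient <- table(m$patient_id)

  quota_test <- round(test_frac * n)
  quota_val <- round(val_frac * (n - quota_test))
  n_test <- sum(fold == "test")
  n_val <- 0L
  for (p in patients) {
    k <- recs_per_patient[[p]]
    if (n_test < quota_test) {
      fold[m$patient_id == p] <- "test"
      n_test <- n_test + k
    } else if (n_val < quota_val) {
      fold[m$patient_id == p] <- "val"
      n_val <- n_val + k
    }
  }
  structure(list(
    fold = factor(fold, levels = c("train", "val", "test")),
    fractions = c(test = test_frac, val = val_frac),
    seed = as.integer(seed),
    fixed_test_ids = fixed_test_ids
  ), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec>", paste(sprintf("%s=%d", names(table(x$fold)),
                                    table(x$fold)), collapse = " "), "\n")
  invisible(x)
}

#' Records of a dataset belonging to one fold
#' @param ds an `sc_dataset`.
#' @param split a `split_spec` from [assign_folds()].
#' @param which "train", "val" or "test".
#' @return the subsetted `sc_dataset`.
#' @export
fold_records <- function(ds, split, which) {
  ids <- names(split$fold)[split$fold == which]
  subset_dataset(ds, ds$manifest$record_id %in% ids)
}

#' Serialize a split to CSV
#' @param split a `split_spec`.
#' @param path output CSV (record_id, fold).
#' @export
write_split <- function(split, path) {
  utils::write.csv(
    data.frame(record_id = names(split$fold), fold = as.character(split$fold),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}
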