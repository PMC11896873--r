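# Classifier evaluation: confusion-matrix metrics, ROC and PR curves with
# explicit tie conventions, seeded k-fold splits, Murcko-scaffold splits,
# cross-validation of the D-MPNN, and the ROC evaluation protocol for the
# similarity-based screen.

#' Confusion counts from labels and binary calls
#'
#' @param labels True 0/1 labels.
#' @param calls Predicted 0/1 calls.
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, calls) {
  stopifnot(length(labels) == length(calls),
            all(labels %in% c(0, 1)), all(calls %in% c(0, 1)))
  tibble(
    TP = sum(labels == 1 & calls == 1),
    TN = sum(labels == 0 & calls == 0),
    FP = sum(labels == 0 & calls == 1),
    FN = sum(labels == 1 & calls == 0)
  )
}

#' Threshold classification metrics
#'
#' Sensitivity (recall, TP/(TP+FN)), specificity (TN/(TN+FP)), accuracy,
#' balanced accuracy (mean of sensitivity and specificity) and the Matthews
#' correlation coefficient. MCC is defined as 0 whenever a denominator
#' factor vanishes (the documented convention for one-sided predictions).
#'
#' @param counts One-row tibble or list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble of the metrics plus the counts.
#' @examples
#' classification_metrics(data.frame(TP = 40, FN = 10, TN = 30, FP = 20))
#' @export
classification_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  total <- TP + TN + FP + FN
  if (length(total) != 1L || total == 0) abort("empty confusion table")
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / total
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
  tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    balanced_accuracy = (sens + spec) / 2, mcc = mcc,
    TP = TP, TN = TN, FP = FP, FN = FN
  )
}

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected probability that a random positive outscores
#' a random negative (midrank Mann-Whitney; ties earn half credit,
#' equivalent to trapezoidal integration over tied thresholds). The curve is
#' the standard FPR/TPR staircase over the distinct score thresholds.
#'
#' @param labels True 0/1 labels (both classes must be present).
#' @param scores Real-valued scores (higher = more positive).
#' @return List with `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("undefined AUC: both classes required")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  curve <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and AUC
#'
#' Step-wise interpolated PR staircase: the AUC sums precision at each
#' achieved recall increment (no linear interpolation between points).
#'
#' @inheritParams roc_curve_auc
#' @return List with `curve` (tibble `threshold`, `recall`, `precision`)
#'   and `auc`.
#' @export
pr_curve_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  if (n1 == 0) abort("undefined PR-AUC: no positives")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  pred_pos <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  prec <- tp / pred_pos
  rec <- tp / n1
  auc <- sum(diff(c(0, rec)) * prec)
  list(curve = tibble(threshold = thr, recall = rec, precision = prec),
       auc = auc)
}

#' Seeded k-fold partition
#'
#' Random partition into `k` near-equal groups (unstratified by default,
#' matching common cross-validation behavior for these models; set
#' `stratified = TRUE` to balance classes per fold for small or imbalanced
#' data).
#'
#' @param data Dataset tibble.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the shuffle.
#' @param stratified Balance the class ratio across folds.
#' @return Integer vector of fold assignments (1..k), one per row.
#' @export
kfold_splits <- function(data, k, seed = 1L, stratified = FALSE) {
  n <- nrow(data)
  if (k < 2L) abort("k must be at least 2")
  if (n < k) abort("fewer records than folds")
  set.seed(seed)
  fold <- integer(n)
  if (stratified && "label" %in% names(data)) {
    for (cl in unique(data$label)) {
      ix <- which(data$label == cl)
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Murcko framework scaffold of a molecule
#'
#' Side chains are pruned (terminal atoms removed iteratively), leaving ring
#' systems and the linkers between them with atom and bond types retained;
#' the scaffold key is the canonical SMILES of that subgraph. Acyclic
#' molecules have no framework and form their own singleton class keyed by
#' their full canonical SMILES.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of scaffold keys.
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  uniq <- unique(smiles)
  keys <- vapply(uniq, murcko_scaffold_one, character(1))
  unname(keys[match(smiles, uniq)])
}

murcko_scaffold_one <- function(smi) {
  mol <- parse_molecules(smi)[[1]]
  if (!any(mol$atoms$in_ring)) return(paste0("acyclic:", smi))
  keep <- rep(TRUE, mol$n_atoms)
  bonds <- mol$bonds
  repeat {
    deg <- tabulate(c(bonds$a1[keep[bonds$a1] & keep[bonds$a2]],
                      bonds$a2[keep[bonds$a1] & keep[bonds$a2]]),
                    nbins = mol$n_atoms)
    drop <- which(keep & deg <= 1L & !mol$atoms$in_ring)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smi, "m")))[[1]]
  sub <- ChemmineR::atomsubset(sdf, which(keep))
  txt <- paste0(paste(ChemmineR::sdf2str(sub), collapse = "\n"), "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                  error = function(e) "")
  key <- strsplit(trimws(out), "\t")[[1]][1]
  if (is.na(key) || !nzchar(key)) paste0("unresolved:", smi) else key
}

#' Scaffold-based train/test split
#'
#' Groups records by Murcko framework scaffold and places whole groups into
#' the test side, largest group first (size ties broken by a seeded
#' shuffle), until the test fraction is reached; everything else trains. No
#' scaffold ever appears on both sides, so the test set probes
#' generalization to unseen chemotypes.
#'
#' @param data Standardized dataset tibble.
#' @param test_fraction Target fraction of records in the test side, in
#'   (0, 1).
#' @param seed Seed for tie-breaking.
#' @return List with `train` and `test` tibbles (each with an added
#'   `scaffold` column).
#' @export
scaffold_split <- function(data, test_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)")
  }
  data$scaffold <- murcko_scaffold(data$canonical_smiles)
  groups <- split(seq_len(nrow(data)), data$scaffold)
  sizes <- lengths(groups)
  set.seed(seed)
  ord <- order(-sizes, sample.int(length(groups)))
  target <- round(test_fraction * nrow(data))
  test_ix <- integer(0)
  for (gi in ord) {
    if (length(test_ix) >= target) break
    test_ix <- c(test_ix, groups[[gi]])
  }
  if (length(test_ix) >= nrow(data) || length(test_ix) == 0L) {
    abort("cannot satisfy fraction without leakage: too few scaffold groups")
  }
  list(train = as_tibble(data[-sort(test_ix), , drop = FALSE]),
       test = as_tibble(data[sort(test_ix), , drop = FALSE]))
}

#' Cross-validate a D-MPNN configuration
#'
#' Runs [kfold_splits()], trains an ensemble on each training fold, predicts
#' the left-out fold and computes the full metric bundle per fold plus a
#' mean/sd summary across folds. Every record is scored exactly once as
#' test.
#'
#' @param data Labeled standardized dataset tibble.
#' @param config A [dmpnn_config()]; `config$seed` also seeds the fold
#'   assignment.
#' @param k Number of folds.
#' @param stratified Passed to [kfold_splits()].
#' @return A `dmpnn_cv` object with elements `folds` (per-fold metrics
#'   tibble), `predictions` (out-of-fold scores for every record) and
#'   `summary` (mean and sd per metric); see [tidy.dmpnn_cv()].
#' @export
cross_validate <- function(data, config = dmpnn_config(), k = 5L,
                           stratified = FALSE) {
  check_trainable(data)
  fold <- kfold_splits(data, k, seed = config$seed, stratified = stratified)
  fold_rows <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    fit <- train_dmpnn(train, config)
    p <- predict(fit, test)
    p$label <- test$label
    p$fold <- f
    preds[[f]] <- p
    m <- classification_metrics(confusion_counts(test$label, p$call))
    m$roc_auc <- roc_curve_auc(test$label, p$probability)$auc
    m$pr_auc <- pr_curve_auc(test$label, p$probability)$auc
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f, n_test = nrow(test)), m)
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy",
                   "balanced_accuracy", "mcc", "roc_auc", "pr_auc")
  summary <- tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(folds[[mc]]), numeric(1)),
    sd = vapply(metric_cols, function(mc) sd(folds[[mc]]), numeric(1))
  )
  structure(list(folds = folds, predictions = dplyr::bind_rows(preds),
                 summary = summary, k = k, config = config),
            class = "dmpnn_cv")
}

#' @describeIn cross_validate Per-fold metrics, one row per fold.
#' @param x A `dmpnn_cv`.
#' @param ... Unused.
#' @export
tidy.dmpnn_cv <- function(x, ...) x$folds

#' @describeIn cross_validate One row per metric with cross-fold mean and
#'   sd.
#' @export
glance.dmpnn_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' @export
print.dmpnn_cv <- function(x, ...) {
  cat(sprintf("<dmpnn_cv: %d folds>\n", x$k))
  print(x$summary)
  invisible(x)
}

#' Evaluate a similarity-based screen against external potency data
#'
#' Implements the retrieval benchmark for MAX-Tanimoto screening: external
#' records are binarized by potency (active at or below `active_cutoff`,
#' inactive at or above `inactive_cutoff`, the gray zone in between
#' dropped), deduplicated, stripped of any structure already present in the
#' reference set, scored by maximum Tanimoto similarity to the reference
#' compounds, and summarized by ROC-AUC.
#'
#' @param reference Standardized reference dataset tibble (known actives).
#' @param external Standardized dataset tibble with a `potency` column in
#'   molar units.
#' @param active_cutoff Potency at or below which a record is active
#'   (default 1e-6 M, i.e. 1 uM).
#' @param inactive_cutoff Potency at or above which a record is inactive
#'   (default 1e-5 M, i.e. 10 uM).
#' @param radius,width Fingerprint parameters.
#' @return List with `auc`, `curve`, `scores` (per-record MAX score and
#'   binary label) and `n_dropped` (gray zone + overlap + duplicates).
#' @export
evaluate_similarity_screen <- function(reference, external,
                                       active_cutoff = 1e-6,
                                       inactive_cutoff = 1e-5,
                                       radius = 2L, width = 2048L) {
  stopifnot(is.data.frame(reference), is.data.frame(external),
            "potency" %in% names(external),
            active_cutoff < inactive_cutoff)
  n0 <- nrow(external)
  ext <- external[!is.na(external$potency), , drop = FALSE]
  ext$label <- ifelse(ext$potency <= active_cutoff, 1L,
                      ifelse(ext$potency >= inactive_cutoff, 0L, NA_integer_))
  ext <- ext[!is.na(ext$label), , drop = FALSE]
  ext <- ext[!duplicated(ext$canonical_smiles), , drop = FALSE]
  ext <- ext[!ext$canonical_smiles %in% reference$canonical_smiles, , drop = FALSE]
  if (length(unique(ext$label)) < 2L) {
    abort("one class empty after potency filtering and overlap removal")
  }
  ref_fp <- add_fingerprints(reference, radius, width)
  ext_fp <- add_fingerprints(ext, radius, width)
  sim <- max_similarity(ext_fp, ref_fp)
  roc <- roc_curve_auc(ext$label, sim$max_score)
  scores <- dplyr::left_join(sim, ext[, c("record_id", "label", "potency")],
                             by = "record_id")
  list(auc = roc$auc, curve = roc$curve, scores = scores,
       n_dropped = n0 - nrow(ext))
}
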