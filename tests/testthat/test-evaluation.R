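test_that("the worked confusion-table example reproduces exactly", {
  m <- classification_metrics(data.frame(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_identical(m$sensitivity, 0.8)
  expect_identical(m$specificity, 0.6)
  expect_identical(m$accuracy, 0.7)
  expect_identical(m$balanced_accuracy, 0.7)
  expect_equal(m$mcc, (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40),
               tolerance = 1e-15)
  expect_equal(m$mcc, 0.4082483, tolerance = 1e-7)
})

test_that("metrics match the formula oracle on random tables", {
  set.seed(21)
  for (i in 1:200) {
    cnt <- as.list(sample(0:40, 4, replace = TRUE))
    names(cnt) <- c("TP", "FN", "TN", "FP")
    if (sum(unlist(cnt)) == 0) cnt$TP <- 1L
    m <- classification_metrics(cnt)
    o <- oracle_metrics(cnt$TP, cnt$FN, cnt$TN, cnt$FP)
    for (k in names(o)) expect_equal(m[[k]], o[[k]], tolerance = 1e-14)
  }
})

test_that("MCC is 0 whenever a denominator factor vanishes", {
  expect_identical(classification_metrics(list(TP = 5, FN = 0, TN = 0, FP = 5))$mcc, 0)
  expect_identical(classification_metrics(list(TP = 0, FN = 3, TN = 4, FP = 0))$mcc, 0)
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "empty confusion table")
})

test_that("confusion_counts tallies each cell", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_identical(unlist(cc[, c("TP", "TN", "FP", "FN")]),
                   c(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
  expect_error(confusion_counts(c(1, 2), c(0, 1)))
})

test_that("ROC-AUC equals the concordant-pair oracle with tie credit", {
  # perfect, inverted, and tied orderings
  expect_identical(roc_curve_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_identical(roc_curve_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$auc, 0)
  expect_identical(roc_curve_auc(c(0, 1), c(0.5, 0.5))$auc, 0.5)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(roc_curve_auc(labels, scores)$auc, oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(8)
  labels <- sample(0:1, 100, replace = TRUE, prob = c(0.6, 0.4))
  scores <- rnorm(100) + labels
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<", quiet = TRUE)))
  expect_equal(roc_curve_auc(labels, scores)$auc, ref, tolerance = 1e-12)
})

test_that("ROC curve is a staircase from (0,0) to (1,1)", {
  set.seed(9)
  labels <- sample(0:1, 30, replace = TRUE)
  labels[1:2] <- 0:1
  scores <- runif(30)
  cv <- roc_curve_auc(labels, scores)$curve
  expect_identical(cv$fpr[1], 0)
  expect_identical(cv$tpr[1], 0)
  expect_identical(cv$fpr[nrow(cv)], 1)
  expect_identical(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  expect_error(roc_curve_auc(c(1, 1), c(0.2, 0.3)), "undefined AUC")
})

test_that("PR-AUC matches step-wise hand integration", {
  labels <- c(1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  # thresholds 0.9..0.5: recall 0.5 at precision 1, recall 1 at precision 2/3
  expect_equal(pr_curve_auc(labels, scores)$auc, 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  expect_identical(pr_curve_auc(c(1, 1, 0), c(0.9, 0.8, 0.1))$auc, 1)
  expect_error(pr_curve_auc(c(0, 0), c(0.1, 0.2)), "no positives")
})

test_that("k-fold assignment covers every record exactly once", {
  data <- tibble::tibble(x = 1:103)
  fold <- kfold_splits(data, k = 5, seed = 2)
  expect_length(fold, 103L)
  expect_setequal(unique(fold), 1:5)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  expect_identical(fold, kfold_splits(data, k = 5, seed = 2))
  expect_false(identical(fold, kfold_splits(data, k = 5, seed = 3)))
  expect_error(kfold_splits(data, k = 1), "at least 2")
  expect_error(kfold_splits(data[1:3, , drop = FALSE], k = 5), "fewer records")
})

test_that("stratified folds balance the classes", {
  data <- tibble::tibble(label = rep(c(0L, 1L), c(80, 20)))
  fold <- kfold_splits(data, k = 5, seed = 1, stratified = TRUE)
  pos_per_fold <- tapply(data$label, fold, sum)
  expect_true(all(pos_per_fold == 4))
})

test_that("Murcko scaffolds strip side chains and keep frameworks", {
  expect_identical(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("CCOc1ccccc1"))
  expect_identical(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("c1ccccc1"))
  expect_false(murcko_scaffold("c1ccccc1") == murcko_scaffold("C1CCCCC1"))
  expect_match(murcko_scaffold("CCO"), "^acyclic:")
  # two-ring framework retains the linker
  expect_identical(murcko_scaffold("Cc1ccc(Cc2ccccc2)cc1"),
                   murcko_scaffold("c1ccc(Cc2ccccc2)cc1"))
})

test_that("scaffold split never leaks a scaffold across sides", {
  data <- generate_motif_dataset(n_compounds = 120L, seed = 13L)
  sp <- scaffold_split(data, test_fraction = 0.2, seed = 1L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(data))
  expect_length(intersect(sp$train$scaffold, sp$test$scaffold), 0L)
  expect_gte(nrow(sp$test), round(0.2 * nrow(data)))
  # degenerate: a single scaffold class cannot be split
  one <- standardize_smiles(c("c1ccccc1C", "c1ccccc1CC", "c1ccccc1O"))
  expect_error(scaffold_split(one, 0.2), "cannot satisfy fraction")
})

test_that("cross_validate scores every record exactly once out-of-fold", {
  data <- tiny_labeled_set(60L, seed = 4L)
  cfg <- dmpnn_config(hidden_size = 16L, epochs = 4L, ensemble_size = 1L,
                      batch_size = 20L, seed = 1L)
  cv <- cross_validate(data, cfg, k = 3L)
  expect_s3_class(cv, "dmpnn_cv")
  expect_identical(nrow(cv$folds), 3L)
  expect_setequal(cv$predictions$record_id, data$record_id)
  expect_identical(anyDuplicated(cv$predictions$record_id), 0L)
  expect_identical(nrow(cv$summary), 7L)
  expect_identical(tidy(cv), cv$folds)
  gl <- glance(cv)
  expect_identical(nrow(gl), 1L)
  expect_true("mean_roc_auc" %in% names(gl))
  expect_output(print(cv), "3 folds")
})

test_that("similarity screen applies the documented potency protocol", {
  bench <- generate_similarity_benchmark(seed = 3L, n_reference = 8L,
                                         n_active = 15L, n_inactive = 30L)
  ext <- bench$external
  # add a gray-zone record and a reference-overlap record
  gray <- ext[1, ]
  gray$record_id <- "gray"
  gray$potency <- 5e-6
  overlap <- ext[1, ]
  overlap$record_id <- "overlap"
  overlap$canonical_smiles <- bench$reference$canonical_smiles[1]
  overlap$potency <- 1e-7
  res <- evaluate_similarity_screen(bench$reference,
                                    rbind(ext, gray, overlap))
  expect_identical(res$n_dropped, 2L)
  expect_identical(nrow(res$scores), nrow(ext))
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_gt(res$auc, 0.8)
  # scores carry the binarized label, matching the generator's
  expect_identical(res$scores$label, ext$label)
  bad <- ext
  bad$potency <- rep(1e-8, nrow(bad))
  expect_error(evaluate_similarity_screen(bench$reference, bad),
               "one class empty")
})
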