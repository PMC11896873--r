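# Small shared fixtures: one similarity model, one reduced-scale gcnn model.
ref <- standardize_smiles(
  c("Cc1ccc2ccccc2c1", "Oc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1",
    "Nc1ccc2ccccc2c1"), id = paste0("ref", 1:4))
sim_model <- fit_transporter_model("OAT1", mode = "inhibitor",
                                   approach = "similarity", reference = ref,
                                   gene_symbol = "SLC22A6")
gcnn_model <- fit_transporter_model(
  "Pgp", mode = "inhibitor", approach = "gcnn",
  data = tiny_labeled_set(30L, seed = 8L),
  gene_symbol = "ABCB1",
  config = dmpnn_config(hidden_size = 8L, epochs = 2L, ensemble_size = 1L,
                        batch_size = 10L))

test_that("the packaged registry mirrors the published target assignment", {
  reg <- load_registry()
  expect_s3_class(reg, "transporter_registry")
  expect_identical(nrow(reg$spec), 24L)
  expect_identical(sum(reg$spec$approach == "gcnn"), 9L)
  expect_identical(sum(reg$spec$approach == "similarity"), 15L)
  expect_identical(sum(reg$spec$mode == "inhibitor"), 12L)
  expect_identical(sum(reg$spec$mode == "substrate"), 12L)
  inh_gcnn <- reg$spec$target_name[reg$spec$mode == "inhibitor" &
                                     reg$spec$approach == "gcnn"]
  expect_setequal(inh_gcnn, c("Pgp", "BCRP", "MRP1", "BSEP", "OATP1B1",
                              "OATP1B3"))
  sub_gcnn <- reg$spec$target_name[reg$spec$mode == "substrate" &
                                     reg$spec$approach == "gcnn"]
  expect_setequal(sub_gcnn, c("Pgp", "BCRP", "MRP1"))
  expect_identical(length(unique(reg$spec$gene_symbol)), 12L)
  expect_length(reg$models, 0L)           # shipped config has no artifacts
  expect_output(print(reg), "24 entries")
})

test_that("registry validation catches duplicates and bad fields", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(
    target_name = c("Pgp", "Pgp"), gene_symbol = "ABCB1",
    mode = "inhibitor", approach = "gcnn"), tmp)
  expect_error(load_registry(tmp), "duplicate \\(target, mode\\)")
  jsonlite::write_json(data.frame(
    target_name = "Pgp", gene_symbol = "ABCB1",
    mode = "inhibitor", approach = "magic"), tmp)
  expect_error(load_registry(tmp))
  jsonlite::write_json(list(), tmp)
  expect_warning(reg <- load_registry(tmp), "empty registry")
  expect_identical(nrow(reg$spec), 0L)
  jsonlite::write_json(data.frame(
    target_name = "Pgp", gene_symbol = "ABCB1", mode = "inhibitor",
    approach = "gcnn", model_path = "does_not_exist"), tmp)
  expect_error(load_registry(tmp), "model artifact not found")
})

test_that("fit_transporter_model validates its inputs", {
  expect_error(fit_transporter_model("X", approach = "gcnn"),
               "needs a labeled 'data' set")
  expect_error(fit_transporter_model("X", approach = "similarity"),
               "non-empty 'reference' set")
  expect_identical(sim_model$approach, "similarity")
  expect_identical(sim_model$ad$n_training, 4L)
  expect_gt(sim_model$ad$threshold, 0)
  expect_output(print(sim_model), "OAT1/inhibitor")
})

test_that("profile rows number |queries| x |registry models|", {
  reg <- build_registry(list(sim_model, gcnn_model))
  queries <- standardize_smiles(c("Clc1ccc2ccccc2c1", "CCO", "C1CC"),
                                id = c("q1", "q2", "bad"))
  prof <- profile_batch(queries, reg)
  expect_s3_class(prof, "screening_profile")
  expect_identical(nrow(prof), nrow(queries) * length(reg$models))
  expect_identical(sum(prof$status == "ok"), 4L)
  expect_identical(sum(grepl("^rejected:", prof$status)),
                   1L * length(reg$models))
  bad_rows <- prof[prof$record_id == "bad", ]
  expect_true(all(is.na(bad_rows$score)))
  expect_identical(unique(bad_rows$status), "rejected:parse_error")
  ok_rows <- prof[prof$status == "ok", ]
  expect_true(all(ok_rows$call %in% c("active", "inactive")))
  expect_identical(ok_rows$call,
                   ifelse(ok_rows$score >= ok_rows$threshold,
                          "active", "inactive"))
  expect_true(all(ok_rows$in_domain %in% c(TRUE, FALSE)))
  # a naphthalene query scores well against the naphthalene reference set
  q1sim <- prof[prof$record_id == "q1" & prof$approach == "similarity", ]
  expect_gt(q1sim$score, 0.3)
  q2sim <- prof[prof$record_id == "q2" & prof$approach == "similarity", ]
  expect_gt(q1sim$score, q2sim$score)
})

test_that("batch limits and empty registries are enforced", {
  reg <- build_registry(list(sim_model))
  queries <- standardize_smiles(c("CCO", "CCN", "CCC"))
  expect_error(profile_batch(queries, reg, batch_limit = 2), "batch limit exceeded")
  empty <- load_registry()
  expect_error(profile_batch(queries, empty), "registry has no scoring models")
  expect_error(build_registry(list(sim_model, sim_model)), "duplicate")
})

test_that("transporter models round-trip through disk", {
  dir_s <- withr::local_tempdir()
  save_transporter_model(sim_model, file.path(dir_s, "sim"))
  save_transporter_model(gcnn_model, file.path(dir_s, "gcnn"))
  sim2 <- load_transporter_model(file.path(dir_s, "sim"))
  gc2 <- load_transporter_model(file.path(dir_s, "gcnn"))
  expect_equal(sim2$ad$threshold, sim_model$ad$threshold, tolerance = 1e-12)
  expect_identical(sim2$reference$canonical_smiles,
                   sim_model$reference$canonical_smiles)
  queries <- standardize_smiles(c("Cc1ccc2ccccc2c1", "CCO"))
  p1 <- profile_batch(queries, build_registry(list(sim_model, gcnn_model)))
  p2 <- profile_batch(queries, build_registry(list(sim2, gc2)))
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
  expect_identical(p1$call, p2$call)
  # registry config can reference the saved artifacts by path
  cfgp <- file.path(dir_s, "reg.json")
  jsonlite::write_json(data.frame(
    target_name = c("OAT1", "Pgp"), gene_symbol = c("SLC22A6", "ABCB1"),
    mode = "inhibitor", approach = c("similarity", "gcnn"),
    model_path = c("sim", "gcnn")), cfgp)
  reg3 <- load_registry(cfgp)
  expect_length(reg3$models, 2L)
  p3 <- profile_batch(queries, reg3)
  expect_equal(p3$score, p1$score, tolerance = 1e-12)
  # approach mismatch between registry and artifact is an error
  jsonlite::write_json(data.frame(
    target_name = "OAT1", gene_symbol = "SLC22A6", mode = "inhibitor",
    approach = "gcnn", model_path = "sim"), cfgp)
  expect_error(load_registry(cfgp), "approach mismatch")
})

test_that("profiles round-trip through CSV and mask only out-of-domain cells", {
  reg <- build_registry(list(sim_model, gcnn_model))
  queries <- standardize_smiles(c("Cc1ccc2ccccc2c1", "CCCCCCCCCCCCCCCC", "C1CC"),
                                id = c("near", "far", "bad"))
  prof <- profile_batch(queries, reg)
  out <- withr::local_tempdir()
  paths <- write_profile(prof, out)
  expect_true(file.exists(file.path(out, "profile_long.csv")))
  back <- read_profile(file.path(out, "profile_long.csv"))
  expect_identical(back$record_id, prof$record_id)
  expect_equal(back$score, prof$score, tolerance = 1e-12)
  expect_identical(back$call, prof$call)
  un <- readr::read_csv(file.path(out, "profile_inhibitor_unmasked.csv"),
                        show_col_types = FALSE)
  ma <- readr::read_csv(file.path(out, "profile_inhibitor_ad_masked.csv"),
                        show_col_types = FALSE)
  expect_identical(dim(un), dim(ma))
  for (tg in setdiff(names(un), "record_id")) {
    sub <- prof[prof$target == tg, ]
    sub <- sub[match(un$record_id, sub$record_id), ]
    in_dom <- !is.na(sub$in_domain) & sub$in_domain
    expect_identical(ma[[tg]][in_dom], un[[tg]][in_dom])
    expect_true(all(ma[[tg]][!is.na(sub$in_domain) & !sub$in_domain] ==
                      "out_of_domain"))
  }
  expect_error(write_profile(prof[0, ], out), "empty profile")
})

test_that("profile and cv autoplots build", {
  reg <- build_registry(list(sim_model))
  prof <- profile_batch(standardize_smiles(c("CCO", "Cc1ccc2ccccc2c1")), reg)
  p <- ggplot2::autoplot(prof)
  expect_s3_class(p, "ggplot")
  roc <- roc_curve_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.4, 0.6))
  expect_s3_class(plot_curve(roc$curve, roc$auc), "ggplot")
  pr <- pr_curve_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.4, 0.6))
  expect_s3_class(plot_curve(pr$curve, pr$auc), "ggplot")
})
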