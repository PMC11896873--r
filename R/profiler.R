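# Per-target model registry and batch screening. Each registered
# (transporter, mode) pair carries either a trained D-MPNN ensemble
# ("gcnn" approach, data-rich targets) or a reference compound set scored by
# maximum Tanimoto similarity ("similarity" approach, data-poor targets).
# Every prediction row additionally carries the SDC applicability-domain
# score against that model's training/reference chemistry.

#' Fit a transporter screening model
#'
#' Builds one registry entry: either a D-MPNN ensemble trained on a labeled
#' dataset (`approach = "gcnn"`) or a MAX-Tanimoto similarity screen over a
#' reference set of known actives (`approach = "similarity"`). In both
#' cases the SDC applicability domain is calibrated on the model's own
#' training/reference fingerprints.
#'
#' @param target_name Transporter name (e.g. `"Pgp"`).
#' @param mode `"inhibitor"` or `"substrate"`.
#' @param approach `"gcnn"` or `"similarity"`.
#' @param data Labeled standardized dataset (gcnn approach).
#' @param reference Standardized reference-actives dataset (similarity
#'   approach).
#' @param gene_symbol Optional gene symbol annotation.
#' @param config [dmpnn_config()] for the gcnn approach.
#' @param call_threshold Score cutoff for the active call (probability for
#'   gcnn, MAX similarity for similarity screening; default 0.5 for both).
#' @param radius,width Fingerprint parameters for similarity and SDC.
#' @param ad_percentile Percentile for [calibrate_sdc_threshold()].
#' @return A `transporter_model` object.
#' @export
fit_transporter_model <- function(target_name, mode = c("inhibitor", "substrate"),
                                  approach = c("gcnn", "similarity"),
                                  data = NULL, reference = NULL,
                                  gene_symbol = "", config = dmpnn_config(),
                                  call_threshold = 0.5, radius = 2L,
                                  width = 2048L, ad_percentile = 0.05) {
  mode <- match.arg(mode)
  approach <- match.arg(approach)
  if (approach == "gcnn") {
    if (is.null(data)) abort("gcnn approach needs a labeled 'data' set")
    ensemble <- train_dmpnn(data, config)
    dom_smiles <- data$canonical_smiles
  } else {
    if (is.null(reference) || nrow(reference) == 0L) {
      abort("similarity approach needs a non-empty 'reference' set")
    }
    ensemble <- NULL
    dom_smiles <- reference$canonical_smiles
  }
  dom_fps <- lapply(parse_molecules(dom_smiles), morgan_fp_mol,
                    radius = radius, width = width)
  ad_threshold <- calibrate_sdc_threshold(dom_fps, ad_percentile)
  structure(list(
    target_name = target_name, gene_symbol = gene_symbol, mode = mode,
    approach = approach, ensemble = ensemble,
    reference = if (approach == "similarity")
      reference[, c("record_id", "canonical_smiles")] else NULL,
    call_threshold = call_threshold, radius = as.integer(radius),
    width = as.integer(width), domain_smiles = dom_smiles,
    ad = list(threshold = ad_threshold, n_training = length(dom_fps),
              percentile = ad_percentile)
  ), class = "transporter_model")
}

#' @export
print.transporter_model <- function(x, ...) {
  cat(sprintf("<transporter_model %s/%s: %s, n=%d, AD threshold %.3g>\n",
              x$target_name, x$mode, x$approach, x$ad$n_training,
              x$ad$threshold))
  invisible(x)
}

#' Save / load a transporter model
#'
#' A model is stored as a directory with `config.json` (target, mode,
#' approach, thresholds, fingerprint parameters, reference/training SMILES)
#' and, for the gcnn approach, member parameter files.
#'
#' @param model A `transporter_model`.
#' @param dir Directory to create.
#' @return `dir` (save) or the restored `transporter_model` (load).
#' @export
save_transporter_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- model[c("target_name", "gene_symbol", "mode", "approach",
                  "call_threshold", "radius", "width", "domain_smiles")]
  meta$ad <- model$ad
  if (!is.null(model$reference)) meta$reference <- as.list(model$reference)
  if (!is.null(model$ensemble)) {
    meta$config <- unclass(model$ensemble$config)
    meta$digest <- model$ensemble$training_dataset_digest
    meta$label_prevalence <- model$ensemble$label_prevalence
    meta$n_training <- model$ensemble$n_training
    meta$training_smiles <- model$ensemble$training_smiles
    saveRDS(lapply(model$ensemble$members, `[`,
                   c("params", "loss", "din", "da", "member_seed")),
            file.path(dir, "members.rds"))
  }
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_transporter_model
#' @export
load_transporter_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  ensemble <- NULL
  if (meta$approach == "gcnn") {
    keep <- intersect(names(formals(dmpnn_config)), names(meta$config))
    cfg <- do.call(dmpnn_config, meta$config[keep])
    raw <- readRDS(file.path(dir, "members.rds"))
    members <- lapply(raw, function(m) {
      m$config <- cfg
      structure(m, class = "dmpnn_member")
    })
    ensemble <- structure(list(
      members = members, config = cfg,
      training_dataset_digest = meta$digest,
      label_prevalence = meta$label_prevalence,
      n_training = meta$n_training,
      training_smiles = meta$training_smiles
    ), class = "dmpnn_ensemble")
  }
  structure(list(
    target_name = meta$target_name, gene_symbol = meta$gene_symbol,
    mode = meta$mode, approach = meta$approach, ensemble = ensemble,
    reference = if (!is.null(meta$reference)) as_tibble(meta$reference) else NULL,
    call_threshold = meta$call_threshold, radius = meta$radius,
    width = meta$width, domain_smiles = meta$domain_smiles,
    ad = meta$ad
  ), class = "transporter_model")
}

#' Load a model registry from a configuration file
#'
#' The configuration is a JSON array of registry entries with fields
#' `target_name`, `gene_symbol`, `mode`, `approach` and optionally
#' `model_path` (a directory written by [save_transporter_model()]; entries
#' without one describe the intended approach but cannot score until a model
#' artifact is attached). The packaged default configuration mirrors the
#' published 12-transporter assignment: 24 entries, 9 gcnn (6 inhibitor + 3
#' substrate modes) and 15 similarity.
#'
#' @param config_path Path to the JSON configuration; defaults to the
#'   packaged registry.
#' @return A `transporter_registry` object: `spec` tibble plus a named list
#'   `models` for entries with artifacts.
#' @export
load_registry <- function(config_path = system.file("extdata",
                                                    "default_registry.json",
                                                    package = "txscreen")) {
  spec <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  if (length(spec) == 0L) {
    warn("empty registry configuration")
    spec <- tibble(target_name = character(), gene_symbol = character(),
                   mode = character(), approach = character(),
                   model_path = character())
  }
  spec <- as_tibble(spec)
  if (!"model_path" %in% names(spec)) spec$model_path <- NA_character_
  stopifnot(all(c("target_name", "mode", "approach") %in% names(spec)),
            all(spec$approach %in% c("gcnn", "similarity")),
            all(spec$mode %in% c("inhibitor", "substrate")))
  key <- paste(spec$target_name, spec$mode, sep = "|")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (target, mode) in registry: %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  models <- list()
  base <- dirname(config_path)
  for (i in seq_len(nrow(spec))) {
    mp <- spec$model_path[i]
    if (is.null(mp) || is.na(mp) || !nzchar(mp)) next
    full <- if (file.exists(mp)) mp else file.path(base, mp)
    if (!file.exists(full)) {
      abort(sprintf("model artifact not found for %s: %s", key[i], mp))
    }
    m <- load_transporter_model(full)
    if (m$approach != spec$approach[i]) {
      abort(sprintf("approach mismatch for %s: registry says %s, artifact is %s",
                    key[i], spec$approach[i], m$approach))
    }
    models[[key[i]]] <- m
  }
  structure(list(spec = spec, models = models), class = "transporter_registry")
}

#' Build a registry directly from fitted models
#'
#' @param models List of `transporter_model` objects.
#' @return A `transporter_registry`.
#' @export
build_registry <- function(models) {
  stopifnot(length(models) > 0,
            all(vapply(models, inherits, logical(1), "transporter_model")))
  key <- vapply(models, function(m) paste(m$target_name, m$mode, sep = "|"),
                character(1))
  if (anyDuplicated(key)) abort("duplicate (target, mode) in registry")
  spec <- tibble(
    target_name = vapply(models, `[[`, character(1), "target_name"),
    gene_symbol = vapply(models, `[[`, character(1), "gene_symbol"),
    mode = vapply(models, `[[`, character(1), "mode"),
    approach = vapply(models, `[[`, character(1), "approach"),
    model_path = NA_character_
  )
  structure(list(spec = spec, models = setNames(models, key)),
            class = "transporter_registry")
}

#' @export
print.transporter_registry <- function(x, ...) {
  cat(sprintf("<transporter_registry: %d entries (%d gcnn, %d similarity), %d with artifacts>\n",
              nrow(x$spec), sum(x$spec$approach == "gcnn"),
              sum(x$spec$approach == "similarity"), length(x$models)))
  invisible(x)
}

#' Batch screening profile
#'
#' Scores every valid query against every model in the registry that has an
#' artifact attached: gcnn models contribute the ensemble probability,
#' similarity models the MAX Tanimoto score; each row also carries the SDC
#' applicability-domain value against that model's training/reference
#' chemistry and the in-domain flag. Invalid queries are retained with a
#' `rejected:<reason>` status so row accounting stays auditable.
#'
#' @param queries Query tibble from [standardize_smiles()] or
#'   [read_smiles_dataset()] (may contain invalid rows).
#' @param registry A `transporter_registry` with at least one scoring model.
#' @param batch_limit Maximum number of queries accepted (default
#'   unlimited; pass 10000 to mirror the hosted web service).
#' @return A `screening_profile` tibble: one row per (query, target, mode)
#'   with `score`, `call` (`"active"`/`"inactive"`), `sdc`, `in_domain` and
#'   `status`.
#' @export
profile_batch <- function(queries, registry, batch_limit = Inf) {
  stopifnot(inherits(registry, "transporter_registry"), is.data.frame(queries))
  if (length(registry$models) == 0L) abort("registry has no scoring models")
  if (nrow(queries) > batch_limit) {
    abort(sprintf("batch limit exceeded: %d queries > limit %d",
                  nrow(queries), batch_limit))
  }
  if (!"valid" %in% names(queries)) {
    queries$valid <- !is.na(queries$canonical_smiles)
  }
  if (!"reject_reason" %in% names(queries)) {
    queries$reject_reason <- ifelse(queries$valid, NA_character_, "invalid")
  }
  ok <- queries[queries$valid, , drop = FALSE]
  bad <- queries[!queries$valid, , drop = FALSE]
  fp_cache <- list()
  rows <- vector("list", length(registry$models))
  for (ki in seq_along(registry$models)) {
    m <- registry$models[[ki]]
    fk <- paste(m$radius, m$width)
    if (nrow(ok) > 0L && is.null(fp_cache[[fk]])) {
      fp_cache[[fk]] <- lapply(parse_molecules(ok$canonical_smiles),
                               morgan_fp_mol, radius = m$radius,
                               width = m$width)
    }
    dom_fps <- lapply(parse_molecules(m$domain_smiles), morgan_fp_mol,
                      radius = m$radius, width = m$width)
    good <- NULL
    if (nrow(ok) > 0L) {
      if (m$approach == "gcnn") {
        score <- predict(m$ensemble, ok)$probability
      } else {
        ref_fp <- m$reference
        ref_fp$fingerprint <- lapply(parse_molecules(ref_fp$canonical_smiles),
                                     morgan_fp_mol, radius = m$radius,
                                     width = m$width)
        qf <- ok[, "record_id", drop = FALSE]
        qf$fingerprint <- fp_cache[[fk]]
        score <- max_similarity(qf, ref_fp)$max_score
      }
      sdc <- vapply(fp_cache[[fk]], sdc_score, numeric(1),
                    training_fps = dom_fps)
      good <- tibble(
        record_id = ok$record_id, target = m$target_name, mode = m$mode,
        approach = m$approach, score = score,
        call = ifelse(score >= m$call_threshold, "active", "inactive"),
        sdc = sdc, threshold = m$call_threshold,
        in_domain = sdc >= m$ad$threshold, status = "ok"
      )
    }
    if (nrow(bad) > 0L) {
      badrows <- tibble(
        record_id = bad$record_id, target = m$target_name, mode = m$mode,
        approach = m$approach, score = NA_real_, call = NA_character_,
        sdc = NA_real_, threshold = m$call_threshold, in_domain = NA,
        status = paste0("rejected:", bad$reject_reason)
      )
      good <- dplyr::bind_rows(good, badrows)
    }
    rows[[ki]] <- good
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$record_id, .data$mode, .data$target)
  class(out) <- c("screening_profile", class(out))
  out
}

#' Write a screening profile to disk
#'
#' Writes four CSV call matrices (inhibitor / substrate crossed with
#' unmasked / applicability-domain masked, where out-of-domain cells show
#' the sentinel `"out_of_domain"`) plus `profile_long.csv` with every
#' column. Output is byte-stable for a fixed profile.
#'
#' @param profile A `screening_profile` from [profile_batch()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_profile <- function(profile, out_dir) {
  stopifnot(is.data.frame(profile))
  if (nrow(profile) == 0L) abort("empty profile")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, "profile_long.csv")
  readr::write_csv(as_tibble(profile), paths, progress = FALSE)
  for (md in c("inhibitor", "substrate")) {
    sub <- profile[profile$mode == md, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (masked in c(FALSE, TRUE)) {
      cell <- sub$call
      cell[is.na(cell)] <- sub$status[is.na(cell)]
      if (masked) cell[!is.na(sub$in_domain) & !sub$in_domain] <- "out_of_domain"
      wide <- tidyr::pivot_wider(
        tibble(record_id = sub$record_id, target = sub$target, value = cell),
        names_from = "target", values_from = "value"
      )
      p <- file.path(out_dir, sprintf("profile_%s_%s.csv", md,
                                      if (masked) "ad_masked" else "unmasked"))
      readr::write_csv(wide, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Re-read a long-format screening profile
#'
#' @param path `profile_long.csv` written by [write_profile()].
#' @return A `screening_profile` tibble.
#' @export
read_profile <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           record_id = "c", target = "c", mode = "c",
                           approach = "c", score = "d", call = "c",
                           sdc = "d", threshold = "d", in_domain = "l",
                           status = "c"))
  class(out) <- c("screening_profile", class(out))
  out
}
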