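#' Standardize SMILES strings
#'
#' Runs the three-step pre-processing pipeline used for every dataset that
#' enters the package: *check* (the SMILES must parse to a valid molecule),
#' *standardize* (rewrite to the canonical form so that identical structures
#' become identical strings), and *salt strip* (keep only the largest organic
#' fragment of a multi-fragment input, dropping counter-ions and solvents).
#' Standardization is idempotent: feeding a `canonical_smiles` back in
#' returns the same `canonical_smiles`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional character vector of record identifiers; defaults to
#'   `"r<row>"`.
#'
#' @return A tibble with one row per input: `record_id`, `input_smiles`,
#'   `canonical_smiles` (`NA` when rejected), `valid`, `actions` (list column
#'   of applied steps among `"checked"`, `"standardized"`, `"salt_stripped"`,
#'   `"rejected"`) and `reject_reason` (`NA` when valid). Reject reasons are
#'   `"empty_input"`, `"parse_error"` and `"no_organic_fragment"`.
#'
#' @examples
#' standardize_smiles(c("CCO", "OCC", "CCO.Cl", "C1CC"))
#' @export
standardize_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles))
  if (is.null(id)) id <- sprintf("r%d", seq_along(smiles))
  id <- as.character(id)
  stopifnot(length(id) == length(smiles))
  n <- length(smiles)
  out <- tibble(
    record_id = id,
    input_smiles = smiles,
    canonical_smiles = NA_character_,
    valid = FALSE,
    actions = rep(list(character()), n),
    reject_reason = NA_character_
  )
  if (n == 0L) return(out)

  trimmed <- trimws(smiles)
  empty <- is.na(trimmed) | trimmed == ""
  out$reject_reason[empty] <- "empty_input"

  todo <- which(!empty)
  if (length(todo)) {
    # step 1: checker -- the whole input must parse
    can_full <- ob_canonical(trimmed[todo])
    bad <- is.na(can_full)
    out$reject_reason[todo[bad]] <- "parse_error"
    ok <- todo[!bad]
    if (length(ok)) {
      # step 2/3: salt strip on the parsed form, then canonicalize the keeper
      frags <- strsplit(can_full[!bad], ".", fixed = TRUE)
      keep <- vapply(frags, pick_organic_fragment, character(1))
      no_org <- is.na(keep)
      out$reject_reason[ok[no_org]] <- "no_organic_fragment"
      ok2 <- ok[!no_org]
      if (length(ok2)) {
        canon <- ob_canonical(keep[!no_org])
        # a fragment of a parseable SMILES is itself parseable
        out$canonical_smiles[ok2] <- canon
        out$valid[ok2] <- !is.na(canon)
        stripped <- lengths(frags)[!no_org] > 1L
        out$actions[ok2] <- lapply(stripped, function(s) {
          if (s) c("checked", "standardized", "salt_stripped")
          else c("checked", "standardized")
        })
        out$reject_reason[ok2[is.na(canon)]] <- "parse_error"
      }
    }
  }
  failed <- !out$valid
  out$actions[failed] <- lapply(out$actions[failed], function(a) c(a, "rejected"))
  out
}

# Batch canonicalization through OpenBabel; returns NA for unparseable input.
# OpenBabel aborts the stream at the first molecule it cannot parse, so
# alignment is recovered from molecule titles and conversion resumes after
# each failure until the whole vector is covered.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character(0))
  out <- rep(NA_character_, n)
  start <- 1L
  while (start <= n) {
    idx <- start:n
    tags <- paste0("m", idx)
    txt <- paste0(paste(smiles[idx], tags), collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(txt, "\n")),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_,
                  character(1))
    val <- vapply(parts, function(p) p[[1]], character(1))
    hit <- !is.na(got) & got %in% tags & nzchar(val)
    pos <- as.integer(sub("^m", "", got[hit]))
    out[pos] <- val[hit]
    miss <- idx[is.na(out[idx])]
    if (!length(miss)) break
    # skip the molecule that aborted the stream and resume after it
    start <- miss[[1]] + 1L
  }
  out
}

# Largest organic fragment (must contain carbon); ties broken by heavy-atom
# count (already the ordering key) then lexicographic SMILES.
pick_organic_fragment <- function(frags) {
  organic <- vapply(frags, is_organic_fragment, logical(1))
  if (!any(organic)) return(NA_character_)
  cand <- frags[organic]
  n_atoms <- vapply(cand, count_heavy_atoms, integer(1))
  cand[order(-n_atoms, cand)][[1]]
}

is_organic_fragment <- function(s) {
  grepl("c", s, fixed = TRUE) || grepl("C(?![a-z])", s, perl = TRUE)
}

# Heavy atoms by SMILES token counting (bracket atoms, two-letter organic
# subset symbols, then single-letter/aromatic symbols).
count_heavy_atoms <- function(s) {
  n_br <- lengths(regmatches(s, gregexpr("\\[[^]]*\\]", s)))
  s2 <- gsub("\\[[^]]*\\]", "", s)
  n_two <- lengths(regmatches(s2, gregexpr("Cl|Br", s2)))
  s3 <- gsub("Cl|Br", "", s2)
  n_one <- lengths(regmatches(s3, gregexpr("[BCNOPSFI]|[bcnops]", s3)))
  # bracket atoms that are explicit hydrogens do not count as heavy
  h_br <- lengths(regmatches(s, gregexpr("\\[[0-9]*H[^a-z]*\\]", s)))
  as.integer(n_br + n_two + n_one - h_br)
}

#' Read a SMILES dataset from CSV
#'
#' Expects a header with a `smiles` column and optionally `activity`
#' (binary 0/1 labels) and `id` columns. Every row is standardized with
#' [standardize_smiles()]; rows that fail standardization are dropped with a
#' message reporting the count. A plain SMILES list file (one SMILES per
#' line, no header) is also accepted for unlabeled input via
#' `format = "list"`.
#'
#' @param path CSV file path.
#' @param mode Dataset endpoint: `"inhibitor"`, `"substrate"` or
#'   `"unlabeled"`.
#' @param format `"csv"` (default) or `"list"` for a headerless one-SMILES-
#'   per-line file.
#' @return A standardized dataset tibble with columns `record_id`,
#'   `input_smiles`, `canonical_smiles`, `label` (`NA` when unlabeled) and
#'   `provenance`; attributes `mode` and `name` record the endpoint and the
#'   file stem.
#' @export
read_smiles_dataset <- function(path, mode = c("unlabeled", "inhibitor", "substrate"),
                                format = c("csv", "list")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (format == "list") {
    sm <- readLines(path, warn = FALSE)
    sm <- trimws(sm)
    sm <- sm[nzchar(sm)]
    raw <- tibble(smiles = sm, activity = NA_real_, id = paste0("q", seq_along(sm)))
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    names(raw) <- tolower(names(raw))
    if (!"smiles" %in% names(raw)) {
      abort(sprintf("column 'smiles' not found in %s", path))
    }
    if (!"activity" %in% names(raw)) raw$activity <- NA_real_
    if (!"id" %in% names(raw)) raw$id <- paste0("r", seq_len(nrow(raw)))
    bad_lab <- which(!(is.na(raw$activity) | raw$activity %in% c(0, 1)))
    if (length(bad_lab)) {
      abort(sprintf("activity values must be 0, 1 or empty; offending row(s): %s",
                    paste(head(bad_lab, 5), collapse = ", ")))
    }
  }
  std <- standardize_smiles(raw$smiles, id = as.character(raw$id))
  n_bad <- sum(!std$valid)
  if (n_bad > 0) {
    message(sprintf("read_smiles_dataset: skipped %d invalid row(s) of %d",
                    n_bad, nrow(std)))
  }
  out <- std[std$valid, c("record_id", "input_smiles", "canonical_smiles")]
  out$label <- as.integer(raw$activity[std$valid])
  out$provenance <- basename(path)
  out <- as_tibble(out)
  attr(out, "mode") <- mode
  attr(out, "name") <- sub("\\.[^.]*$", "", basename(path))
  out
}

#' Write a SMILES dataset to CSV
#'
#' Inverse of [read_smiles_dataset()]: writes `smiles` (the canonical form),
#' `activity` (omitted when the dataset is unlabeled) and `id` columns, so
#' that reading the file back yields an identical dataset.
#'
#' @param data Standardized dataset tibble (see [read_smiles_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_smiles_dataset <- function(data, path) {
  stopifnot(is.data.frame(data), "canonical_smiles" %in% names(data))
  out <- tibble(smiles = data$canonical_smiles)
  labeled <- "label" %in% names(data) && any(!is.na(data$label))
  if (labeled) out$activity <- as.integer(data$label)
  out$id <- if ("record_id" %in% names(data)) data$record_id else paste0("r", seq_len(nrow(data)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Collapse duplicate structures in a standardized dataset
#'
#' Records sharing a `canonical_smiles` and the same label are collapsed to
#' the first occurrence; records sharing a `canonical_smiles` but carrying
#' conflicting labels are removed entirely and reported, since neither label
#' can be trusted. Output order preserves first occurrence.
#'
#' @param data Standardized dataset tibble.
#' @return A list with `dataset` (the deduplicated tibble) and `report`, a
#'   tibble of removed conflicting structures (`canonical_smiles`, `n_records`,
#'   `labels`).
#' @export
dedupe_dataset <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) {
    return(list(dataset = as_tibble(data),
                report = tibble(canonical_smiles = character(),
                                n_records = integer(), labels = character())))
  }
  lab <- if ("label" %in% names(data)) data$label else rep(NA_integer_, nrow(data))
  key <- data$canonical_smiles
  by_key <- split(seq_len(nrow(data)), key)
  conflict_keys <- names(by_key)[vapply(by_key, function(ix) {
    u <- unique(lab[ix])
    length(u[!is.na(u)]) > 1L
  }, logical(1))]
  keep_first <- !duplicated(key) & !(key %in% conflict_keys)
  report <- tibble(
    canonical_smiles = conflict_keys,
    n_records = unname(vapply(by_key[conflict_keys], length, integer(1))),
    labels = unname(vapply(by_key[conflict_keys],
                           function(ix) paste(sort(unique(lab[ix])),
                                              collapse = "/"),
                           character(1)))
  )
  ds <- as_tibble(data[keep_first, , drop = FALSE])
  attributes(ds)[c("mode", "name")] <- attributes(data)[c("mode", "name")]
  list(dataset = ds, report = report)
}
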