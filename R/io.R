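# CSV and config IO.  Categorical level maps are stored in a plain-text YAML
# sidecar (<path>.meta.yaml) so round-trips through CSV are lossless.

#' Read a rectangular dataset for imputation
#'
#' Reads a headed CSV; the tokens `""`, `"NA"` and `"."` are treated as
#' missing.  Character columns become factors.  If a metadata sidecar written
#' by [write_imputation_data()] exists, its recorded level maps are restored.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_imputation_data <- function(path) {
  out <- readr::read_csv(path, na = c("", "NA", "."), show_col_types = FALSE,
                         progress = FALSE)
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    for (v in names(meta$levels %||% list())) {
      if (v %in% names(out)) {
        out[[v]] <- factor(as.character(out[[v]]), levels = meta$levels[[v]])
      }
    }
  } else {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.character), factor))
  }
  out
}

#' Write a dataset and its level-map sidecar
#'
#' @param data A data frame.
#' @param path Output CSV path; factor level maps go to `<path>.meta.yaml`.
#' @return `path`, invisibly.
#' @export
write_imputation_data <- function(data, path) {
  fac <- names(data)[vapply(data, is.factor, logical(1))]
  readr::write_csv(data, path, na = "")
  if (length(fac)) {
    yaml::write_yaml(
      list(levels = stats::setNames(lapply(data[fac], base::levels), fac)),
      paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Write completed datasets and the imputation audit trail
#'
#' Writes `prefix_1.csv ... prefix_m.csv` (one per completed dataset, level
#' labels restored) and `prefix_audit.csv` with one row per fitted
#' imputation model: draw method, separation flag and the likelihood-ratio
#' diagnostic R.  Separation is never silent: a summary line is printed when
#' any fit was separated.
#'
#' @param run An `"imputation_run"`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_imputations <- function(run, prefix) {
  stopifnot(inherits(run, "imputation_run"))
  files <- character(0)
  for (i in seq_len(run$m)) {
    f <- paste0(prefix, "_", i, ".csv")
    write_imputation_data(run$completed[[i]], f)
    files <- c(files, f)
  }
  fa <- paste0(prefix, "_audit.csv")
  readr::write_csv(run$audit, fa, na = "")
  files <- c(files, fa)
  nsep <- sum(run$audit$separated, na.rm = TRUE)
  if (nsep > 0) {
    message(sprintf("Note: perfect prediction occurred in %d of %d imputation-model fits (see %s).",
                    nsep, nrow(run$audit), fa))
  }
  invisible(files)
}

#' Read an imputation configuration from YAML
#'
#' Expected structure: top-level keys `m`, `n_cycles`, `method`, `seed`,
#' optional `variable_order`, and `models`, a list of blocks each with
#' `variable`, `predictors`, `kind` and optional `levels`.  Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return An [imputation_config()].
#' @export
read_imputation_config <- function(path) {
  # keep YAML boolean-lookalike tokens ("y", "n", "yes", ...) as the literal
  # strings: the schema has no boolean fields, but column names often do
  # collide with them
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  allowed <- c("m", "n_cycles", "method", "seed", "variable_order", "models",
               "prior", "maxit")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
                 class = "sepmi_config_error")
  }
  if (is.null(cfg$models)) {
    rlang::abort("Config must declare a 'models' list.", class = "sepmi_config_error")
  }
  specs <- lapply(cfg$models, function(mdl) {
    bad <- setdiff(names(mdl), c("variable", "predictors", "kind", "levels"))
    if (length(bad)) {
      rlang::abort(paste0("Unknown model key(s): ", paste(bad, collapse = ", ")),
                   class = "sepmi_config_error")
    }
    imp_spec(mdl$variable, unlist(mdl$predictors), kind = mdl$kind %||% "binary",
             levels = mdl$levels)
  })
  imputation_config(specs,
                    m = cfg$m %||% 5L, n_cycles = cfg$n_cycles %||% 1L,
                    method = cfg$method %||% "normal_augment",
                    seed = cfg$seed %||% 1L,
                    variable_order = unlist(cfg$variable_order),
                    prior = unlist(cfg$prior) %||% c(1, 1),
                    maxit = cfg$maxit %||% 25L)
}
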