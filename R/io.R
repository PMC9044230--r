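#' Write a simulated dataset as CSV with a provenance sidecar
#'
#' The dataset is written as a headered CSV (`item01..item15`, one row per
#' respondent). A JSON sidecar at `<path>.json` records the structure label,
#' scenario, seed, dimensions and the Fleishman coefficients used, so the file
#' can be regenerated bit-for-bit.
#'
#' @param data matrix from [simulate.nonnormal_population()] or
#'   [generate_dataset()].
#' @param path output CSV path.
#' @param population optional [nonnormal_population()] used to generate the
#'   data; adds solver coefficients to the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, population = NULL) {
  df <- as.data.frame(as.matrix(data))
  if (is.null(colnames(data))) {
    names(df) <- sprintf("item%02d", seq_len(ncol(df)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    structure = attr(data, "structure_label"),
    scenario = attr(data, "scenario_id"),
    seed = attr(data, "seed"),
    n = nrow(df), k = ncol(df)
  )
  if (!is.null(population)) {
    cf <- population$intermediate$coefficients[[1]]
    meta$fleishman <- list(a = cf$a, b = cf$b, c = cf$c, d = cf$d)
    meta$intermediate_repaired <- population$intermediate$repaired
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset CSV written by [write_dataset()]
#'
#' @param path CSV path.
#' @return Numeric matrix. Non-numeric cells raise an error naming the first
#'   offending row and column.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop(sprintf("empty dataset: %s", path))
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(df)[j], if (is.na(bad)) 1L else bad, path))
    }
  }
  as.matrix(df)
}

#' Serialize a fitted reducer to JSON
#'
#' Writes variant, latent dimension, layer shapes, flattened weights and
#' biases (or the PCA center/rotation), and optionally the standardizer used
#' for preprocessing, to a self-contained JSON file readable by
#' [read_reducer_json()].
#'
#' @param model a fitted [reducer()].
#' @param path output path.
#' @param scaler optional [standardize_fit()] result to store alongside.
#' @return `path`, invisibly.
#' @export
write_reducer_json <- function(model, path, scaler = NULL) {
  stopifnot(inherits(model, "reducer"))
  obj <- list(variant = model$variant, k = model$k, m = model$m, n = model$n,
              seed = model$seed)
  if (model$variant == "pca") {
    obj$center <- model$fit$center
    obj$rotation <- list(dim = dim(model$fit$rotation),
                         values = as.numeric(model$fit$rotation))
    obj$eigenvalues <- model$fit$eigenvalues
  } else {
    obj$dims <- model$fit$dims
    obj$acts <- model$fit$acts
    obj$tied <- model$fit$tied
    obj$bottleneck <- model$fit$bottleneck
    obj$weights <- lapply(model$fit$weights, function(w)
      list(dim = dim(w), values = as.numeric(w)))
    obj$biases <- model$fit$biases
  }
  if (!is.null(scaler)) obj$scaler <- list(mean = scaler$mean, sd = scaler$sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reducer_json
#' @export
read_reducer_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  unflatten <- function(x) matrix(num(x$values), x$dim[[1]], x$dim[[2]])
  fit <- if (obj$variant == "pca") {
    list(center = num(obj$center), rotation = unflatten(obj$rotation),
         eigenvalues = num(obj$eigenvalues))
  } else {
    list(dims = as.integer(unlist(obj$dims)),
         acts = as.character(unlist(obj$acts)),
         tied = isTRUE(obj$tied),
         bottleneck = as.integer(obj$bottleneck),
         weights = lapply(obj$weights, unflatten),
         biases = lapply(obj$biases, num))
  }
  model <- structure(list(variant = obj$variant, k = obj$k, m = obj$m,
                          n = obj$n, fit = fit, x = NULL, seed = obj$seed,
                          call = NULL),
                     class = "reducer")
  if (!is.null(obj$scaler)) {
    attr(model, "scaler") <- structure(list(mean = num(obj$scaler$mean),
                                            sd = num(obj$scaler$sd)),
                                       class = "standardizer")
  }
  model
}

#' Write a construct assignment as CSV
#'
#' @param assignment result of [assign_items()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE)
  invisible(path)
}

#' Write grid results, summaries and run metadata to a directory
#'
#' Writes `results.csv` (one row per condition-replicate-algorithm),
#' `summary_communality.csv`, `summary_normality.csv`,
#' `summary_sample_size.csv`, and `run_metadata.json` (the resolved grid
#' specification).
#'
#' @param results a [run_grid()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_grid_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(results), file.path(dir, "results.csv"),
                   row.names = FALSE)
  for (by in c("communality", "normality", "sample_size")) {
    utils::write.csv(summarize_results(results, by),
                     file.path(dir, sprintf("summary_%s.csv", by)),
                     row.names = FALSE)
  }
  spec <- attr(results, "spec")
  if (!is.null(spec)) {
    meta <- unclass(spec)
    meta$control <- unclass(meta$control)
    jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
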