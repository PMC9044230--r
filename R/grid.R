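#' The study's sample-size ladder
#'
#' Sample sizes rise by 10 below 200 and by 50 from 200 up to the study's
#' ceiling of 1,000: 100, 110, ..., 190, 200, 250, ..., 1000 (27 values).
#'
#' @return Integer vector of length 27.
#' @export
sample_size_ladder <- function() {
  as.integer(c(seq(100, 190, by = 10), seq(200, 1000, by = 50)))
}

#' Specify a Monte Carlo experiment grid
#'
#' The full study design crosses the three communality structures, the three
#' non-normality scenarios and the 27-value sample-size ladder (243
#' conditions), runs 10 replicates of each, and fits all five reducers per
#' replicate on an 80/20 train/test split.
#'
#' @param structures subset of `c("high", "wide", "low")`.
#' @param scenarios subset of `c("s1", "s2", "s3")`.
#' @param sample_sizes strictly increasing integer vector.
#' @param replicates replicates per condition.
#' @param train_fraction fraction of rows used for training, in (0, 1).
#' @param master_seed integer seed from which every condition-replicate seed is
#'   derived.
#' @param variants reducers to fit.
#' @param k latent dimension.
#' @param control a [reducer_control()] shared by the autoencoder variants.
#' @param literal_ned compute the literal (unsquared-sum) NED instead of the
#'   default sign-distance form; see [ned()].
#'
#' @return A list of class `"grid_spec"`.
#' @export
grid_spec <- function(structures = c("high", "wide", "low"),
                      scenarios = c("s1", "s2", "s3"),
                      sample_sizes = sample_size_ladder(),
                      replicates = 10,
                      train_fraction = 0.8,
                      master_seed = 1,
                      variants = c("pca", "simple_ae", "tied_ae", "deep_ae",
                                   "independent_ae"),
                      k = 3,
                      control = reducer_control(),
                      literal_ned = FALSE) {
  structures <- match.arg(structures, c("high", "wide", "low"), several.ok = TRUE)
  scenarios <- match.arg(scenarios, c("s1", "s2", "s3"), several.ok = TRUE)
  variants <- match.arg(variants,
                        c("pca", "simple_ae", "tied_ae", "deep_ae",
                          "independent_ae"), several.ok = TRUE)
  if (length(sample_sizes) == 0) stop("'sample_sizes' must be non-empty")
  if (any(diff(sample_sizes) <= 0)) stop("'sample_sizes' must be strictly increasing")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie strictly between 0 and 1")
  }
  stopifnot(replicates >= 1, inherits(control, "reducer_control"))
  structure(list(structures = structures, scenarios = scenarios,
                 sample_sizes = as.integer(sample_sizes),
                 replicates = as.integer(replicates),
                 train_fraction = train_fraction,
                 master_seed = as.integer(master_seed),
                 variants = variants, k = as.integer(k), control = control,
                 literal_ned = isTRUE(literal_ned)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid spec: %d structures x %d scenarios x %d sample sizes = %d conditions, %d replicate(s)\n",
              length(x$structures), length(x$scenarios), length(x$sample_sizes),
              length(x$structures) * length(x$scenarios) * length(x$sample_sizes),
              x$replicates))
  cat(sprintf("  reducers: %s (k = %d); train fraction %.2f; master seed %d\n",
              paste(x$variants, collapse = ", "), x$k, x$train_fraction,
              x$master_seed))
  invisible(x)
}

#' Enumerate the conditions of a grid
#'
#' @param spec a [grid_spec()].
#' @return Data frame with columns `structure`, `scenario`, `n`; the full study
#'   spec yields 243 rows.
#' @export
enumerate_conditions <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(spec$structures) == 0 || length(spec$scenarios) == 0 ||
      length(spec$sample_sizes) == 0) {
    stop("every design factor must have at least one level")
  }
  expand.grid(n = spec$sample_sizes, scenario = spec$scenarios,
              structure = spec$structures, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)[, c("structure", "scenario", "n")]
}

# Deterministic per-(condition, replicate) seed below 2^31, derived from the
# master seed. Arithmetic kept in doubles (exact below 2^53).
condition_seed <- function(master_seed, structure, scenario, n, replicate) {
  si <- match(structure, c("high", "wide", "low"))
  sc <- match(scenario, c("s1", "s2", "s3"))
  if (is.na(si)) si <- 4
  if (is.na(sc)) sc <- 4
  h <- (master_seed %% 2147483647) * 31 + si
  h <- (h * 131071 + sc * 524287) %% 2147483629
  h <- (h * 8191 + n * 104729) %% 2147483629
  h <- (h * 127 + replicate * 130363) %% 2147483629
  as.integer(h + 1)
}

#' Run one condition of the experiment grid
#'
#' Per replicate: draws `n` observations from the condition's population with
#' a seed derived from the master seed, splits them into train/test by a
#' random permutation, z-scores both partitions with training statistics, fits
#' every requested reducer on the training partition, and computes the three
#' reconstruction metrics on the test partition. A failed fit is recorded with
#' `failed = TRUE` rather than aborting.
#'
#' @param structure,scenario,n the condition.
#' @param spec a [grid_spec()] supplying replicates, split, reducers and seeds.
#' @param population optional pre-built [nonnormal_population()] for the
#'   condition (built on the fly if omitted).
#'
#' @return Data frame with one row per (replicate, algorithm): the condition
#'   columns, `replicate`, `algorithm`, `mse`, `mae`, `ned`, `seed`, `failed`.
#' @export
run_condition <- function(structure, scenario, n, spec, population = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(population)) population <- nonnormal_population(structure, scenario)
  rows <- vector("list", spec$replicates * length(spec$variants))
  r <- 0L
  for (rep_i in seq_len(spec$replicates)) {
    seed <- condition_seed(spec$master_seed, structure, scenario, n, rep_i)
    x <- simulate(population, nsim = 1, seed = seed, n = n)
    n_test <- round((1 - spec$train_fraction) * n)
    perm <- sample.int(n)
    test_idx <- perm[seq_len(n_test)]
    train <- x[-test_idx, , drop = FALSE]
    test <- x[test_idx, , drop = FALSE]
    scaler <- standardize_fit(train)
    train_z <- standardize_apply(scaler, train)
    test_z <- standardize_apply(scaler, test)
    for (v in spec$variants) {
      r <- r + 1L
      met <- tryCatch({
        fit <- reducer(train_z, v, k = spec$k, control = spec$control,
                       seed = seed)
        reconstruction_metrics(test_z, reconstruct(fit, test_z),
                               literal = isTRUE(spec$literal_ned))
      }, error = function(e) NULL)
      rows[[r]] <- data.frame(
        structure = structure, scenario = scenario, n = n,
        replicate = rep_i, algorithm = v,
        mse = if (is.null(met)) NA_real_ else met$mse,
        mae = if (is.null(met)) NA_real_ else met$mae,
        ned = if (is.null(met)) NA_real_ else met$ned,
        seed = seed, failed = is.null(met))
    }
  }
  do.call(rbind, rows)
}

#' Run the full experiment grid
#'
#' Enumerates the conditions of `spec` and runs each through
#' [run_condition()], caching one population per (structure, scenario) pair so
#' the moment solvers run only once per pair.
#'
#' @param spec a [grid_spec()].
#' @param verbose print per-condition progress.
#' @return Data frame of class `"grid_results"` (one row per
#'   condition-replicate-algorithm) with the spec attached as attribute
#'   `"spec"`.
#' @export
run_grid <- function(spec, verbose = FALSE) {
  conditions <- enumerate_conditions(spec)
  populations <- list()
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    key <- paste(cond$structure, cond$scenario)
    if (is.null(populations[[key]])) {
      populations[[key]] <- nonnormal_population(cond$structure, cond$scenario)
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s %s n=%d", i, nrow(conditions),
                      cond$structure, cond$scenario, cond$n))
    }
    out[[i]] <- run_condition(cond$structure, cond$scenario, cond$n, spec,
                              populations[[key]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "spec") <- spec
  class(res) <- c("grid_results", "data.frame")
  res
}

#' Aggregate grid results by a design factor
#'
#' Mirrors the study's summary layout: the mean and standard deviation of each
#' metric per algorithm within each level of one design factor, pooling all
#' other factors and replicates. Failed fits are dropped with a message.
#'
#' @param results a data frame from [run_grid()] or [run_condition()].
#' @param by grouping factor: `"communality"` (structure), `"normality"`
#'   (scenario), or `"sample_size"`.
#' @return Data frame with columns `level`, `algorithm`, and
#'   `<metric>_mean`/`<metric>_sd` for the three metrics.
#' @export
summarize_results <- function(results, by = c("communality", "normality",
                                              "sample_size")) {
  by <- match.arg(by)
  col <- switch(by, communality = "structure", normality = "scenario",
                sample_size = "n")
  if (!all(c(col, "algorithm", "mse", "mae", "ned") %in% names(results))) {
    stop("'results' does not look like grid results")
  }
  if (nrow(results) == 0) stop("'results' is empty")
  failed <- results$failed
  if (!is.null(failed) && any(failed)) {
    message(sprintf("dropping %d failed fit(s) from the summary", sum(failed)))
    results <- results[!failed, , drop = FALSE]
  }
  groups <- list(level = results[[col]], algorithm = results$algorithm)
  agg <- function(fun, suffix) {
    a <- stats::aggregate(results[, c("mse", "mae", "ned")], groups, fun)
    names(a)[3:5] <- paste0(c("mse", "mae", "ned"), suffix)
    a
  }
  out <- merge(agg(mean, "_mean"), agg(stats::sd, "_sd"),
               by = c("level", "algorithm"), sort = TRUE)
  out[order(out$level, out$algorithm), , drop = FALSE]
}
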