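#' Pipeline configuration
#'
#' Collects the tunable parameters of the reconstruction pipeline with the
#' defaults used throughout the package: significance level 0.005, 100
#' permutation rounds, UCV bandwidth selection over all (or at most 100
#' sampled) pairs, listwise deletion and a 3:1 train/test ratio. All
#' randomness derives from the single `seed`, split deterministically per
#' stage.
#'
#' @param p_value tail probability for the MI threshold.
#' @param n_permutations permutation rounds for the null.
#' @param n_pairs pairs for bandwidth cross-validation (`NULL` = automatic,
#'   see [select_bandwidth()]).
#' @param h_override fixed bandwidth bypassing UCV selection (`NULL` = select
#'   by UCV).
#' @param deletion missing-data policy, `"listwise"` or `"pairwise"`.
#' @param mode `"bipartite"` or `"full"`.
#' @param test_fraction test fraction for predictive models.
#' @param seed master integer seed.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(p_value = 0.005, n_permutations = 100L,
                            n_pairs = NULL, h_override = NULL,
                            deletion = c("listwise", "pairwise"),
                            mode = c("bipartite", "full"),
                            test_fraction = 0.25, seed = 1L) {
  deletion <- match.arg(deletion); mode <- match.arg(mode)
  stopifnot(p_value > 0, p_value < 1, n_permutations >= 1,
            test_fraction > 0, test_fraction < 1)
  if (!is.null(h_override)) check_positive_scalar(h_override, "h_override")
  structure(list(p_value = p_value,
                 n_permutations = as.integer(n_permutations),
                 n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
                 h_override = h_override, deletion = deletion, mode = mode,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` invisibly (writer); a `pipeline_config` (reader).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full network-reconstruction pipeline
#'
#' Executes the whole method on one dataset: listwise deletion and
#' per-column standardization, UCV bandwidth selection, mutual information
#' matrix, permutation null and large-deviation threshold, network
#' reconstruction, and (optionally) one linear predictive model per output
#' using its significant inputs. When `out_dir` is given, writes
#' `mim.tsv`, `null_fit.json`, `network_edges.tsv`, `network.graphml`,
#' `model_metrics.json` and a `manifest.json` holding every seed and fitted
#' quantity needed to re-execute the run; re-running with the same seed
#' produces byte-identical artifacts.
#'
#' @param data a [sample_matrix()], or a file path passed to
#'   [read_sample_matrix()] (then `output_path`/`roles` apply).
#' @param config a [pipeline_config()].
#' @param out_dir directory for artifacts (`NULL` = return results only).
#' @param fit_models fit per-output linear models (default `TRUE` in
#'   bipartite mode).
#' @param output_path,roles passed to [read_sample_matrix()] when `data` is
#'   a path.
#' @return List with `bandwidth`, `mim`, `null_fit`, `threshold`, `network`,
#'   `models` (per-output metric lists, or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL,
                         fit_models = config$mode == "bipartite",
                         output_path = NULL, roles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(data))
    data <- read_sample_matrix(data, output_path = output_path, roles = roles)
  stopifnot(inherits(data, "sample_matrix"))
  seed <- config$seed

  bw <- if (is.null(config$h_override)) {
    select_bandwidth(data, n_pairs = config$n_pairs,
                     seed = stage_seed(seed, "bandwidth"),
                     mode = config$mode)
  } else {
    structure(list(h = config$h_override, method = "fixed",
                   per_pair_h = numeric(), ucv_scores = numeric(),
                   n_observations = NA_integer_, mode = config$mode,
                   seed = NA_integer_),
              class = "bandwidth")
  }
  mim <- compute_mim(data, config$mode, bw$h, deletion = config$deletion)
  null_mi <- permutation_null(data, config$mode, bw$h,
                              n_permutations = config$n_permutations,
                              seed = stage_seed(seed, "null"))
  fit <- fit_large_deviation(null_mi)
  threshold <- threshold_for_pvalue(fit, config$p_value)
  net <- reconstruct(mim, threshold, roles = data$roles)
  net$metadata$p_value <- config$p_value

  models <- NULL
  if (isTRUE(fit_models)) {
    models <- list()
    for (out in output_names(data)) {
      res <- tryCatch(
        evaluate_output_model(data, net, out,
                              test_fraction = config$test_fraction,
                              seed = stage_seed(seed, "split")),
        error = function(e) list(error = conditionMessage(e)))
      if (is.null(res$error)) res$model <- NULL  # metrics only in manifest
      models[[out]] <- res
    }
  }

  manifest <- list(
    package = "kdenet",
    version = as.character(utils::packageVersion("kdenet")),
    dataset_label = data$dataset_label,
    config = unclass(config),
    seeds = list(master = seed,
                 bandwidth = stage_seed(seed, "bandwidth"),
                 null = stage_seed(seed, "null"),
                 split = stage_seed(seed, "split")),
    h = bw$h, bandwidth_method = bw$method,
    n_observations = mim$n_observations,
    null_fit = list(a = fit$a, b = fit$b, fit_r2 = fit$fit_r2,
                    fit_range = fit$fit_range, n_null = fit$n_null),
    threshold = threshold,
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    models = models)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mim(mim, file.path(out_dir, "mim.tsv"))
    jsonlite::write_json(manifest$null_fit,
                         file.path(out_dir, "null_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
    write_graphml(net, file.path(out_dir, "network.graphml"))
    if (!is.null(models))
      jsonlite::write_json(models, file.path(out_dir, "model_metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(bandwidth = bw, mim = mim, null_fit = fit, threshold = threshold,
       network = net, models = models, manifest = manifest)
}
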