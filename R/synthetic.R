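#' Draw a bivariate Gaussian pair with known mutual information
#'
#' Samples `n` observations from a bivariate normal with unit variances and
#' correlation `rho`, for which the mutual information has the closed form
#' \eqn{I = -\tfrac{1}{2}\ln(1 - \rho^2)} nats — the standard oracle for
#' benchmarking continuous MI estimators.
#'
#' @param rho correlation, `|rho| < 1`.
#' @param n number of observations.
#' @param seed integer seed.
#' @return A data.frame with columns `x` and `y` and attribute `true_mi`.
#' @examples
#' gp <- gaussian_pair(0.8, 100, seed = 1)
#' attr(gp, "true_mi")  # 0.5108256
#' @export
gaussian_pair <- function(rho, n, seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("'rho' must be a single number with |rho| < 1")
  if (!is.numeric(n) || n < 1) stop("'n' must be a positive integer")
  d <- with_seed(seed, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(x = x, y = y)
  })
  attr(d, "true_mi") <- -0.5 * log(1 - rho^2)
  d
}

planted_links <- list(
  linear = function(z) z,
  quadratic = function(z) z^2 - 1,     # mean-zero, uncorrelated with z
  saturating = function(z) tanh(2 * z)
)

#' Specify a planted input-output network
#'
#' Describes a synthetic dataset with the shape and statistical structure of
#' a phosphoprotein-cytokine screen: continuous Gaussian inputs (optionally
#' with exchangeable correlation), outputs driven by a sparse set of planted
#' links that may be linear, quadratic (zero Pearson correlation) or
#' saturating, additive Gaussian noise, and an optional fraction of rows
#' carrying missing values. The defaults mirror a 22-input / 7-output design.
#'
#' @param n_inputs,n_outputs,n_observations dimensions of the dataset.
#' @param edges data.frame with columns `input`, `output` (1-based indices or
#'   variable names `in01`.../`out1`...), `link` (one of `"linear"`,
#'   `"quadratic"`, `"saturating"`) and `effect_size`. `NULL` means no
#'   planted edges (pure-noise outputs).
#' @param noise_sd standard deviation of the additive output noise, relative
#'   to the unit-variance signal scale.
#' @param input_correlation exchangeable correlation among inputs, in
#'   \[0, 1).
#' @param missing_row_fraction fraction of rows in which one randomly chosen
#'   variable is masked missing, in \[0, 1).
#' @param seed integer seed.
#' @return An object of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_inputs = 22L, n_outputs = 7L,
                                 n_observations = 78L, edges = NULL,
                                 noise_sd = 0.3, input_correlation = 0,
                                 missing_row_fraction = 0, seed = 1L) {
  stopifnot(n_inputs >= 1, n_outputs >= 1, n_observations >= 2,
            noise_sd > 0, input_correlation >= 0, input_correlation < 1,
            missing_row_fraction >= 0, missing_row_fraction < 1)
  in_names <- sprintf("in%02d", seq_len(n_inputs))
  out_names <- sprintf("out%d", seq_len(n_outputs))
  if (!is.null(edges)) {
    stopifnot(is.data.frame(edges),
              all(c("input", "output", "link", "effect_size") %in%
                    names(edges)))
    if (is.numeric(edges$input)) edges$input <- in_names[edges$input]
    if (is.numeric(edges$output)) edges$output <- out_names[edges$output]
    if (!all(edges$input %in% in_names) || !all(edges$output %in% out_names))
      stop("edges reference unknown variables")
    if (!all(edges$link %in% names(planted_links)))
      stop("link must be one of: ", paste(names(planted_links), collapse = ", "))
    if (anyDuplicated(edges[c("input", "output")]))
      stop("duplicate planted edges")
  } else {
    edges <- data.frame(input = character(), output = character(),
                        link = character(), effect_size = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 n_observations = as.integer(n_observations),
                 input_names = in_names, output_names = out_names,
                 edges = edges, noise_sd = noise_sd,
                 input_correlation = input_correlation,
                 missing_row_fraction = missing_row_fraction,
                 seed = as.integer(seed)),
            class = "planted_network_spec")
}

#' Draw a random planted edge set
#'
#' Convenience sampler for benchmark specs: `n_edges` distinct input-output
#' pairs with link types drawn from `links` and the given effect size.
#'
#' @param n_inputs,n_outputs dimensions of the network.
#' @param n_edges number of distinct planted edges.
#' @param links character vector of link types to cycle through (recycled
#'   over the sampled edges).
#' @param effect_size common effect size.
#' @param seed integer seed.
#' @return An edge data.frame for [planted_network_spec()].
#' @export
sample_planted_edges <- function(n_inputs, n_outputs, n_edges,
                                 links = c("linear", "quadratic"),
                                 effect_size = 1, seed = 1L) {
  total <- n_inputs * n_outputs
  if (n_edges > total) stop("more edges requested than input-output pairs")
  idx <- with_seed(seed, sample.int(total, n_edges))
  data.frame(input = ((idx - 1L) %% n_inputs) + 1L,
             output = ((idx - 1L) %/% n_inputs) + 1L,
             link = rep_len(links, n_edges),
             effect_size = effect_size, stringsAsFactors = FALSE)
}

#' Generate data from a planted network specification
#'
#' Inputs are drawn from a correlated Gaussian (exchangeable correlation);
#' each output is the sum of its planted links applied to the corresponding
#' standardized inputs plus Gaussian noise, then standardized so that
#' `noise_sd` is interpretable relative to unit output scale. A seeded
#' fraction of rows is masked missing in one randomly chosen variable each.
#'
#' @param spec a [planted_network_spec()].
#' @return List with `data` (a [sample_matrix()]), `adjacency` (logical
#'   inputs-by-outputs truth matrix) and `spec`.
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  n <- spec$n_observations; p <- spec$n_inputs; q <- spec$n_outputs
  r <- spec$input_correlation
  with_seed(spec$seed, {
    common <- stats::rnorm(n)
    X <- sqrt(r) * common + sqrt(1 - r) * matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- spec$input_names
    Y <- matrix(stats::rnorm(n * q, sd = spec$noise_sd), n, q)
    colnames(Y) <- spec$output_names
    adj <- matrix(FALSE, p, q,
                  dimnames = list(spec$input_names, spec$output_names))
    if (nrow(spec$edges)) for (k in seq_len(nrow(spec$edges))) {
      e <- spec$edges[k, ]
      z <- drop(scale(X[, e$input]))
      Y[, e$output] <- Y[, e$output] +
        e$effect_size * planted_links[[e$link]](z)
      adj[e$input, e$output] <- TRUE
    }
    Y <- scale(Y)
    attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
    v <- cbind(X, Y)
    if (spec$missing_row_fraction > 0) {
      n_miss <- floor(spec$missing_row_fraction * n)
      rows <- sample.int(n, n_miss)
      cols <- sample.int(p + q, n_miss, replace = TRUE)
      v[cbind(rows, cols)] <- NA_real_
    }
    data <- sample_matrix(v, c(rep("input", p), rep("output", q)))
    list(data = data, adjacency = adj, spec = spec)
  })
}

#' Precision and recall of a recovered edge set
#'
#' Compares the input-output edges of an inferred network against the
#' planted truth: precision is the fraction of inferred edges that are true,
#' recall the fraction of true edges recovered. When a denominator is zero
#' the corresponding value is `NA` (flagged rather than forced to 0 or 1).
#'
#' @param truth logical inputs-by-outputs adjacency matrix with dimnames, as
#'   returned by [generate_planted()].
#' @param net an `mi_network` whose variable names match the truth matrix.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
evaluate_recovery <- function(truth, net) {
  stopifnot(is.matrix(truth), is.logical(truth), inherits(net, "mi_network"))
  e <- net$edges[net$edges$edge_type == "input-output", , drop = FALSE]
  src <- ifelse(e$source %in% rownames(truth), e$source, e$target)
  dst <- ifelse(e$source %in% rownames(truth), e$target, e$source)
  if (length(src) && (!all(src %in% rownames(truth)) ||
                      !all(dst %in% colnames(truth))))
    stop("network variables do not match the truth matrix")
  n_inferred <- nrow(e)
  n_true <- sum(truth)
  tp <- if (n_inferred) sum(truth[cbind(src, dst)]) else 0L
  c(precision = if (n_inferred) tp / n_inferred else NA_real_,
    recall = if (n_true) tp / n_true else NA_real_)
}
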