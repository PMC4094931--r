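#' Shannon entropy of a discrete distribution
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats, with the convention
#' \eqn{0 \ln 0 = 0}. The mutual information of two variables equals
#' \eqn{H(X) + H(Y) - H(X, Y)}; kdenet estimates it for continuous data via
#' kernel densities ([mutual_information()]) rather than through discrete
#' entropies, but the entropy itself is exposed for diagnostics.
#'
#' @param p numeric vector of probabilities summing to 1 (tolerance 1e-8).
#' @return Entropy in nats, a non-negative number.
#' @examples
#' entropy(c(0.5, 0.5))  # ln 2
#' @export
entropy <- function(p) {
  if (!is.numeric(p) || !length(p) || anyNA(p) || any(p < 0))
    stop("'p' must be non-negative probabilities")
  if (abs(sum(p) - 1) > 1e-8)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

# Gaussian kernel Gram matrix exp(-(xi-xj)^2 / (2h^2)); the workhorse shared
# by the MI estimator and the permutation null (which only needs reindexing).
kernel_gram <- function(x, h) exp(-sqdist(x) / (2 * h^2))

# mean log marginal density at the sample points, from a Gram matrix
mean_log_marginal <- function(K, h) {
  n <- nrow(K)
  mean(log(rowSums(K) / (sqrt(2 * pi) * n * h)))
}

mi_from_grams <- function(Kx, Ky, h) {
  n <- nrow(Kx)
  fj <- rowSums(Kx * Ky) / (2 * pi * n * h^2)
  mean(log(fj)) - mean_log_marginal(Kx, h) - mean_log_marginal(Ky, h)
}

#' Kernel-density mutual information of two continuous variables
#'
#' Resubstitution estimator of the mutual information in nats:
#' \deqn{\hat I(X, Y) = \frac{1}{n} \sum_{j=1}^{n}
#'       \ln \frac{\hat f(x_j, y_j)}{\hat f(x_j)\,\hat f(y_j)},}
#' with the joint density from [kde_bivariate()] and the marginals from
#' [kde_univariate()], all with the same bandwidth `h`, evaluated at the
#' sample points themselves. The estimate can be slightly negative by
#' estimation noise; it is returned raw (clamping at zero happens only where
#' estimates are compared against a significance threshold).
#'
#' @param x,y equal-length numeric vectors of paired observations
#'   (standardize upstream so that one `h` fits both coordinates).
#' @param h kernel bandwidth, a single positive number.
#' @return The mutual information estimate in nats.
#' @examples
#' gp <- gaussian_pair(rho = 0.8, n = 400, seed = 1)
#' mutual_information(scale(gp$x)[, 1], scale(gp$y)[, 1], h = 0.25)
#' @export
mutual_information <- function(x, y, h) {
  check_positive_scalar(h, "h")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop("sample must be finite")
  mi_from_grams(kernel_gram(x, h), kernel_gram(y, h), h)
}

#' Mutual information matrix (MIM) of a dataset
#'
#' Computes the pairwise kernel-density mutual information for every
#' input-output pair (`mode = "bipartite"`, a rectangular matrix such as the
#' 22 phosphoproteins by 7 cytokines of a signaling screen) or for every
#' variable pair (`mode = "full"`, a symmetric square matrix whose diagonal
#' is set to `NA` — self-information is not an edge). Rows with missing
#' values are removed listwise across all analysed variables by default;
#' `deletion = "pairwise"` instead keeps, for each pair, all rows complete in
#' that pair (standardizing per pair), which retains more data at the cost of
#' entries estimated on different row sets.
#'
#' @param data a [sample_matrix()].
#' @param mode `"bipartite"` or `"full"`.
#' @param h kernel bandwidth: a positive number or a `bandwidth` object from
#'   [select_bandwidth()].
#' @param deletion missing-data policy, `"listwise"` (default) or
#'   `"pairwise"`.
#' @param standardize standardize columns to zero mean / unit sd before
#'   estimation (default `TRUE`; set `FALSE` only if the data are already
#'   standardized).
#' @return An object of class `mi_matrix`: list with `values` (named numeric
#'   matrix, nats), `mode`, `h`, `n_observations`, `deletion` and
#'   `dataset_label`. Pairs with fewer than 2 complete observations get `NA`
#'   with a warning.
#' @export
compute_mim <- function(data, mode = c("bipartite", "full"), h,
                        deletion = c("listwise", "pairwise"),
                        standardize = TRUE) {
  mode <- match.arg(mode); deletion <- match.arg(deletion)
  stopifnot(inherits(data, "sample_matrix"))
  if (inherits(h, "bandwidth")) h <- h$h
  check_positive_scalar(h, "h")
  ins <- input_names(data); outs <- output_names(data)
  if (mode == "bipartite" && (!length(ins) || !length(outs)))
    stop("bipartite mode needs both input and output variables")
  rn <- if (mode == "bipartite") ins else names(data$roles)
  cn <- if (mode == "bipartite") outs else names(data$roles)
  vals <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))

  if (deletion == "listwise") {
    sm <- complete_rows(data)
    if (standardize) sm <- standardize_columns(sm)
    v <- sm$values
    n_obs <- nrow(v)
    if (n_obs < 2L) stop("fewer than 2 complete observations")
    keep_rn <- intersect(rn, colnames(v)); keep_cn <- intersect(cn, colnames(v))
    grams <- lapply(colnames(v), function(nm) kernel_gram(v[, nm], h))
    names(grams) <- colnames(v)
    mlog <- vapply(grams, mean_log_marginal, numeric(1), h = h)
    n <- n_obs
    for (a in keep_rn) for (b in keep_cn) {
      if (a == b) next
      if (mode == "full" && !is.na(vals[b, a])) { vals[a, b] <- vals[b, a]; next }
      fj <- rowSums(grams[[a]] * grams[[b]]) / (2 * pi * n * h^2)
      vals[a, b] <- mean(log(fj)) - mlog[[a]] - mlog[[b]]
    }
  } else {
    n_pair <- 0L
    for (a in rn) for (b in cn) {
      if (a == b) next
      if (mode == "full" && !is.na(vals[b, a])) { vals[a, b] <- vals[b, a]; next }
      x <- data$values[, a]; y <- data$values[, b]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2L) {
        warning("fewer than 2 complete observations for pair ", a, ":", b)
        next
      }
      x <- x[ok]; y <- y[ok]
      if (standardize) {
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          warning("zero variance in pair ", a, ":", b); next
        }
        x <- (x - mean(x)) / stats::sd(x); y <- (y - mean(y)) / stats::sd(y)
      }
      vals[a, b] <- mutual_information(x, y, h)
      n_pair <- max(n_pair, sum(ok))
    }
    n_obs <- n_pair
  }
  structure(list(values = vals, mode = mode, h = h, n_observations = n_obs,
                 deletion = deletion, dataset_label = data$dataset_label),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("mi_matrix (%s): %d x %d, h = %.4f, n = %d\n", x$mode,
              nrow(x$values), ncol(x$values), x$h, x$n_observations))
  print(round(x$values, 4))
  invisible(x)
}

#' Write / read a mutual information matrix as TSV
#'
#' @param mim an `mi_matrix` from [compute_mim()].
#' @param path file path; header comment lines (`#`) record mode, bandwidth
#'   and observation count so the matrix can be re-read in context.
#' @return `path` invisibly (writer); an `mi_matrix` (reader).
#' @export
write_mim <- function(mim, path) {
  stopifnot(inherits(mim, "mi_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# mode=%s h=%.17g n=%d deletion=%s",
                     mim$mode, mim$h, mim$n_observations, mim$deletion), con)
  v <- mim$values
  writeLines(paste(c("variable", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], format(v[i, ], digits = 15, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_mim
#' @export
read_mim <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("missing MIM header line")
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  body <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                            check.names = FALSE)
  v <- as.matrix(body[, -1, drop = FALSE])
  rownames(v) <- body[[1]]
  structure(list(values = v, mode = meta[["mode"]],
                 h = as.numeric(meta[["h"]]),
                 n_observations = as.integer(meta[["n"]]),
                 deletion = meta[["deletion"]], dataset_label = ""),
            class = "mi_matrix")
}
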