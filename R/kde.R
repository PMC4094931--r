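#' Gaussian kernel density estimate in one dimension
#'
#' Estimates the density of a univariate sample as a sum of Gaussian kernels
#' of common bandwidth `h` centred at the observations:
#' \deqn{\hat f(x) = \frac{1}{\sqrt{2\pi}\,n\,h} \sum_{i=1}^{n}
#'       \exp\!\left(-\frac{(x - x_i)^2}{2h^2}\right).}
#'
#' @param x numeric vector of finite observations (length >= 1).
#' @param h kernel bandwidth, a single positive number.
#' @param query numeric vector of evaluation points.
#' @return Numeric vector of non-negative density values, one per query point.
#' @examples
#' kde_univariate(c(-1, 1), h = 1, query = 0)  # exp(-1/2)/sqrt(2*pi)
#' @export
kde_univariate <- function(x, h, query) {
  check_positive_scalar(h, "h")
  x <- as.numeric(x)
  if (!length(x)) stop("empty sample")
  if (anyNA(x) || any(!is.finite(x))) stop("sample must be finite")
  n <- length(x)
  d2 <- outer(query, x, "-")^2
  rowSums(exp(-d2 / (2 * h^2))) / (sqrt(2 * pi) * n * h)
}

#' Gaussian kernel density estimate in two dimensions
#'
#' Bivariate analogue of [kde_univariate()] with a single shared bandwidth
#' for both coordinates:
#' \deqn{\hat f(x, y) = \frac{1}{2\pi\,n\,h^2} \sum_{i=1}^{n}
#'       \exp\!\left(-\frac{(x-x_i)^2 + (y-y_i)^2}{2h^2}\right).}
#'
#' @param x,y equal-length numeric vectors of paired finite observations.
#' @param h kernel bandwidth, a single positive number.
#' @param qx,qy equal-length numeric vectors of evaluation coordinates.
#' @return Numeric vector of non-negative density values, one per query pair.
#' @export
kde_bivariate <- function(x, y, h, qx, qy) {
  check_positive_scalar(h, "h")
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x)) stop("empty sample")
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(qx) != length(qy)) stop("'qx' and 'qy' must have equal length")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop("sample must be finite")
  n <- length(x)
  d2 <- outer(qx, x, "-")^2 + outer(qy, y, "-")^2
  rowSums(exp(-d2 / (2 * h^2))) / (2 * pi * n * h^2)
}

# Squared-distance Gram matrices reused across bandwidth evaluations.
sqdist <- function(x) outer(x, x, "-")^2

# UCV objective evaluated from a precomputed squared-distance matrix.
# dim = 1: D = (xi - xj)^2;  dim = 2: D = (xi - xj)^2 + (yi - yj)^2.
ucv_from_sqdist <- function(D, h, dim) {
  n <- nrow(D)
  # closed-form integral of fhat^2: Gaussian convolution has bandwidth h*sqrt(2)
  E4 <- exp(-D / (4 * h^2))
  term1 <- if (dim == 1L) sum(E4) / (2 * n^2 * h * sqrt(pi))
           else sum(E4) / (4 * pi * n^2 * h^2)
  # leave-one-out density at each observation
  E2 <- exp(-D / (2 * h^2))
  loo <- (rowSums(E2) - 1) / (n - 1)   # kernel at zero distance contributes 1
  norm <- if (dim == 1L) sqrt(2 * pi) * h else 2 * pi * h^2
  term2 <- (2 / n) * sum(loo / norm)
  term1 - term2
}

#' Unbiased cross-validation objective for the univariate KDE
#'
#' The least-squares cross-validation score whose minimizer over `h`
#' estimates the bandwidth minimizing the mean integrated squared error:
#' \deqn{\mathrm{UCV}(h) = \int \hat f_h^2(x)\,dx -
#'       \frac{2}{n} \sum_{i=1}^{n} \hat f_{(-i),h}(x_i),}
#' where \eqn{\hat f_{(-i),h}} is the leave-one-out estimate. The first term
#' uses the closed form for Gaussian kernels.
#'
#' @param x numeric vector of finite observations, length >= 2.
#' @param h bandwidth, a single positive number.
#' @return The UCV score (can be negative).
#' @export
ucv_objective_1d <- function(x, h) {
  check_positive_scalar(h, "h")
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations for leave-one-out")
  if (anyNA(x) || any(!is.finite(x))) stop("sample must be finite")
  ucv_from_sqdist(sqdist(x), h, 1L)
}

#' Unbiased cross-validation objective for the bivariate KDE
#'
#' Extension of [ucv_objective_1d()] to the bivariate kernel density with one
#' shared bandwidth in both coordinates; this is the objective minimized per
#' variable pair by [select_bandwidth()].
#'
#' @param x,y equal-length numeric vectors of paired finite observations,
#'   length >= 2.
#' @param h bandwidth, a single positive number.
#' @return The UCV score (can be negative).
#' @export
ucv_objective_2d <- function(x, y, h) {
  check_positive_scalar(h, "h")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations for leave-one-out")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop("sample must be finite")
  ucv_from_sqdist(sqdist(x) + sqdist(y), h, 2L)
}

# Golden-section minimization of f on [lo, hi]; f assumed unimodal there.
golden_section <- function(f, lo, hi, iter = 40L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (k in seq_len(iter)) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  if (f1 < f2) list(minimum = c1, objective = f1)
  else list(minimum = c2, objective = f2)
}

# UCV-optimal bandwidth for one pair from its squared-distance matrix:
# global minimum over the grid, refined by golden-section search between the
# neighbouring grid points (UCV is prone to local minima, so the grid scan
# comes first).
ucv_optimum_pair <- function(D, h_grid) {
  obj <- vapply(h_grid, function(h) ucv_from_sqdist(D, h, 2L), numeric(1))
  i <- which.min(obj)
  lo <- h_grid[max(1L, i - 1L)]
  hi <- h_grid[min(length(h_grid), i + 1L)]
  if (lo == hi) return(list(h = h_grid[i], score = obj[i]))
  ref <- golden_section(function(h) ucv_from_sqdist(D, h, 2L), lo, hi)
  if (ref$objective <= obj[i]) list(h = ref$minimum, score = ref$objective)
  else list(h = h_grid[i], score = obj[i])
}

default_h_grid <- function() exp(seq(log(0.02), log(2), length.out = 40L))

#' Select a shared kernel bandwidth by pairwise unbiased cross-validation
#'
#' Draws variable pairs from the data, minimizes the bivariate UCV objective
#' ([ucv_objective_2d()]) for each pair over a bandwidth grid with
#' golden-section refinement, and returns the mean of the per-pair optima as
#' the single bandwidth shared by all subsequent density and
#' mutual-information estimates. Variables are standardized (and rows with
#' missing values dropped) first, so one bandwidth is meaningful across
#' variables.
#'
#' @param data a [sample_matrix()].
#' @param n_pairs number of variable pairs to cross-validate. Default: all
#'   eligible pairs when there are at most 200, otherwise 100 pairs sampled
#'   uniformly without replacement (seeded). Values exceeding the number of
#'   available pairs are clamped with a warning.
#' @param h_grid ascending vector of candidate bandwidths (default 40
#'   log-spaced points in \[0.02, 2\]).
#' @param seed integer seed for the pair sampling.
#' @param mode `"bipartite"` draws input-output pairs only; `"full"` draws
#'   from all unordered variable pairs.
#' @return An object of class `bandwidth`: list with `h` (the mean optimum),
#'   `method`, `per_pair_h` (named numeric vector), `ucv_scores`, and
#'   `n_observations`.
#' @examples
#' sm <- generate_planted(planted_network_spec(
#'   n_inputs = 4, n_outputs = 2, n_observations = 60, seed = 1))$data
#' select_bandwidth(sm, n_pairs = 3, seed = 1)
#' @export
select_bandwidth <- function(data, n_pairs = NULL, h_grid = default_h_grid(),
                             seed = 1L, mode = c("bipartite", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "sample_matrix"))
  if (is.unsorted(h_grid) || any(h_grid <= 0))
    stop("'h_grid' must be positive and sorted ascending")
  sm <- standardize_columns(complete_rows(data))
  v <- sm$values
  if (nrow(v) < 2L) stop("need at least 2 complete observations")
  ins <- input_names(sm); outs <- output_names(sm)
  pairs <- if (mode == "bipartite") {
    if (!length(ins) || !length(outs))
      stop("bipartite bandwidth selection needs both inputs and outputs")
    expand.grid(a = ins, b = outs, stringsAsFactors = FALSE)
  } else {
    vn <- colnames(v)
    idx <- which(upper.tri(diag(length(vn))), arr.ind = TRUE)
    data.frame(a = vn[idx[, 1]], b = vn[idx[, 2]], stringsAsFactors = FALSE)
  }
  np <- nrow(pairs)
  if (is.null(n_pairs)) n_pairs <- if (np <= 200L) np else 100L
  if (n_pairs > np) {
    warning("n_pairs = ", n_pairs, " exceeds the ", np,
            " available pairs; using all pairs")
    n_pairs <- np
  }
  if (n_pairs < np) {
    # order-invariant sampling: pairs are indexed in a canonical (sorted) order
    ord <- order(pairs$a, pairs$b)
    pairs <- pairs[ord, , drop = FALSE]
    sel <- with_seed(seed, sample.int(np, n_pairs))
    pairs <- pairs[sort(sel), , drop = FALSE]
  }
  hs <- numeric(nrow(pairs)); scores <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    D <- sqdist(v[, pairs$a[k]]) + sqdist(v[, pairs$b[k]])
    opt <- ucv_optimum_pair(D, h_grid)
    hs[k] <- opt$h; scores[k] <- opt$score
  }
  names(hs) <- names(scores) <- paste(pairs$a, pairs$b, sep = ":")
  structure(list(h = mean(hs), method = "ucv_pair_mean", per_pair_h = hs,
                 ucv_scores = scores, n_observations = nrow(v),
                 mode = mode, seed = as.integer(seed)),
            class = "bandwidth")
}

#' @export
print.bandwidth <- function(x, ...) {
  cat(sprintf("bandwidth h = %.4f (%s; mean of %d pair optima, n = %d)\n",
              x$h, x$method, length(x$per_pair_h), x$n_observations))
  invisible(x)
}
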