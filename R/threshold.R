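#' Permutation null distribution of the mutual information
#'
#' Estimates the distribution of the kernel-density MI estimate under the
#' independence null by repeatedly shuffling the rows of every variable
#' column independently (destroying all dependencies while preserving each
#' marginal), recomputing the full set of MIM entries, and pooling them.
#' Negative estimates are clamped at zero, matching how estimates are
#' compared to thresholds.
#'
#' Because a row permutation leaves each marginal density (as a set of values
#' at its own sample points) unchanged, only the joint-density term has to be
#' recomputed per permutation, which makes a few hundred permutations cheap.
#'
#' @inheritParams compute_mim
#' @param n_permutations number of permutation rounds (>= 1).
#' @param seed integer seed controlling the permutations.
#' @return Numeric vector of pooled null MI values, length
#'   `n_permutations * (number of MIM entries)`.
#' @export
permutation_null <- function(data, mode = c("bipartite", "full"), h,
                             n_permutations = 100L, seed = 1L,
                             standardize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "sample_matrix"))
  if (inherits(h, "bandwidth")) h <- h$h
  check_positive_scalar(h, "h")
  if (!is.numeric(n_permutations) || n_permutations < 1)
    stop("'n_permutations' must be a positive integer")
  n_permutations <- as.integer(n_permutations)
  sm <- complete_rows(data)
  if (standardize) sm <- standardize_columns(sm)
  v <- sm$values
  n <- nrow(v)
  if (n < 2L) stop("fewer than 2 complete observations")
  ins <- input_names(sm); outs <- output_names(sm)
  pairs <- if (mode == "bipartite") {
    expand.grid(a = ins, b = outs, stringsAsFactors = FALSE)
  } else {
    vn <- colnames(v)
    idx <- which(upper.tri(diag(length(vn))), arr.ind = TRUE)
    data.frame(a = vn[idx[, 1]], b = vn[idx[, 2]], stringsAsFactors = FALSE)
  }
  cols <- union(pairs$a, pairs$b)
  grams <- lapply(cols, function(nm) kernel_gram(v[, nm], h))
  names(grams) <- cols
  mlog <- vapply(grams, mean_log_marginal, numeric(1), h = h)
  null_mi <- with_seed(seed, {
    out <- numeric(n_permutations * nrow(pairs))
    k <- 0L
    for (r in seq_len(n_permutations)) {
      perm <- lapply(cols, function(nm) sample.int(n))
      names(perm) <- cols
      Kp <- lapply(cols, function(nm) grams[[nm]][perm[[nm]], perm[[nm]]])
      names(Kp) <- cols
      for (p in seq_len(nrow(pairs))) {
        a <- pairs$a[p]; b <- pairs$b[p]
        fj <- rowSums(Kp[[a]] * Kp[[b]]) / (2 * pi * n * h^2)
        out[k <- k + 1L] <- mean(log(fj)) - mlog[[a]] - mlog[[b]]
      }
    }
    out
  })
  pmax(null_mi, 0)
}

#' Fit the large-deviation tail of a permutation null
#'
#' Under the independence null, the probability that the empirical MI exceeds
#' a value \eqn{I_0} decays exponentially, \eqn{P(I > I_0) \sim e^{-cNI_0}},
#' so \eqn{\ln P} is linear in \eqn{I_0} with a negative slope whose
#' magnitude grows with the sample size \eqn{N}. This function computes the
#' empirical survival function of the pooled null on a grid of 200 equally
#' spaced \eqn{I_0} values (from 0 to the null's 99.9th percentile),
#' restricts it to survival probabilities inside `p_range` (by default from
#' `10/length(null_mi)` — excluding tail points supported by fewer than 10
#' draws, whose log-probabilities are unstable — up to 0.5), and fits
#' \eqn{\ln P = a + b I_0} by least squares.
#'
#' @param null_mi numeric vector of pooled null MI values, e.g. from
#'   [permutation_null()].
#' @param p_range length-2 numeric, the survival-probability window used in
#'   the fit (`0 < p_lo < p_hi <= 1`).
#' @param n_grid number of survival grid points.
#' @return An object of class `null_fit`: list with intercept `a`, slope `b`
#'   (negative), `fit_range` (the \eqn{I_0} window actually used), `fit_r2`,
#'   `p_range`, `n_null`, and the `null_mi` sample itself.
#' @export
fit_large_deviation <- function(null_mi, p_range = NULL, n_grid = 200L) {
  null_mi <- as.numeric(null_mi)
  if (!length(null_mi) || anyNA(null_mi)) stop("'null_mi' must be non-empty and finite")
  if (is.null(p_range)) p_range <- c(min(10 / length(null_mi), 0.25), 0.5)
  if (length(p_range) != 2L || p_range[1] <= 0 || p_range[1] >= p_range[2] ||
      p_range[2] > 1)
    stop("'p_range' must satisfy 0 < p_lo < p_hi <= 1")
  hi <- stats::quantile(null_mi, 0.999, names = FALSE)
  if (hi <= 0) stop("degenerate null: all values are zero")
  grid <- seq(0, hi, length.out = n_grid)
  surv <- vapply(grid, function(g) mean(null_mi > g), numeric(1))
  use <- surv >= p_range[1] & surv <= p_range[2]
  if (sum(use) < 3L || length(unique(surv[use])) < 3L)
    stop("calibration failure: fewer than 3 usable survival points; ",
         "increase the number of permutations")
  x <- grid[use]; y <- log(surv[use])
  fit <- stats::lm(y ~ x)
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 fit_range = range(x), fit_r2 = summary(fit)$r.squared,
                 p_range = p_range, n_null = length(null_mi),
                 null_mi = null_mi),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("null_fit: ln P = %.4f %+.2f * I0 (R2 = %.4f) on I0 in [%.4f, %.4f], %d null draws\n",
              x$a, x$b, x$fit_r2, x$fit_range[1], x$fit_range[2], x$n_null))
  invisible(x)
}

#' Convert a p-value into a mutual-information threshold
#'
#' Inverts the fitted large-deviation relation: for a desired tail
#' probability `p_value`, the MI threshold is
#' \eqn{I_0 = (\ln p - a) / b}. Smaller p-values give larger thresholds.
#'
#' @param fit a `null_fit` from [fit_large_deviation()].
#' @param p_value desired tail probability in (0, 1).
#' @return The MI threshold \eqn{I_0} (nats).
#' @examples
#' fit <- structure(list(a = 0, b = -1), class = "null_fit")
#' threshold_for_pvalue(fit, exp(-2))  # 2
#' @export
threshold_for_pvalue <- function(fit, p_value) {
  stopifnot(inherits(fit, "null_fit"))
  if (!is.numeric(p_value) || length(p_value) != 1L || p_value <= 0 ||
      p_value >= 1)
    stop("'p_value' must be a single number in (0, 1)")
  if (!is.finite(fit$b) || fit$b >= 0)
    stop("calibration failure: fitted slope b must be negative")
  (log(p_value) - fit$a) / fit$b
}

#' Calibrate a mutual-information threshold for a dataset
#'
#' Convenience wrapper running [permutation_null()], [fit_large_deviation()]
#' and [threshold_for_pvalue()] in sequence.
#'
#' @inheritParams permutation_null
#' @param p_value desired tail probability (default 0.005).
#' @return List with elements `fit` (a `null_fit`) and `threshold`.
#' @export
calibrate_threshold <- function(data, mode = c("bipartite", "full"), h,
                                p_value = 0.005, n_permutations = 100L,
                                seed = 1L) {
  mode <- match.arg(mode)
  null_mi <- permutation_null(data, mode, h, n_permutations, seed)
  fit <- fit_large_deviation(null_mi)
  list(fit = fit, threshold = threshold_for_pvalue(fit, p_value))
}
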