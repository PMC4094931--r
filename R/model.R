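#' Fit the linear input-output model on significant inputs
#'
#' Least-squares model \eqn{Y = Xb + \epsilon} between the standardized
#' significant inputs and one mean-centred output: each input column is
#' centred and scaled by its training standard deviation, the output is
#' mean-centred, and the coefficients \eqn{\hat b = (X^T X)^{-1} X^T Y} are
#' computed by a QR least-squares solve (numerically stable and identical to
#' the normal equations on full-rank problems). The training
#' standardization parameters are stored so that test data can be
#' standardized with them at prediction time.
#'
#' @param X numeric matrix of inputs (rows = observations) with column
#'   names; no missing values.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @return An object of class `mi_linear_model`: list with `input_names`,
#'   `x_means`, `x_sds`, `y_mean`, `coefficients` and `trained_on`.
#' @examples
#' X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
#' y <- 2 * scale(X[, 1]) - scale(X[, 2])
#' fit_linear(X, y)$coefficients
#' @export
fit_linear <- function(X, y) {
  if (is.data.frame(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  if (is.null(colnames(X))) stop("'X' must have column names")
  if (nrow(X) != length(y)) stop("rows of 'X' must match length of 'y'")
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least ", ncol(X) + 1L, " observations for ", ncol(X),
         " inputs")
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  zero <- sg == 0
  if (any(zero))
    stop("zero-variance input column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  yc <- y - mean(y)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    coll <- colnames(Xs)[qrX$pivot[(qrX$rank + 1L):ncol(Xs)]]
    stop("least-squares degeneracy: collinear column(s) ",
         paste(coll, collapse = ", "))
  }
  b <- qr.coef(qrX, yc)
  structure(list(input_names = colnames(X), x_means = mu, x_sds = sg,
                 y_mean = mean(y), coefficients = b,
                 trained_on = nrow(X)),
            class = "mi_linear_model")
}

#' Predict from a fitted linear input-output model
#'
#' Applies the training standardization to the new inputs, multiplies by the
#' fitted coefficients and adds back the training response mean.
#'
#' @param object an `mi_linear_model` from [fit_linear()].
#' @param newdata numeric matrix whose column names include the model's
#'   `input_names`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mi_linear_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata) || is.null(colnames(newdata)))
    stop("'newdata' must be a matrix with column names")
  miss <- setdiff(object$input_names, colnames(newdata))
  if (length(miss))
    stop("missing input column(s): ", paste(miss, collapse = ", "))
  Xs <- sweep(sweep(newdata[, object$input_names, drop = FALSE], 2,
                    object$x_means, "-"), 2, object$x_sds, "/")
  drop(Xs %*% object$coefficients) + object$y_mean
}

#' @export
print.mi_linear_model <- function(x, ...) {
  cat(sprintf("mi_linear_model: %d inputs, trained on %d observations\n",
              length(x$input_names), x$trained_on))
  print(round(stats::setNames(x$coefficients, x$input_names), 4))
  invisible(x)
}

#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}}.
#'
#' @param y,y_pred equal-length numeric vectors of observed and predicted
#'   values.
#' @return A non-negative number.
#' @export
rmse <- function(y, y_pred) {
  if (length(y) != length(y_pred)) stop("'y' and 'y_pred' lengths differ")
  if (!length(y)) stop("empty vectors")
  sqrt(mean((y - y_pred)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2},
#' where \eqn{\bar y} is the mean of the evaluation set itself (so test-set
#' R-squared is computed against the test mean). Negative values indicate a
#' model worse than predicting the mean.
#'
#' @inheritParams rmse
#' @return A number, at most 1.
#' @export
r_squared <- function(y, y_pred) {
  if (length(y) != length(y_pred)) stop("'y' and 'y_pred' lengths differ")
  if (length(y) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("undefined metric: 'y' is constant")
  1 - sum((y - y_pred)^2) / ss_tot
}

#' Seeded train/test split of a sample matrix
#'
#' Removes rows with missing values across the chosen variables (listwise,
#' mirroring per-output effective row counts when `variables` is the
#' significant-input set of one output) and splits the remaining rows
#' uniformly at random into a training and a test set.
#'
#' @param data a [sample_matrix()].
#' @param test_fraction fraction of complete rows assigned to the test set
#'   (default 0.25, an approximate 3:1 train:test ratio).
#' @param seed integer seed.
#' @param variables variables across which rows must be complete (default
#'   all).
#' @return List with `sample_matrix` elements `train` and `test`.
#' @export
split_train_test <- function(data, test_fraction = 0.25, seed = 1L,
                             variables = NULL) {
  stopifnot(inherits(data, "sample_matrix"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must be in (0, 1)")
  sm <- complete_rows(data, variables)
  n <- nrow(sm$values)
  if (n < 4L) stop("too few complete rows to split (", n, ")")
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) n_test <- n - 1L
  test_idx <- sort(with_seed(seed, sample.int(n, n_test)))
  list(train = sample_matrix(sm$values[-test_idx, , drop = FALSE], sm$roles,
                             sm$dataset_label),
       test = sample_matrix(sm$values[test_idx, , drop = FALSE], sm$roles,
                            sm$dataset_label))
}

#' Fit and evaluate the linear model for one output of a network
#'
#' Glue between the reconstructed network and the predictive model: takes
#' the significant inputs of `output_name` (its neighbours in `net`), applies
#' per-output listwise deletion, splits train/test, fits [fit_linear()] and
#' reports RMSE and R-squared on both sets.
#'
#' @param data a [sample_matrix()] holding inputs and outputs.
#' @param net an `mi_network` whose input-output edges define the significant
#'   inputs.
#' @param output_name the output variable to model.
#' @param test_fraction,seed passed to [split_train_test()].
#' @return List with `model` (`mi_linear_model`), `inputs`, `n_train`,
#'   `n_test`, `rmse_train`, `rmse_test`, `r2_train`, `r2_test`.
#' @export
evaluate_output_model <- function(data, net, output_name,
                                  test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(data, "sample_matrix"), inherits(net, "mi_network"))
  if (!output_name %in% output_names(data))
    stop("unknown output variable: ", output_name)
  e <- net$edges
  e <- e[e$edge_type == "input-output" &
           (e$source == output_name | e$target == output_name), ,
         drop = FALSE]
  inputs <- unique(ifelse(e$source == output_name, e$target, e$source))
  if (!length(inputs))
    stop("no significant inputs for output ", output_name)
  sp <- split_train_test(data, test_fraction, seed,
                         variables = c(inputs, output_name))
  Xtr <- sp$train$values[, inputs, drop = FALSE]
  ytr <- sp$train$values[, output_name]
  Xte <- sp$test$values[, inputs, drop = FALSE]
  yte <- sp$test$values[, output_name]
  fit <- fit_linear(Xtr, ytr)
  ptr <- predict(fit, Xtr); pte <- predict(fit, Xte)
  list(model = fit, inputs = inputs,
       n_train = length(ytr), n_test = length(yte),
       rmse_train = rmse(ytr, ptr), rmse_test = rmse(yte, pte),
       r2_train = r_squared(ytr, ptr), r2_test = r_squared(yte, pte))
}
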