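#' Construct a sample matrix of observations by named variables
#'
#' The unit of all analysis in kdenet: a numeric matrix of observations
#' (rows) by variables (columns), where each variable carries a role label
#' marking it as a signaling input (e.g. a phosphoprotein) or a measured
#' output (e.g. a secreted cytokine). Missing values are stored as `NA` and
#' handled downstream by listwise or pairwise deletion.
#'
#' @param values numeric matrix (or data.frame of numerics) with unique
#'   column names; rows are observations/conditions.
#' @param roles character vector, one of `"input"`/`"output"` per column.
#'   Either named by variable or positional.
#' @param dataset_label optional string tagging the dataset (e.g. `"Toll"`).
#' @return An object of class `sample_matrix`: a list with elements
#'   `values`, `roles` (named character vector) and `dataset_label`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "y")))
#' sm <- sample_matrix(m, roles = c("input", "input", "input", "output"))
#' input_names(sm)
#' @export
sample_matrix <- function(values, roles, dataset_label = "") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  vn <- colnames(values)
  if (is.null(vn) || anyNA(vn) || any(vn == ""))
    stop("'values' must have non-empty column names")
  dup <- unique(vn[duplicated(vn)])
  if (length(dup))
    stop("duplicate variable names: ", paste(dup, collapse = ", "))
  if (!is.null(names(roles))) {
    if (!setequal(names(roles), vn))
      stop("names of 'roles' must match the variable names")
    roles <- roles[vn]
  } else {
    if (length(roles) != ncol(values))
      stop("'roles' must have one entry per column")
    names(roles) <- vn
  }
  if (!all(roles %in% c("input", "output")))
    stop("roles must be 'input' or 'output'")
  structure(list(values = values, roles = roles,
                 dataset_label = as.character(dataset_label)),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("sample_matrix: %d observations x %d variables (%d inputs, %d outputs)\n",
              nrow(x$values), ncol(x$values),
              sum(x$roles == "input"), sum(x$roles == "output")))
  if (nzchar(x$dataset_label)) cat("dataset:", x$dataset_label, "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("missing cells: %d (%d complete rows)\n",
                         nmiss, sum(stats::complete.cases(x$values))))
  invisible(x)
}

#' @rdname sample_matrix
#' @param x a `sample_matrix`.
#' @export
input_names <- function(x) names(x$roles)[x$roles == "input"]

#' @rdname sample_matrix
#' @export
output_names <- function(x) names(x$roles)[x$roles == "output"]

#' Drop observation rows containing missing values (listwise deletion)
#'
#' @param x a [sample_matrix()].
#' @param variables variables across which completeness is required
#'   (default: all).
#' @return A `sample_matrix` restricted to `variables` with only complete
#'   rows retained.
#' @export
complete_rows <- function(x, variables = NULL) {
  stopifnot(inherits(x, "sample_matrix"))
  if (is.null(variables)) variables <- colnames(x$values)
  miss <- setdiff(variables, colnames(x$values))
  if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
  v <- x$values[, variables, drop = FALSE]
  keep <- stats::complete.cases(v)
  sample_matrix(v[keep, , drop = FALSE], x$roles[variables], x$dataset_label)
}

#' Standardize each variable to zero mean and unit standard deviation
#'
#' Standardization makes a single shared kernel bandwidth meaningful across
#' variables. Zero-variance columns cannot be standardized and are dropped
#' with a warning.
#'
#' @param x a [sample_matrix()] (missing values are ignored in the per-column
#'   mean/sd and preserved in the output).
#' @return A standardized `sample_matrix`.
#' @export
standardize_columns <- function(x) {
  stopifnot(inherits(x, "sample_matrix"))
  v <- x$values
  mu <- colMeans(v, na.rm = TRUE)
  sg <- apply(v, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sg) | sg == 0
  if (any(bad)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(v)[bad], collapse = ", "))
    v <- v[, !bad, drop = FALSE]
    mu <- mu[!bad]; sg <- sg[!bad]
  }
  if (!ncol(v)) stop("no variables left after dropping zero-variance columns")
  v <- sweep(sweep(v, 2, mu, "-"), 2, sg, "/")
  sample_matrix(v, x$roles[colnames(v)], x$dataset_label)
}

parse_numeric_table <- function(path, na_token = "NA") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  vn <- colnames(raw)
  dup <- unique(vn[duplicated(vn)])
  if (length(dup))
    stop("duplicate column names in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, vn))
  for (j in seq_along(vn)) {
    cell <- trimws(raw[[j]])
    is_na <- cell == na_token | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s: row %d, column '%s' ('%s')",
                   basename(path), bad[1], vn[j], cell[bad[1]]))
    num[is_na] <- NA_real_
    m[, j] <- num
  }
  m
}

#' Read a sample matrix from delimited text
#'
#' Reads one file (with a role map) or a pair of input/output files, as
#' produced by [write_sample_matrix()] or by upstream preprocessing. The
#' delimiter is chosen from the extension (`.csv` comma, otherwise tab); the
#' first row must hold unique variable names.
#'
#' @param path path to the matrix (when `roles` is given) or to the input
#'   block (when `output_path` is given).
#' @param output_path optional path to the output block; its columns get role
#'   `"output"`, those of `path` get `"input"`.
#' @param roles named or positional role vector for the single-file form.
#' @param na_token string marking missing cells (default `"NA"`; empty cells
#'   are also treated as missing).
#' @param dataset_label dataset tag stored on the result.
#' @return A [sample_matrix()].
#' @export
read_sample_matrix <- function(path, output_path = NULL, roles = NULL,
                               na_token = "NA", dataset_label = "") {
  if (!is.null(output_path)) {
    xin <- parse_numeric_table(path, na_token)
    xout <- parse_numeric_table(output_path, na_token)
    if (nrow(xin) != nrow(xout))
      stop("input and output files have different row counts (",
           nrow(xin), " vs ", nrow(xout), ")")
    clash <- intersect(colnames(xin), colnames(xout))
    if (length(clash))
      stop("variable names shared between input and output files: ",
           paste(clash, collapse = ", "))
    v <- cbind(xin, xout)
    roles <- c(rep("input", ncol(xin)), rep("output", ncol(xout)))
  } else {
    v <- parse_numeric_table(path, na_token)
    if (is.null(roles)) stop("'roles' is required when reading a single file")
  }
  sample_matrix(v, roles, dataset_label)
}

#' Write a sample matrix (or plain matrix) as delimited text
#'
#' @param x a [sample_matrix()] or numeric matrix with column names.
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param na_token string used for missing cells.
#' @return `path`, invisibly.
#' @export
write_sample_matrix <- function(x, path, na_token = "NA") {
  v <- if (inherits(x, "sample_matrix")) x$values else x
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = na_token)
  invisible(path)
}
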