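#' Internal-standard normalization of a peak-area matrix
#'
#' Stable-isotope internal standards (IS) are spiked at fixed concentration
#' into every extraction, so any cross-sample variation in the IS rows is
#' technical. Each sample's scale factor is the geometric mean of its IS
#' peak areas divided by the grand geometric mean of IS areas across all
#' samples; every non-IS peak area is divided by that factor. IS rows are
#' retained unchanged but flagged consumed: normalizing an already
#' normalized matrix is a no-op, making the operation idempotent.
#'
#' Because scale factors are anchored to the grand geometric mean, rescaling
#' a single sample's column changes normalized values only by a common
#' global constant (the grand mean moves); relative abundances are exactly
#' invariant.
#'
#' @param matrix A linear-scale [metabolite_matrix()] with at least one IS
#'   peak; every IS area must be positive in every sample.
#' @return The normalized matrix, with `normalized = TRUE` and attribute
#'   `"scale_factors"` (named per-sample factors).
#' @examples
#' sim <- simulate_metabolome(metabolome_config(seed = 3))
#' norm <- is_normalize(sim$matrix)
#' @export
is_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  stop_if(matrix$log2, "is_normalize expects a linear-scale matrix")
  if (matrix$normalized) {
    return(matrix) # IS rows already consumed; idempotent by contract
  }
  is_row <- matrix$peaks$is_internal_standard
  stop_if(!any(is_row), "no internal-standard peaks flagged")
  is_area <- matrix$values[is_row, , drop = FALSE]
  bad <- colnames(is_area)[apply(is_area, 2,
                                 function(x) any(!is.finite(x) | x <= 0))]
  stop_if(length(bad) > 0,
          "internal standard missing or nonpositive in sample(s): ",
          paste(bad, collapse = ", "))
  g <- apply(is_area, 2, geomean)
  s <- g / geomean(g)
  matrix$values[!is_row, ] <- sweep(matrix$values[!is_row, , drop = FALSE],
                                    2, s, `/`)
  matrix$normalized <- TRUE
  attr(matrix, "scale_factors") <- s
  matrix
}

#' Half-minimum imputation and log2 transform
#'
#' Replaces zero or missing peak areas by half the minimum positive area of
#' that peak across samples, then log2-transforms the matrix. Half-minimum
#' imputation keeps fold changes of low-abundance peaks bounded, unlike a
#' fixed offset; `method = "offset"` instead uses `log2(x + 1)` with
#' missing values treated as 0. Peaks missing in all samples cannot be
#' imputed and are dropped with a warning.
#'
#' @param matrix A linear-scale [metabolite_matrix()] (normally the output
#'   of [is_normalize()]).
#' @param method `"halfmin"` (default) or `"offset"`.
#' @return The matrix on the log2 scale (`log2 = TRUE`), with attribute
#'   `"n_dropped"` (all-missing peaks removed).
#' @export
impute_and_log2 <- function(matrix, method = c("halfmin", "offset")) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  method <- match.arg(method)
  stop_if(matrix$log2, "matrix is already on the log2 scale")
  v <- matrix$values
  stop_if(any(v < 0, na.rm = TRUE), "negative areas cannot be transformed")
  all_missing <- apply(v, 1, function(x) all(is.na(x) | x == 0))
  if (any(all_missing)) {
    warning(sum(all_missing), " peak(s) missing in all samples; dropped",
            call. = FALSE)
    v <- v[!all_missing, , drop = FALSE]
    matrix$peaks <- matrix$peaks[!all_missing, ]
  }
  if (method == "halfmin") {
    v <- t(apply(v, 1, function(x) {
      miss <- is.na(x) | x == 0
      if (any(miss)) x[miss] <- min(x[!miss]) / 2
      x
    }))
    matrix$values <- log2(v)
  } else {
    v[is.na(v)] <- 0
    matrix$values <- log2(v + 1)
  }
  dimnames(matrix$values) <- list(matrix$peaks$peak_id,
                                  matrix$samples$sample_id)
  matrix$log2 <- TRUE
  attr(matrix, "n_dropped") <- sum(all_missing)
  matrix
}
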