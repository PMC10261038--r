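# Internal helpers shared across modules.

#' @importFrom rlang .data %||%
#' @importFrom stats pf ptukey qtukey sd var
NULL

geomean <- function(x) exp(mean(log(x)))

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Two-sample pooled-variance Student's t-test with degenerate-case handling
#'
#' Thin wrapper around [stats::t.test()] (`var.equal = TRUE`, two-sided) that
#' resolves the zero-variance cases `t.test()` refuses: two constant groups
#' with equal means give `p = 1`; constant groups with unequal means give a
#' p-value at the machine limit and a `degenerate` flag.
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return List with `statistic`, `df`, `p`, `mean_x`, `mean_y`, `degenerate`.
#' @keywords internal
student_t2 <- function(x, y) {
  stop_if(length(x) < 2 || length(y) < 2, "need >= 2 replicates per group")
  mx <- mean(x)
  my <- mean(y)
  df <- length(x) + length(y) - 2
  pooled <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) / df
  if (pooled <= 0) {
    if (isTRUE(all.equal(mx, my))) {
      return(list(statistic = 0, df = df, p = 1, mean_x = mx, mean_y = my,
                  degenerate = FALSE))
    }
    return(list(statistic = sign(mx - my) * Inf, df = df,
                p = .Machine$double.xmin, mean_x = mx, mean_y = my,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mx, mean_y = my, degenerate = FALSE)
}

# Draw positive trait replicates: Normal(mean, cv * mean) truncated at zero
# by resampling (negative draws are essentially impossible at the cv values
# used for plant fresh weight, but the support contract is values > 0).
rnorm_trunc_pos <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, cv * mean)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, cv * mean)
  }
  x
}
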