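#' Principal component analysis of a log2 metabolite matrix
#'
#' Treats samples as observations and peaks as variables (samples x peaks),
#' mean-centers each peak, optionally scales to unit variance
#' (`autoscale`), and decomposes via [stats::prcomp()] (SVD). Mean-centering
#' only is the default, the usual choice for log-transformed GC-MS peak
#' areas where the log already tames the dynamic range. Internal-standard
#' rows are excluded. Loadings follow a fixed sign convention — the element
#' of largest magnitude in each loading vector is positive — so results are
#' reproducible across platforms.
#'
#' @param matrix A log2-scale [metabolite_matrix()] with no missing values
#'   (impute upstream with [impute_and_log2()]).
#' @param scaling `"center"` (default) or `"autoscale"`. Under autoscaling,
#'   constant peaks carry no usable variance and are dropped with a
#'   warning.
#' @return List of class `pca_result`: `scores` (samples x components,
#'   with sample metadata as a `samples` tibble), `loadings` (peaks x
#'   components), `explained_pct` (percent variance per component,
#'   nonincreasing), `scaling`.
#' @examples
#' sim <- simulate_metabolome(metabolome_config(seed = 5))
#' m <- impute_and_log2(is_normalize(sim$matrix))
#' res <- run_pca(m)
#' head(res$explained_pct)
#' @export
run_pca <- function(matrix, scaling = c("center", "autoscale")) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  scaling <- match.arg(scaling)
  stop_if(!matrix$log2, "run_pca expects a log2-scale matrix")
  keep <- !matrix$peaks$is_internal_standard
  x <- t(matrix$values[keep, , drop = FALSE]) # samples x peaks
  stop_if(anyNA(x), "missing values present; impute first")
  stop_if(nrow(x) < 2 || ncol(x) < 2, "need >= 2 samples and >= 2 peaks")
  peak_sd <- apply(x, 2, sd)
  stop_if(all(peak_sd == 0), "no variance in the matrix")
  if (scaling == "autoscale" && any(peak_sd == 0)) {
    warning(sum(peak_sd == 0), " constant peak(s) dropped under autoscaling",
            call. = FALSE)
    x <- x[, peak_sd > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scaling == "autoscale")
  # deterministic sign: largest-|.| loading element positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  lambda <- pc$sdev^2
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 explained_pct = 100 * lambda / sum(lambda),
                 scaling = scaling,
                 samples = matrix$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(4, length(x$explained_pct))
  cat(sprintf("<pca_result> %d samples x %d peaks (%s)\n",
              nrow(x$scores), nrow(x$loadings), x$scaling))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("PC%d %.2f%%", seq_len(k),
                            x$explained_pct[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Group centroids and separation in the PC1/PC2 plane
#'
#' Descriptive summary of how the lines of a combination separate in score
#' space: the centroid of each group on PC1/PC2 and all pairwise centroid
#' distances, with each group's mean within-group distance to its centroid
#' for comparison.
#'
#' @param result A `pca_result` from [run_pca()].
#' @param sample_groups Optional named vector `sample_id -> group`; default
#'   is the line of each sample.
#' @return List with `centroids` (tibble `group`, `pc1`, `pc2`,
#'   `within_mean_dist`, `n`) and `distances` (tibble `group1`, `group2`,
#'   `dist`; empty for a single group).
#' @export
group_separation_summary <- function(result, sample_groups = NULL) {
  stopifnot(inherits(result, "pca_result"))
  groups <- sample_groups %||%
    stats::setNames(result$samples$line_id, result$samples$sample_id)
  ids <- rownames(result$scores)
  stop_if(!all(ids %in% names(groups)), "groups must cover all samples")
  g <- groups[ids]
  sc <- result$scores[, seq_len(min(2, ncol(result$scores))), drop = FALSE]
  if (ncol(sc) == 1) sc <- cbind(sc, 0)
  centroids <- purrr::map_dfr(unique(g), function(grp) {
    pts <- sc[g == grp, , drop = FALSE]
    ctr <- colMeans(pts)
    tibble::tibble(
      group = grp, pc1 = ctr[1], pc2 = ctr[2],
      within_mean_dist = mean(sqrt(rowSums(sweep(pts, 2, ctr)^2))),
      n = nrow(pts))
  })
  if (nrow(centroids) < 2) {
    return(list(centroids = centroids,
                distances = tibble::tibble(group1 = character(),
                                           group2 = character(),
                                           dist = numeric())))
  }
  prs <- utils::combn(centroids$group, 2)
  distances <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    a <- centroids[centroids$group == prs[1, k], ]
    b <- centroids[centroids$group == prs[2, k], ]
    tibble::tibble(group1 = prs[1, k], group2 = prs[2, k],
                   dist = sqrt((a$pc1 - b$pc1)^2 + (a$pc2 - b$pc2)^2))
  })
  list(centroids = centroids, distances = distances)
}
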