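#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: after sorting ascending, `q(i)` is the minimum
#' over `j >= i` of `p(j) * m / j`, capped at 1, returned in input order.
#' Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p_values) {
  stop_if(length(p_values) == 0, "empty p-value vector")
  stop_if(any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-peak two-sample t-tests between two lines
#'
#' For every peak, a two-sample pooled-variance Student's t-test on the
#' log2-scale values of the two lines' samples. Internal-standard rows are
#' excluded (they carry no biology). Peaks with zero pooled variance and
#' equal means get p = 1.
#'
#' @param matrix A log2-scale [metabolite_matrix()].
#' @param group_a,group_b Line identifiers or roles (e.g. `"F1"`,
#'   `"parent1"`, or an accession name), >= 2 samples each.
#' @return Tibble with `peak_id`, `annotation`, `p`, and `direction`
#'   (`"up"` / `"down"`: sign of group_a mean minus group_b mean;
#'   `"none"` on an exact tie).
#' @export
per_peak_tests <- function(matrix, group_a, group_b) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  stop_if(!matrix$log2, "per_peak_tests expects a log2-scale matrix")
  ia <- sample_index(matrix, group_a)
  ib <- sample_index(matrix, group_b)
  stop_if(length(ia) < 2 || length(ib) < 2,
          "need >= 2 samples per group")
  keep <- !matrix$peaks$is_internal_standard
  v <- matrix$values[keep, , drop = FALSE]
  res <- apply(v, 1, function(x) {
    tt <- student_t2(x[ia], x[ib])
    c(p = tt$p, delta = tt$mean_x - tt$mean_y)
  })
  tibble::tibble(
    peak_id = matrix$peaks$peak_id[keep],
    annotation = matrix$peaks$annotation[keep],
    p = res["p", ],
    direction = dplyr::case_when(res["delta", ] > 0 ~ "up",
                                 res["delta", ] < 0 ~ "down",
                                 TRUE ~ "none"))
}

#' Log2 fold change of a hybrid mean over the mid-parent value
#'
#' @param hybrid_mean,parent1_mean,parent2_mean Positive linear-scale means.
#' @return `log2(hybrid_mean / ((parent1_mean + parent2_mean) / 2))`.
#' @examples
#' log2fc_vs_mpv(8, 4, 4) # 1
#' @export
log2fc_vs_mpv <- function(hybrid_mean, parent1_mean, parent2_mean) {
  stop_if(any(c(hybrid_mean, parent1_mean, parent2_mean) <= 0),
          "means must be > 0 on the linear scale")
  log2(hybrid_mean / ((parent1_mean + parent2_mean) / 2))
}

#' Combine per-parent calls into a both-parents call
#'
#' A metabolite counts as changed in a hybrid only when it differs from
#' *both* parents in the same direction at the FDR threshold.
#'
#' @param q_vs_p1,q_vs_p2 BH-adjusted q-values of the hybrid-vs-parent
#'   comparisons.
#' @param dir_vs_p1,dir_vs_p2 Directions (`"up"` / `"down"`) of the same
#'   comparisons.
#' @param threshold FDR threshold, default 0.05.
#' @return `"up"`, `"down"`, or `"ns"` (vectorized).
#' @export
call_vs_both_parents <- function(q_vs_p1, dir_vs_p1, q_vs_p2, dir_vs_p2,
                                 threshold = 0.05) {
  dplyr::case_when(
    q_vs_p1 < threshold & q_vs_p2 < threshold &
      dir_vs_p1 == "up" & dir_vs_p2 == "up" ~ "up",
    q_vs_p1 < threshold & q_vs_p2 < threshold &
      dir_vs_p1 == "down" & dir_vs_p2 == "down" ~ "down",
    TRUE ~ "ns")
}

#' Differential-metabolite table for one hybrid of a combination
#'
#' Tests the hybrid against each parent per peak on the log2 matrix, adjusts
#' each hybrid-vs-parent comparison family with Benjamini-Hochberg, computes
#' the log2 fold change of the hybrid over the mid-parent value on
#' back-transformed linear-scale means, and combines the two parental
#' comparisons into a both-parents call. The alternative fold change as a
#' difference of log2 means is reported alongside
#' (`log2fc_vs_mpv_logmeans`).
#'
#' @param matrix A log2-scale [metabolite_matrix()] holding the four lines
#'   of a combination.
#' @param hybrid Role or line id of the hybrid (`"F1"` or `"F1rec"`).
#' @param threshold FDR threshold for calls, default 0.05.
#' @return Tibble with one row per non-IS peak: `peak_id`, `annotation`,
#'   `hybrid`, `p_vs_p1`, `q_vs_p1`, `dir_vs_p1`, `p_vs_p2`, `q_vs_p2`,
#'   `dir_vs_p2`, `log2fc_vs_mpv`, `log2fc_vs_mpv_logmeans`, `call`.
#' @export
differential_table <- function(matrix, hybrid, threshold = 0.05) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  stop_if(!matrix$log2, "differential_table expects a log2-scale matrix")
  t1 <- per_peak_tests(matrix, hybrid, "parent1")
  t2 <- per_peak_tests(matrix, hybrid, "parent2")
  # BH within each hybrid-vs-parent family of peaks
  q1 <- bh_fdr(t1$p)
  q2 <- bh_fdr(t2$p)

  keep <- !matrix$peaks$is_internal_standard
  lin <- linear_values(matrix)[keep, , drop = FALSE]
  log2v <- matrix$values[keep, , drop = FALSE]
  ih <- sample_index(matrix, hybrid)
  i1 <- sample_index(matrix, "parent1")
  i2 <- sample_index(matrix, "parent2")
  fc <- log2fc_vs_mpv(rowMeans(lin[, ih, drop = FALSE]),
                      rowMeans(lin[, i1, drop = FALSE]),
                      rowMeans(lin[, i2, drop = FALSE]))
  fc_logmeans <- rowMeans(log2v[, ih, drop = FALSE]) -
    (rowMeans(log2v[, i1, drop = FALSE]) +
       rowMeans(log2v[, i2, drop = FALSE])) / 2

  # direction flags are reported only for FDR-significant comparisons
  gate <- function(q, dir) ifelse(q < threshold & dir %in% c("up", "down"),
                                  dir, "ns")
  tibble::tibble(
    peak_id = t1$peak_id, annotation = t1$annotation,
    hybrid = hybrid,
    p_vs_p1 = t1$p, q_vs_p1 = q1, dir_vs_p1 = gate(q1, t1$direction),
    p_vs_p2 = t2$p, q_vs_p2 = q2, dir_vs_p2 = gate(q2, t2$direction),
    log2fc_vs_mpv = unname(fc),
    log2fc_vs_mpv_logmeans = unname(fc_logmeans),
    call = call_vs_both_parents(q1, t1$direction, q2, t2$direction,
                                threshold = threshold))
}

#' Wide fold-change table across combinations (heatmap layout)
#'
#' Stacks differential tables from several combinations into a peaks x
#' hybrid-lines matrix of log2 fold changes versus the mid-parent value,
#' with an asterisk mark wherever the both-parents call is significant and
#' `"ND"` where a peak was not detected in a combination.
#'
#' @param tables Named list of differential tables ([differential_table()]
#'   output); names identify the hybrid line (e.g. `"Col x C24"`).
#' @return Tibble with `peak_id`, `annotation`, then one column per hybrid
#'   holding formatted cells: a signed fold change (2 decimals), `"*"`
#'   appended when significant, or `"ND"`.
#' @export
heatmap_table <- function(tables) {
  stop_if(length(tables) == 0, "no differential tables given")
  stop_if(is.null(names(tables)) || any(names(tables) == ""),
          "tables must be named by hybrid line")
  all_peaks <- purrr::map_dfr(tables, ~ .x[, c("peak_id", "annotation")]) |>
    dplyr::distinct()
  cells <- purrr::imap(tables, function(tab, nm) {
    x <- sprintf("%.2f%s", tab$log2fc_vs_mpv,
                 ifelse(tab$call != "ns", "*", ""))
    stats::setNames(x, tab$peak_id)
  })
  out <- all_peaks
  for (nm in names(cells)) {
    out[[nm]] <- unname(cells[[nm]][all_peaks$peak_id])
    out[[nm]][is.na(out[[nm]])] <- "ND"
  }
  out
}
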