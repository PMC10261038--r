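#' Per-sample fumarate/malate ratio
#'
#' @param fumarate_area,malate_area Positive linear-scale peak areas from
#'   the same sample. A missing fumarate gives a missing ratio with a
#'   warning; a nonpositive malate is an error (vectorized).
#' @return `fumarate_area / malate_area`.
#' @examples
#' sample_ratio(2, 1) # 2
#' @export
sample_ratio <- function(fumarate_area, malate_area) {
  stop_if(any(!is.na(malate_area) & malate_area <= 0),
          "malate area must be > 0")
  if (anyNA(fumarate_area)) {
    warning("missing fumarate area; ratio set to NA", call. = FALSE)
  }
  fumarate_area / malate_area
}

#' Fold change of a hybrid's mean ratio over the mid-parent ratio
#'
#' Ratios are computed per sample and averaged per line; the mid-parent
#' ratio is the mean of the two parental mean ratios. The fold is the
#' hybrid's mean ratio over that mid-parent ratio.
#'
#' @param hybrid_ratios,parent1_ratios,parent2_ratios Per-sample ratios,
#'   >= 2 per line.
#' @return Dimensionless fold.
#' @examples
#' fold_vs_mpv_ratio(c(4.3, 4.5), c(2.4, 2.6), c(1.4, 1.6)) # 2.2
#' @export
fold_vs_mpv_ratio <- function(hybrid_ratios, parent1_ratios,
                              parent2_ratios) {
  stop_if(length(hybrid_ratios) < 2 || length(parent1_ratios) < 2 ||
            length(parent2_ratios) < 2, "need >= 2 samples per line")
  mpv <- (mean(parent1_ratios) + mean(parent2_ratios)) / 2
  stop_if(mpv <= 0, "mid-parent ratio must be > 0")
  mean(hybrid_ratios) / mpv
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA over the groups, runs all pairwise Tukey honest
#' significant difference comparisons ([stats::TukeyHSD()]), and summarizes
#' them as a compact letter display: two groups share a letter if and only
#' if their Tukey-adjusted p-value is at least `alpha`. Letters are
#' assigned by the insert-and-absorb algorithm with groups ordered by
#' descending mean, so output is deterministic.
#'
#' @param groups Named list `line -> numeric values` (>= 2 groups, >= 2
#'   values each).
#' @param alpha Significance level, default 0.05.
#' @return List with `anova_p`, `tukey` (tibble `group1`, `group2`, `diff`,
#'   `p_adj`), and `letters` (named character vector per group, in input
#'   order).
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1),
#'                  c = c(8, 9, 10)))
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stop_if(length(groups) < 2, "need >= 2 groups")
  stop_if(is.null(names(groups)) || any(names(groups) == ""),
          "groups must be named")
  stop_if(any(lengths(groups) < 2), "each group needs >= 2 values")
  df <- tibble::tibble(
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)),
    value = unlist(groups, use.names = FALSE))
  if (stats::var(df$value) == 0) {
    # all observations identical: nothing to distinguish
    return(list(anova_p = 1,
                tukey = tibble::tibble(group1 = character(),
                                       group2 = character(),
                                       diff = numeric(), p_adj = numeric()),
                letters = stats::setNames(rep("a", length(groups)),
                                          names(groups))))
  }
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  # TukeyHSD rows follow combn(levels, 2) order; carry the pair explicitly
  # because group names may themselves contain the "-" separator
  pairs <- t(utils::combn(levels(df$group), 2))
  tukey <- tibble::tibble(group1 = pairs[, 1], group2 = pairs[, 2],
                          diff = tk[, "diff"], p_adj = tk[, "p adj"])
  means <- vapply(groups, mean, numeric(1))
  sig <- tukey[tukey$p_adj < alpha, ]
  sig_pairs <- purrr::map2(sig$group1, sig$group2, c)
  letters <- compact_letter_display(names(groups)[order(-means)], sig_pairs)
  list(anova_p = anova_p, tukey = tukey,
       letters = letters[names(groups)])
}

# Insert-and-absorb compact letter display. `ordered_groups` fixes letter
# order (descending mean); `sig_pairs` is a list of length-2 character
# vectors of significantly different groups. Guarantees: a significantly
# different pair never shares a letter; a non-different pair always does.
compact_letter_display <- function(ordered_groups, sig_pairs) {
  cols <- list(ordered_groups) # start: one letter containing everything
  for (pr in sig_pairs) {
    new_cols <- list()
    for (col in cols) {
      if (all(pr %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, pr[1])),
                      list(setdiff(col, pr[2])))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the first (highest-mean) group they contain
  first_idx <- vapply(cols, function(col)
    min(match(col, ordered_groups)), numeric(1))
  cols <- cols[order(first_idx)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Fumarate/malate ratio analysis for one combination
#'
#' Extracts the fumarate and malate peaks from a linear-scale (normalized)
#' matrix, computes per-sample ratios, per-line mean ratios, the fold
#' change of each hybrid's mean ratio versus the mid-parent ratio, and
#' Tukey letter groups over the per-sample ratios of the four lines. The
#' alternative mid-parent convention — the ratio of mid-parent fumarate to
#' mid-parent malate — is reported alongside (`fold_vs_mpv_of_areas`).
#'
#' @param matrix A linear-scale [metabolite_matrix()].
#' @param fumarate,malate Peak ids or annotations of the two peaks
#'   (defaults look up the annotations `"fumarate"` / `"malate"`).
#' @param alpha Significance level for Tukey letters, default 0.05.
#' @return List of class `ratio_result`: `samples` (tibble `sample_id`,
#'   `line_id`, `role`, `ratio`), `line_means` (named vector),
#'   `fold_vs_mpv` and `fold_vs_mpv_of_areas` (named vectors for `F1`,
#'   `F1rec`), `anova_p`, `letters`.
#' @export
tca_ratio <- function(matrix, fumarate = "fumarate", malate = "malate",
                      alpha = 0.05) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  stop_if(matrix$log2,
          "ratios are computed on linear-scale (pre-log) areas")
  find_peak <- function(id) {
    i <- which(matrix$peaks$peak_id == id | matrix$peaks$annotation == id)
    stop_if(length(i) == 0, "peak '", id, "' not found")
    stop_if(length(i) > 1, "peak '", id, "' matches several rows")
    i
  }
  fi <- find_peak(fumarate)
  mi <- find_peak(malate)
  ratio <- sample_ratio(matrix$values[fi, ], matrix$values[mi, ])
  samples <- dplyr::mutate(matrix$samples, ratio = unname(ratio))
  by_role <- split(samples$ratio, samples$role)
  line_means <- vapply(by_role, mean, numeric(1))

  fold <- c(
    F1 = fold_vs_mpv_ratio(by_role$F1, by_role$parent1, by_role$parent2),
    F1rec = fold_vs_mpv_ratio(by_role$F1rec, by_role$parent1,
                              by_role$parent2))
  # alternative convention: ratio of MPV areas
  mpv_area_ratio <-
    ((mean(matrix$values[fi, sample_index(matrix, "parent1")]) +
        mean(matrix$values[fi, sample_index(matrix, "parent2")])) / 2) /
    ((mean(matrix$values[mi, sample_index(matrix, "parent1")]) +
        mean(matrix$values[mi, sample_index(matrix, "parent2")])) / 2)
  fold_areas <- c(F1 = unname(line_means["F1"]) / mpv_area_ratio,
                  F1rec = unname(line_means["F1rec"]) / mpv_area_ratio)

  groups <- split(samples$ratio, samples$line_id)
  at <- anova_tukey(groups, alpha = alpha)
  structure(list(samples = samples, line_means = line_means,
                 fold_vs_mpv = fold, fold_vs_mpv_of_areas = fold_areas,
                 anova_p = at$anova_p, letters = at$letters),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat("<ratio_result> fumarate/malate ratio analysis\n")
  cat(sprintf("  line mean ratios: %s\n",
              paste(sprintf("%s=%.3g", names(x$line_means), x$line_means),
                    collapse = ", ")))
  cat(sprintf("  fold vs MPV: F1=%.3g, F1rec=%.3g\n",
              x$fold_vs_mpv["F1"], x$fold_vs_mpv["F1rec"]))
  cat(sprintf("  ANOVA p=%.3g; letters: %s\n", x$anova_p,
              paste(sprintf("%s=%s", names(x$letters), x$letters),
                    collapse = ", ")))
  invisible(x)
}
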