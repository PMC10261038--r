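#' Mid-parent value
#'
#' The mid-parent value (MPV) is the arithmetic mean of the two parental
#' trait means.
#'
#' @param parent1_values,parent2_values Nonempty numeric vectors of
#'   replicate trait values.
#' @return The MPV in trait units.
#' @examples
#' compute_mpv(c(10, 12, 14), c(6, 8, 10)) # 10
#' @export
compute_mpv <- function(parent1_values, parent2_values) {
  stop_if(length(parent1_values) == 0 || length(parent2_values) == 0,
          "parental value vectors must be nonempty")
  (mean(parent1_values) + mean(parent2_values)) / 2
}

#' Better-parent value
#'
#' The better-parent value (BPV) is the trait mean of the better-performing
#' parent in the cross. On an exact tie parent1 is designated better and a
#' tie flag is set.
#'
#' @inheritParams compute_mpv
#' @return List with `bpv`, `better_parent` (`"parent1"` or `"parent2"`),
#'   and `tie` (logical).
#' @export
compute_bpv <- function(parent1_values, parent2_values) {
  stop_if(length(parent1_values) == 0 || length(parent2_values) == 0,
          "parental value vectors must be nonempty")
  m1 <- mean(parent1_values)
  m2 <- mean(parent2_values)
  if (m1 >= m2) {
    list(bpv = m1, better_parent = "parent1", tie = isTRUE(all.equal(m1, m2)))
  } else {
    list(bpv = m2, better_parent = "parent2", tie = FALSE)
  }
}

#' Percent heterosis of a hybrid mean over a reference value
#'
#' Heterosis is expressed as the percentage increase of the F1 trait mean
#' over a reference: the mid-parent value (mid-parent heterosis, MPH) or the
#' better-parent value (better-parent heterosis, BPH).
#'
#' @param f1_mean Hybrid trait mean.
#' @param reference MPV or BPV, > 0.
#' @return Signed percentage `100 * (f1_mean - reference) / reference`.
#' @examples
#' heterosis_percent(13.2, 12) # 10
#' @export
heterosis_percent <- function(f1_mean, reference) {
  stop_if(reference <= 0, "reference must be > 0")
  100 * (f1_mean - reference) / reference
}

#' Test a hybrid against the better parent
#'
#' Two-sample pooled-variance Student's t-test (two-sided) of the hybrid
#' replicates against the better parent's replicates, with direction flags:
#' `significant_above` when p < alpha and the hybrid mean exceeds the better
#' parent's, `significant_below` symmetrically. Degenerate zero-variance
#' inputs follow [student_t2()]'s rules.
#'
#' @param f1_values,better_parent_values Numeric vectors, >= 2 replicates.
#' @param alpha Significance level, default 0.05.
#' @return List with `p`, `significant_above`, `significant_below`,
#'   `degenerate`.
#' @export
test_vs_bpv <- function(f1_values, better_parent_values, alpha = 0.05) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  tt <- student_t2(f1_values, better_parent_values)
  list(p = tt$p,
       significant_above = tt$p < alpha && tt$mean_x > tt$mean_y,
       significant_below = tt$p < alpha && tt$mean_x < tt$mean_y,
       degenerate = tt$degenerate)
}

#' Classify a hybrid combination's heterosis level
#'
#' Applies the four-class rule to the two reciprocal hybrids of a
#' combination, each evaluated against the same better-parent value. The
#' decision tree, in order:
#'
#' 1. `unclassifiable` — the reciprocals show opposite significant trends
#'    (one significantly above the BPV, the other significantly below);
#' 2. `high` — both reciprocals significantly above the BPV and at least
#'    one with BPH >= `bph_threshold` (default 10%);
#' 3. `weak` — at least one reciprocal significantly above, with both BPH
#'    values in `[0, bph_threshold)`;
#' 4. `none` — neither reciprocal significantly above the BPV;
#' 5. `unclassifiable` — any remaining mixed pattern.
#'
#' @param f1,f1rec Lists with elements `bph_pct`, `significant_above`,
#'   `significant_below` for each reciprocal hybrid (as produced by
#'   [evaluate_combination()] internals).
#' @param bph_threshold Percent BPH required of the stronger reciprocal for
#'   the high class, default 10.
#' @return One of `"high"`, `"weak"`, `"none"`, `"unclassifiable"`.
#' @export
classify_combination <- function(f1, f1rec, bph_threshold = 10) {
  need <- c("bph_pct", "significant_above", "significant_below")
  stop_if(!all(need %in% names(f1)) || !all(need %in% names(f1rec)),
          "both reciprocal results need bph_pct and significance flags")
  opposite <- (f1$significant_above && f1rec$significant_below) ||
    (f1$significant_below && f1rec$significant_above)
  if (opposite) return("unclassifiable")
  bph <- c(f1$bph_pct, f1rec$bph_pct)
  sig_above <- c(f1$significant_above, f1rec$significant_above)
  if (all(sig_above) && max(bph) >= bph_threshold) return("high")
  if (any(sig_above) && all(bph >= 0) && all(bph < bph_threshold)) {
    return("weak")
  }
  if (!any(sig_above)) return("none")
  "unclassifiable"
}

#' Evaluate heterosis for one combination's trait table
#'
#' Computes MPV, BPV, per-hybrid means, mid-parent and better-parent
#' heterosis percentages, significance of each reciprocal hybrid against the
#' better parent's replicates, and the four-class label.
#'
#' @param trait_table Tibble with columns `combination_id`, `line_id`,
#'   `role` (`parent1`, `parent2`, `F1`, `F1rec`), `replicate`, `value`;
#'   one combination per call (see [evaluate_population()] for many).
#' @param alpha Significance level for the t-tests, default 0.05.
#' @param bph_threshold Percent BPH for the high class, default 10.
#' @return One-row tibble (a heterosis result): `combination_id`, `mpv`,
#'   `bpv`, `better_parent`, `parent_tie`, then for each reciprocal hybrid
#'   `f1_mean`, `f1_bph_pct`, `f1_mph_pct`, `f1_p`, `f1_sig_above`,
#'   `f1_sig_below` (and the same with prefix `f1rec_`), and `class_label`.
#' @examples
#' tab <- simulate_trait_table(cross_config(seed = 42))
#' evaluate_combination(tab)
#' @export
evaluate_combination <- function(trait_table, alpha = 0.05,
                                 bph_threshold = 10) {
  check_trait_table(trait_table)
  comb <- unique(trait_table$combination_id)
  stop_if(length(comb) != 1,
          "evaluate_combination expects a single combination; got ",
          length(comb))
  vals <- split(trait_table$value, trait_table$role)
  mpv <- compute_mpv(vals$parent1, vals$parent2)
  bp <- compute_bpv(vals$parent1, vals$parent2)
  bp_values <- vals[[bp$better_parent]]

  eval_hybrid <- function(v) {
    tt <- test_vs_bpv(v, bp_values, alpha = alpha)
    list(mean = mean(v),
         bph_pct = heterosis_percent(mean(v), bp$bpv),
         mph_pct = heterosis_percent(mean(v), mpv),
         p = tt$p,
         significant_above = tt$significant_above,
         significant_below = tt$significant_below)
  }
  h1 <- eval_hybrid(vals$F1)
  h2 <- eval_hybrid(vals$F1rec)
  tibble::tibble(
    combination_id = comb, mpv = mpv, bpv = bp$bpv,
    better_parent = bp$better_parent, parent_tie = bp$tie,
    f1_mean = h1$mean, f1_bph_pct = h1$bph_pct, f1_mph_pct = h1$mph_pct,
    f1_p = h1$p, f1_sig_above = h1$significant_above,
    f1_sig_below = h1$significant_below,
    f1rec_mean = h2$mean, f1rec_bph_pct = h2$bph_pct,
    f1rec_mph_pct = h2$mph_pct, f1rec_p = h2$p,
    f1rec_sig_above = h2$significant_above,
    f1rec_sig_below = h2$significant_below,
    class_label = classify_combination(h1, h2,
                                       bph_threshold = bph_threshold))
}

#' Evaluate heterosis for every combination in a trait table
#'
#' @inheritParams evaluate_combination
#' @param trait_table Replicate-level table possibly holding many
#'   combinations.
#' @return Tibble with one heterosis-result row per combination.
#' @export
evaluate_population <- function(trait_table, alpha = 0.05,
                                bph_threshold = 10) {
  check_trait_table(trait_table)
  trait_table |>
    dplyr::group_split(.data$combination_id) |>
    purrr::map_dfr(evaluate_combination, alpha = alpha,
                   bph_threshold = bph_threshold)
}

#' Summarize heterosis classes over a population of combinations
#'
#' Counts combinations per class, their share of the population, and the
#' range of the stronger reciprocal's BPH within each class.
#'
#' @param results Tibble of heterosis results from [evaluate_population()].
#' @return Tibble with columns `class_label`, `n`, `pct_of_total`,
#'   `bph_min`, `bph_max` (the BPH range is `NA` for empty classes). All
#'   four classes always appear.
#' @export
summarize_population <- function(results) {
  stop_if(nrow(results) == 0, "no combinations to summarize")
  classes <- c("high", "weak", "none", "unclassifiable")
  results |>
    dplyr::mutate(max_bph = pmax(.data$f1_bph_pct, .data$f1rec_bph_pct),
                  class_label = factor(.data$class_label, levels = classes)) |>
    dplyr::group_by(.data$class_label, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      bph_min = if (dplyr::n() > 0) min(.data$max_bph) else NA_real_,
      bph_max = if (dplyr::n() > 0) max(.data$max_bph) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(pct_of_total = 100 * .data$n / sum(.data$n)) |>
    dplyr::select("class_label", "n", "pct_of_total", "bph_min", "bph_max")
}

check_trait_table <- function(tab) {
  need <- c("combination_id", "line_id", "role", "replicate", "value")
  stop_if(!all(need %in% names(tab)),
          "trait table needs columns: ", paste(need, collapse = ", "))
  stop_if(any(tab$value <= 0), "trait values must be > 0")
  roles <- c("parent1", "parent2", "F1", "F1rec")
  by_comb <- split(tab$role, tab$combination_id)
  bad <- names(by_comb)[!vapply(by_comb, function(r) all(roles %in% r),
                                logical(1))]
  stop_if(length(bad) > 0,
          "combination(s) missing one of parent1/parent2/F1/F1rec: ",
          paste(bad, collapse = ", "))
  counts <- tab |>
    dplyr::count(.data$combination_id, .data$role)
  stop_if(any(counts$n < 2), "every role needs >= 2 replicates")
  invisible(tab)
}
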