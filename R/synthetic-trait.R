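#' Configuration for a simulated reciprocal-cross trait experiment
#'
#' Describes one hybrid combination: two parental accessions with known trait
#' means (e.g., mg fresh weight at 15 days after sowing) and the two
#' reciprocal F1 hybrids, whose population means are placed at a chosen
#' percentage above (or below) the better-parent value (BPV). Replicate noise
#' is Normal with a fixed coefficient of variation, truncated at zero.
#'
#' @param parent1_id,parent2_id Accession identifiers.
#' @param parent_means Length-2 positive numeric: trait means of parent1 and
#'   parent2 in trait units (mg fresh weight by default scale).
#' @param heterosis_bph_pct Length-2 signed percentages: target
#'   better-parent heterosis of the F1 (parent1 x parent2) and the
#'   reciprocal F1 (parent2 x parent1). `c(30, 30)` is the default
#'   high-heterosis condition used throughout the package's recovery checks;
#'   it sits inside the 6.1--44% range typical of strongly heterotic
#'   Arabidopsis biomass crosses.
#' @param cv Coefficient of variation of replicate noise (fraction, >= 0).
#' @param n_reps Replicates (individual plants) per line, >= 2.
#' @param seed Integer random seed; identical seed and configuration give
#'   byte-identical output.
#' @param combination_id Label for the combination; default
#'   `"parent1_id x parent2_id"`.
#' @return A list of class `cross_config`.
#' @examples
#' cfg <- cross_config(parent_means = c(100, 80), heterosis_bph_pct = c(30, 30))
#' simulate_trait_table(cfg)
#' @export
cross_config <- function(parent1_id = "P1", parent2_id = "P2",
                         parent_means = c(100, 80),
                         heterosis_bph_pct = c(30, 30),
                         cv = 0.05, n_reps = 6, seed = 1,
                         combination_id = NULL) {
  stop_if(length(parent_means) != 2 || any(parent_means <= 0),
          "parent_means must be 2 positive values")
  stop_if(length(heterosis_bph_pct) != 2,
          "heterosis_bph_pct must have one value per reciprocal hybrid")
  stop_if(cv < 0, "cv must be >= 0")
  stop_if(n_reps < 2, "n_reps must be >= 2")
  structure(
    list(parent1_id = parent1_id, parent2_id = parent2_id,
         parent_means = as.numeric(parent_means),
         heterosis_bph_pct = as.numeric(heterosis_bph_pct),
         cv = cv, n_reps = as.integer(n_reps), seed = as.integer(seed),
         combination_id = combination_id %||%
           paste(parent1_id, "x", parent2_id)),
    class = "cross_config")
}

#' Simulate a replicate-level trait table for one reciprocal cross
#'
#' Generates `n_reps` replicate trait values for each of the four lines of a
#' combination: parent1, parent2, the F1 (parent1 x parent2, maternal parent
#' first) and the reciprocal F1 (parent2 x parent1). F1 population means are
#' `BPV * (1 + heterosis_bph_pct / 100)`, so the generator's ground-truth
#' heterosis class is known by construction.
#'
#' @param config A [cross_config()].
#' @return A tibble (class `trait_table`) with columns `combination_id`,
#'   `line_id`, `role` (`parent1`, `parent2`, `F1`, `F1rec`), `replicate`,
#'   `value`, carrying the ground-truth configuration as attribute
#'   `"ground_truth"`.
#' @seealso [evaluate_combination()], [classify_combination()]
#' @export
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  bpv <- max(config$parent_means)
  means <- c(parent1 = config$parent_means[1],
             parent2 = config$parent_means[2],
             F1      = bpv * (1 + config$heterosis_bph_pct[1] / 100),
             F1rec   = bpv * (1 + config$heterosis_bph_pct[2] / 100))
  line_ids <- c(parent1 = config$parent1_id,
                parent2 = config$parent2_id,
                F1      = paste(config$parent1_id, "x", config$parent2_id),
                F1rec   = paste(config$parent2_id, "x", config$parent1_id))
  tab <- withr::with_seed(config$seed, {
    purrr::map_dfr(names(means), function(r) {
      vals <- rnorm_trunc_pos(config$n_reps, means[[r]], config$cv)
      tibble::tibble(
        combination_id = config$combination_id,
        line_id = unname(line_ids[r]),
        role = r,
        replicate = seq_len(config$n_reps),
        value = vals)
    })
  })
  attr(tab, "ground_truth") <- list(
    true_means = means,
    true_bph_pct = config$heterosis_bph_pct,
    true_class = true_class_of(config$heterosis_bph_pct))
  class(tab) <- c("trait_table", class(tab))
  tab
}

# Ground-truth label implied by the injected effect sizes (noise-free limit).
true_class_of <- function(bph) {
  if (all(bph > 0) && max(bph) >= 10) return("high")
  if (any(bph > 0) && all(bph >= 0) && all(bph < 10)) return("weak")
  if (all(bph <= 0)) return("none")
  "unclassifiable"
}
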