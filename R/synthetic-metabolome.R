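#' Configuration for a simulated GC-TOF-MS metabolite experiment
#'
#' Describes one reciprocal-cross metabolite profiling experiment: a
#' peak-area matrix over the four lines of a combination (two parents and
#' the two reciprocal F1 hybrids) with a designated set of annotated peaks,
#' spiked stable-isotope internal standards, line-specific multiplicative
#' effects on chosen metabolites, lognormal biological noise, and a
#' per-sample multiplicative technical scale factor shared by every peak of
#' that sample (what internal-standard normalization is meant to remove).
#'
#' The defaults emulate the dimensions of a typical Arabidopsis leaf
#' profiling experiment — 188 detected peaks of which 103 are known
#' metabolites, 10 internal standards, 4 lines x 6 replicates = 24 samples —
#' and a high-heterosis metabolic signature: TCA cycle intermediates
#' (citrate, cis-aconitate, isocitrate, 2-oxoglutarate) depressed to 0.7x in
#' both hybrids, and fumarate elevated 2.2x in the F1 and 1.9x in the
#' reciprocal F1 with malate unchanged, so the ground-truth fumarate/malate
#' ratio fold versus the mid-parent value is 2.2 and 1.9.
#'
#' @param n_peaks Total detected peaks (rows), including internal standards.
#' @param n_known Annotated (known-metabolite) peaks among the non-IS rows.
#' @param n_is Internal-standard peaks.
#' @param n_reps Samples per line.
#' @param noise_sd_log2 SD of biological replicate noise on the log2 scale.
#' @param tech_sdlog SD (natural-log scale) of the per-sample technical
#'   scale factor; factors are renormalized to unit geometric mean so that
#'   internal-standard normalization can recover the noise-free matrix
#'   exactly.
#' @param line_effects Named list `role -> named numeric vector` of
#'   multiplicative effects, keyed by peak annotation. Roles are `parent1`,
#'   `parent2`, `F1`, `F1rec`; absent entries mean no effect (1x).
#' @param parent1_id,parent2_id Accession labels used to build line names.
#' @param seed Integer random seed.
#' @return A list of class `metabolome_config`.
#' @export
metabolome_config <- function(n_peaks = 188, n_known = 103, n_is = 10,
                              n_reps = 6, noise_sd_log2 = 0.1,
                              tech_sdlog = 0.1,
                              line_effects = list(
                                F1 = c(fumarate = 2.2, citrate = 0.7,
                                       `cis-aconitate` = 0.7,
                                       isocitrate = 0.7,
                                       `2-oxoglutarate` = 0.7),
                                F1rec = c(fumarate = 1.9, citrate = 0.7,
                                          `cis-aconitate` = 0.7,
                                          isocitrate = 0.7,
                                          `2-oxoglutarate` = 0.7)),
                              parent1_id = "Col", parent2_id = "C24",
                              seed = 1) {
  stop_if(n_is >= n_peaks, "n_is must be < n_peaks")
  stop_if(n_known > n_peaks - n_is,
          "n_known cannot exceed the number of non-IS peaks")
  stop_if(n_reps < 2, "n_reps must be >= 2")
  stop_if(noise_sd_log2 < 0 || tech_sdlog < 0, "noise scales must be >= 0")
  for (eff in line_effects) {
    stop_if(any(eff <= 0), "all multiplicative effects must be > 0")
  }
  bad <- setdiff(names(line_effects),
                 c("parent1", "parent2", "F1", "F1rec"))
  stop_if(length(bad) > 0,
          "unknown roles in line_effects: ", paste(bad, collapse = ", "))
  structure(
    list(n_peaks = as.integer(n_peaks), n_known = as.integer(n_known),
         n_is = as.integer(n_is), n_reps = as.integer(n_reps),
         noise_sd_log2 = noise_sd_log2, tech_sdlog = tech_sdlog,
         line_effects = line_effects,
         parent1_id = parent1_id, parent2_id = parent2_id,
         seed = as.integer(seed)),
    class = "metabolome_config")
}

# Annotation table implied by a config: known metabolites first (the TCA
# compounds and other named metabolites up front so default effects land on
# real rows), then unknown peaks, then the IS rows.
peak_annotations <- function(config) {
  named <- c("fumarate", "malate", "citrate", "cis-aconitate", "isocitrate",
             "2-oxoglutarate", "succinate", "sucrose", "glucose", "fructose",
             "maltose", "raffinose", "ribose", "glutamine", "glutamate",
             "phenylalanine", "alanine", "serine", "glycine", "proline")
  n_named <- min(length(named), config$n_known)
  known <- c(named[seq_len(n_named)],
             if (config$n_known > n_named)
               sprintf("metabolite_%03d", seq_len(config$n_known - n_named)))
  n_unknown <- config$n_peaks - config$n_is - config$n_known
  tibble::tibble(
    peak_id = sprintf("peak_%03d", seq_len(config$n_peaks)),
    annotation = c(known, rep("unknown", n_unknown),
                   sprintf("IS_%02d", seq_len(config$n_is))),
    is_internal_standard = c(rep(FALSE, config$n_peaks - config$n_is),
                             rep(TRUE, config$n_is)))
}

#' Simulate a metabolite peak-area matrix with known ground truth
#'
#' Draws a peaks x samples matrix of positive peak areas for the four lines
#' of a reciprocal cross. Each non-IS peak has a lognormal base abundance,
#' multiplied by any line-specific effect, by lognormal biological noise
#' (`noise_sd_log2` on the log2 scale), and by the sample's technical scale
#' factor. Internal-standard rows carry only the spiked base level times the
#' technical factor, so [is_normalize()] can identify and remove it. The
#' technical factors have unit geometric mean by construction, making the
#' removal exact.
#'
#' @param config A [metabolome_config()].
#' @return A list with elements:
#'   * `matrix`: a [metabolite_matrix()] (linear scale, not normalized);
#'   * `ground_truth`: list with `effects` (tibble role/annotation/
#'     multiplier), `ratio_fold_vs_mpv` (named vector, true fumarate/malate
#'     fold vs MPV per hybrid, when both peaks exist), `tech_factors`
#'     (named per-sample scale factors), and `noise_free` (the matrix
#'     without noise and technical factors).
#' @examples
#' sim <- simulate_metabolome(metabolome_config(seed = 7))
#' dim(sim$matrix)
#' @export
simulate_metabolome <- function(config) {
  stopifnot(inherits(config, "metabolome_config"))
  peaks <- peak_annotations(config)
  roles <- c("parent1", "parent2", "F1", "F1rec")
  line_ids <- c(parent1 = config$parent1_id,
                parent2 = config$parent2_id,
                F1 = paste(config$parent1_id, "x", config$parent2_id),
                F1rec = paste(config$parent2_id, "x", config$parent1_id))
  samples <- tidyr::expand_grid(role = roles,
                                replicate = seq_len(config$n_reps))
  samples$line_id <- unname(line_ids[samples$role])
  samples$sample_id <- paste(samples$line_id, samples$replicate, sep = ".")
  samples <- samples[, c("sample_id", "line_id", "role", "replicate")]
  n_s <- nrow(samples)
  is_row <- peaks$is_internal_standard

  # per-role multiplier matrix (peaks x roles), default 1
  mult <- matrix(1, nrow = config$n_peaks, ncol = length(roles),
                 dimnames = list(peaks$peak_id, roles))
  for (role in names(config$line_effects)) {
    eff <- config$line_effects[[role]]
    hit <- match(names(eff), peaks$annotation)
    stop_if(anyNA(hit), "line_effects name not among peak annotations: ",
            paste(names(eff)[is.na(hit)], collapse = ", "))
    mult[hit, role] <- eff
  }

  out <- withr::with_seed(config$seed, {
    base <- stats::rlnorm(config$n_peaks, meanlog = log(1e5), sdlog = 1)
    base[is_row] <- stats::rlnorm(config$n_is, meanlog = log(5e4),
                                  sdlog = 0.3)
    s <- stats::rlnorm(n_s, meanlog = 0, sdlog = config$tech_sdlog)
    s <- s / geomean(s) # unit geometric mean: IS normalization is exact
    noise <- matrix(2^stats::rnorm(config$n_peaks * n_s, 0,
                                   config$noise_sd_log2),
                    nrow = config$n_peaks)
    noise[is_row, ] <- 1 # IS rows carry technical variation only
    list(base = base, s = s, noise = noise)
  })

  noise_free <- out$base * mult[, samples$role, drop = FALSE]
  values <- noise_free * out$noise *
    matrix(out$s, nrow = config$n_peaks, ncol = n_s, byrow = TRUE)
  dimnames(noise_free) <- list(peaks$peak_id, samples$sample_id)

  effects <- purrr::imap_dfr(config$line_effects, function(eff, role) {
    tibble::tibble(role = role, annotation = names(eff),
                   multiplier = unname(eff))
  })
  ratio_fold <- true_ratio_fold(mult, peaks)
  mat <- metabolite_matrix(values, peaks, samples)
  list(matrix = mat,
       ground_truth = list(
         effects = effects,
         ratio_fold_vs_mpv = ratio_fold,
         tech_factors = stats::setNames(out$s, samples$sample_id),
         noise_free = noise_free))
}

# True fumarate/malate ratio fold vs MPV implied by the injected effects.
# Parental ratio folds are (by construction) their own effect ratios; the
# MPV ratio averages the two parental mean ratios.
true_ratio_fold <- function(mult, peaks) {
  fi <- match("fumarate", peaks$annotation)
  mi <- match("malate", peaks$annotation)
  if (is.na(fi) || is.na(mi)) return(NULL)
  base_ratio <- 1 # base abundances cancel in the fold
  r <- function(role) base_ratio * mult[fi, role] / mult[mi, role]
  mpv <- (r("parent1") + r("parent2")) / 2
  c(F1 = r("F1") / mpv, F1rec = r("F1rec") / mpv)
}
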