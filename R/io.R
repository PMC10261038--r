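# Readers, writers and the end-to-end pipeline. All files are plain tidy
# CSV (UTF-8, comma separator, header row, "." decimal, missing values as
# empty fields) so every output round-trips through its reader.

#' Read / write a replicate-level trait table
#'
#' @param path CSV with columns `combination_id`, `line_id`, `role`,
#'   `replicate`, `value`; every combination must carry all four roles
#'   (`parent1`, `parent2`, `F1`, `F1rec`).
#' @return A validated trait tibble.
#' @export
read_trait_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  check_trait_table(tab)
  tab
}

#' @rdname read_trait_table
#' @param table Trait tibble to write.
#' @export
write_trait_table <- function(table, path) {
  check_trait_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Read / write germination courses
#'
#' @param path CSV with columns `line_id`, `time_has`, `fraction`.
#' @return Tibble of courses (possibly several lines).
#' @export
read_germination <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stop_if(!all(c("line_id", "time_has", "fraction") %in% names(tab)),
          "germination file needs line_id, time_has, fraction")
  tab
}

#' @rdname read_germination
#' @param courses Tibble of courses to write.
#' @export
write_germination <- function(courses, path) {
  readr::write_csv(courses, path)
  invisible(path)
}

#' Read / write a metabolite matrix as a pair of CSV files
#'
#' The matrix file has peaks as rows with leading columns `peak_id`,
#' `annotation`, `is_internal_standard`, then one column per sample; the
#' companion samples file carries the column metadata (`sample_id`,
#' `line_id`, `role`, `replicate`).
#'
#' @param matrix_path Path to the peaks x samples CSV.
#' @param samples_path Path to the sample-metadata CSV.
#' @param log2,normalized Scale flags of the stored matrix.
#' @return A [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(matrix_path, samples_path,
                                   log2 = FALSE, normalized = FALSE) {
  wide <- readr::read_csv(matrix_path, show_col_types = FALSE)
  meta_cols <- c("peak_id", "annotation", "is_internal_standard")
  stop_if(!all(meta_cols %in% names(wide)),
          "matrix file needs columns ", paste(meta_cols, collapse = ", "))
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  value_cols <- setdiff(names(wide), meta_cols)
  stop_if(!setequal(value_cols, samples$sample_id),
          "matrix columns and sample metadata disagree")
  values <- as.matrix(wide[, samples$sample_id])
  metabolite_matrix(values, wide[, meta_cols], samples,
                    log2 = log2, normalized = normalized)
}

#' @rdname read_metabolite_matrix
#' @param matrix A [metabolite_matrix()] to write.
#' @export
write_metabolite_matrix <- function(matrix, matrix_path, samples_path) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  wide <- dplyr::bind_cols(matrix$peaks,
                           tibble::as_tibble(matrix$values))
  readr::write_csv(wide, matrix_path)
  readr::write_csv(matrix$samples, samples_path)
  invisible(matrix_path)
}

#' Pipeline configuration
#'
#' Collects the thresholds of the full analysis — seed-screen alpha 0.01,
#' heterosis alpha 0.05, FDR threshold 0.05, Tukey alpha 0.05, BPH
#' threshold 10% — plus imputation mode, PCA scaling and the random seed
#' used when inputs are simulated rather than read from files. Can be
#' written to and read from YAML.
#'
#' @param trait_csv,germination_csv,matrix_csv,samples_csv Optional input
#'   paths; any `NULL` input is simulated from the package's generators
#'   under `seed`.
#' @param seed_screen_alpha,heterosis_alpha,fdr_threshold,tukey_alpha
#'   Significance levels, each in (0, 1).
#' @param bph_threshold Percent BPH for the high class, >= 0.
#' @param impute `"halfmin"` or `"offset"`.
#' @param pca_scaling `"center"` or `"autoscale"`.
#' @param seed Integer seed for simulated inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(trait_csv = NULL, germination_csv = NULL,
                            matrix_csv = NULL, samples_csv = NULL,
                            seed_screen_alpha = 0.01,
                            heterosis_alpha = 0.05,
                            fdr_threshold = 0.05, tukey_alpha = 0.05,
                            bph_threshold = 10,
                            impute = "halfmin", pca_scaling = "center",
                            seed = 1) {
  alphas <- c(seed_screen_alpha, heterosis_alpha, fdr_threshold,
              tukey_alpha)
  stop_if(any(alphas <= 0 | alphas >= 1), "all alphas must be in (0, 1)")
  stop_if(bph_threshold < 0, "bph_threshold must be >= 0")
  stop_if(!impute %in% c("halfmin", "offset"), "unknown impute mode")
  stop_if(!pca_scaling %in% c("center", "autoscale"),
          "unknown pca_scaling")
  structure(list(trait_csv = trait_csv, germination_csv = germination_csv,
                 matrix_csv = matrix_csv, samples_csv = samples_csv,
                 seed_screen_alpha = seed_screen_alpha,
                 heterosis_alpha = heterosis_alpha,
                 fdr_threshold = fdr_threshold, tukey_alpha = tukey_alpha,
                 bph_threshold = bph_threshold, impute = impute,
                 pca_scaling = pca_scaling, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file to read or write.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  stop_if(length(bad) > 0,
          "unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(purrr::compact(unclass(config)), path)
  invisible(path)
}

#' Run the full heterosis + metabolomics pipeline
#'
#' Chains the analysis end to end: germination t50 and sowing plan,
#' heterosis classification of the trait table, internal-standard
#' normalization and log2 preprocessing of the metabolite matrix,
#' differential tables for both reciprocal hybrids, fumarate/malate ratio
#' analysis, and PCA. Inputs not given as files are simulated with the
#' package generators under `config$seed`, so a default run is fully
#' self-contained and reproducible: rerunning with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Directory for stage outputs and the run manifest
#'   (`manifest.json`: package version, configuration, seed, stage files).
#' @return Invisibly, a list with `t50`, `sowing_plan`, `heterosis`,
#'   `differential` (list for `F1`, `F1rec`), `ratio`, `pca`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tab, path)
    outputs <<- c(outputs, name)
    path
  }

  # --- inputs: read or simulate -------------------------------------------
  trait <- if (is.null(config$trait_csv)) {
    simulate_trait_table(cross_config(seed = config$seed))
  } else read_trait_table(config$trait_csv)

  germ <- if (is.null(config$germination_csv)) {
    dplyr::bind_rows(
      simulate_germination(50, 0.5, line_id = "parent1"),
      simulate_germination(58, 0.5, line_id = "parent2"),
      simulate_germination(54, 0.5, line_id = "F1"),
      simulate_germination(54, 0.5, line_id = "F1rec"))
  } else read_germination(config$germination_csv)

  metab <- if (is.null(config$matrix_csv)) {
    simulate_metabolome(metabolome_config(seed = config$seed))$matrix
  } else {
    read_metabolite_matrix(config$matrix_csv, config$samples_csv)
  }

  # --- germination synchronization ----------------------------------------
  t50s <- germ |>
    dplyr::group_split(.data$line_id) |>
    purrr::map_dfr(function(course) {
      est <- estimate_t50(course)
      tibble::tibble(line_id = course$line_id[1], t50 = est$t50,
                     status = est$status, method = est$method)
    })
  emit(t50s, "t50.csv")
  germinated <- t50s[t50s$status == "ok", ]
  plan <- tibble::tibble(
    line_id = germinated$line_id,
    sowing_offset_h = sowing_offsets(
      stats::setNames(germinated$t50, germinated$line_id)))
  emit(plan, "sowing_plan.csv")

  # --- heterosis classification -------------------------------------------
  het <- evaluate_population(trait, alpha = config$heterosis_alpha,
                             bph_threshold = config$bph_threshold)
  emit(het, "heterosis.csv")

  # --- metabolome ----------------------------------------------------------
  norm <- is_normalize(metab)
  logm <- impute_and_log2(norm, method = config$impute)
  diffs <- list(F1 = differential_table(logm, "F1",
                                        threshold = config$fdr_threshold),
                F1rec = differential_table(logm, "F1rec",
                                           threshold = config$fdr_threshold))
  emit(diffs$F1, "differential_F1.csv")
  emit(diffs$F1rec, "differential_F1rec.csv")
  emit(heatmap_table(list(F1 = diffs$F1, F1rec = diffs$F1rec)),
       "heatmap.csv")

  ratio <- tca_ratio(norm, alpha = config$tukey_alpha)
  emit(ratio$samples, "tca_ratio_samples.csv")
  emit(tibble::tibble(hybrid = names(ratio$fold_vs_mpv),
                      fold_vs_mpv = unname(ratio$fold_vs_mpv),
                      fold_vs_mpv_of_areas =
                        unname(ratio$fold_vs_mpv_of_areas)),
       "tca_ratio_folds.csv")

  pca <- run_pca(logm, scaling = config$pca_scaling)
  emit(tibble::as_tibble(pca$scores, rownames = "sample_id"), "pca_scores.csv")
  emit(tibble::as_tibble(pca$loadings, rownames = "peak_id"),
       "pca_loadings.csv")
  emit(tibble::tibble(component = seq_along(pca$explained_pct),
                      explained_pct = pca$explained_pct),
       "pca_explained.csv")

  manifest <- list(
    package = "vigormet",
    version = as.character(utils::packageVersion("vigormet")),
    seed = config$seed,
    config = purrr::compact(unclass(config)),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(t50 = t50s, sowing_plan = plan, heterosis = het,
                 differential = diffs, ratio = ratio, pca = pca,
                 manifest = manifest))
}
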