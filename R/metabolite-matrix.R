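#' Construct a metabolite peak-area matrix with metadata
#'
#' Container for a GC-TOF-MS style peak-area matrix: peaks as rows, samples
#' as columns, with peak annotations, internal-standard flags, and sample
#' metadata (line and replicate). All downstream stages (normalization,
#' log2 transform, differential tests, ratio analysis, PCA) operate on this
#' class.
#'
#' @param values Numeric matrix, peaks x samples, areas >= 0 or `NA`
#'   (missing). Row and column names are taken from `peaks$peak_id` and
#'   `samples$sample_id`.
#' @param peaks Tibble with columns `peak_id`, `annotation` (metabolite name
#'   or `"unknown"`), `is_internal_standard` (logical).
#' @param samples Tibble with columns `sample_id`, `line_id`, `role`,
#'   `replicate`.
#' @param log2 Is the matrix on the log2 scale?
#' @param normalized Has internal-standard normalization been applied (the
#'   IS rows are then flagged consumed and [is_normalize()] is a no-op)?
#' @return An object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, peaks, samples,
                              log2 = FALSE, normalized = FALSE) {
  values <- as.matrix(values)
  stop_if(nrow(values) != nrow(peaks),
          "values must have one row per peak")
  stop_if(ncol(values) != nrow(samples),
          "values must have one column per sample")
  stop_if(!all(c("peak_id", "annotation", "is_internal_standard") %in%
                 names(peaks)),
          "peaks needs columns peak_id, annotation, is_internal_standard")
  stop_if(!all(c("sample_id", "line_id", "role", "replicate") %in%
                 names(samples)),
          "samples needs columns sample_id, line_id, role, replicate")
  stop_if(anyDuplicated(peaks$peak_id) > 0, "duplicated peak_id")
  stop_if(anyDuplicated(samples$sample_id) > 0, "duplicated sample_id")
  if (!log2) {
    stop_if(any(values < 0, na.rm = TRUE), "negative peak areas")
  }
  dimnames(values) <- list(peaks$peak_id, samples$sample_id)
  structure(list(values = values,
                 peaks = tibble::as_tibble(peaks),
                 samples = tibble::as_tibble(samples),
                 log2 = log2, normalized = normalized),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf(
    "<metabolite_matrix> %d peaks x %d samples (%d internal standards)\n",
    nrow(x$values), ncol(x$values), sum(x$peaks$is_internal_standard)))
  cat(sprintf("  lines: %s\n",
              paste(unique(x$samples$line_id), collapse = ", ")))
  cat(sprintf("  scale: %s, IS-normalized: %s\n",
              if (x$log2) "log2" else "linear", x$normalized))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)

#' Count detected and annotated peaks
#'
#' Tallies the number of detected peaks and the number carrying a metabolite
#' annotation. Internal-standard peaks are spiked compounds, not detected
#' metabolites, so they are excluded from the annotated count.
#'
#' @param matrix A [metabolite_matrix()].
#' @return A list with `n_peaks` (total rows) and `n_known` (non-IS peaks
#'   whose annotation is not `"unknown"`).
#' @examples
#' m <- simulate_metabolome(metabolome_config())
#' count_annotated(m$matrix) # 188 peaks, 103 known
#' @export
count_annotated <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  known <- !matrix$peaks$is_internal_standard &
    matrix$peaks$annotation != "unknown"
  list(n_peaks = nrow(matrix$peaks), n_known = sum(known))
}

# Linear-scale values for a set of samples, back-transforming if needed.
linear_values <- function(matrix) {
  if (matrix$log2) 2^matrix$values else matrix$values
}

# Column indices of the samples belonging to one line (by line_id or role).
sample_index <- function(matrix, line) {
  idx <- which(matrix$samples$line_id == line | matrix$samples$role == line)
  stop_if(length(idx) == 0, "no samples for line '", line, "'")
  idx
}
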