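#' Estimate germination time (t50) from a cumulative course
#'
#' The germination time of a line is the time at which 50% of its seeds show
#' fully opened cotyledons. The estimate is the linearly interpolated time at
#' which the cumulative curve first crosses 0.5; if the first observation is
#' already at or above 0.5 the first observation time is returned. Scoring
#' schedules are typically coarse (12-hour, densified to 4-hour around the
#' expected crossing), so interpolation resolves t50 within one observation
#' interval; the method used is recorded in the result.
#'
#' @param course A tibble with columns `time_has` (strictly increasing hours
#'   after sowing) and `fraction` (cumulative fraction in `[0, 1]`,
#'   nondecreasing), e.g. from [simulate_germination()].
#' @return A list with `t50` (hours, or `NA` if the curve never reaches
#'   0.5), `status` (`"ok"` or `"not_germinated"`), and `method`
#'   (`"interpolation"`, `"first_observation"`, or `NA`).
#' @examples
#' estimate_t50(tibble::tibble(time_has = c(48, 52), fraction = c(0.2, 0.6)))
#' @export
estimate_t50 <- function(course) {
  stop_if(!all(c("time_has", "fraction") %in% names(course)),
          "course needs columns time_has and fraction")
  t <- course$time_has
  f <- course$fraction
  stop_if(length(t) != length(f) || length(t) == 0, "malformed course")
  stop_if(any(diff(t) <= 0), "time_has must be strictly increasing")
  stop_if(any(f < 0 | f > 1), "fractions must lie in [0, 1]")
  stop_if(any(diff(f) < -1e-12), "fractions must be nondecreasing")
  if (all(f < 0.5)) {
    return(list(t50 = NA_real_, status = "not_germinated", method = NA_character_))
  }
  i <- which(f >= 0.5)[1]
  if (i == 1) {
    return(list(t50 = t[1], status = "ok", method = "first_observation"))
  }
  # first crossing wins; exact 0.5 at an observation needs no interpolation
  t50 <- t[i - 1] + (t[i] - t[i - 1]) * (0.5 - f[i - 1]) / (f[i] - f[i - 1])
  list(t50 = t50, status = "ok", method = "interpolation")
}

#' Sowing offsets that synchronize germination across lines
#'
#' Lines germinate at different times; sowing each line later by
#' `max(t50) - t50(line)` hours aligns their expected germination instants,
#' so parents and hybrids reach the same developmental stage together. The
#' slowest-germinating line gets offset 0.
#'
#' @param t50_by_line Named numeric vector of t50 values (hours) per line.
#'   Any `NA` (a line that never germinated) is an error naming the line;
#'   exclude such lines upstream.
#' @return Named numeric vector of nonnegative sowing offsets (hours), in
#'   the input order, containing at least one zero.
#' @examples
#' sowing_offsets(c(A = 48, B = 54, C = 60))
#' @export
sowing_offsets <- function(t50_by_line) {
  stop_if(length(t50_by_line) == 0, "no lines given")
  stop_if(is.null(names(t50_by_line)) || any(names(t50_by_line) == ""),
          "t50_by_line must be named by line")
  missing <- names(t50_by_line)[is.na(t50_by_line)]
  stop_if(length(missing) > 0,
          "missing t50 for line(s): ", paste(missing, collapse = ", "))
  max(t50_by_line) - t50_by_line
}

#' Screen accessions by seed area against a control line
#'
#' Maternal effects can inflate hybrid seed size, confounding downstream
#' biomass comparisons. This screen compares each accession's replicate seed
#' areas to a control accession with a two-sample pooled-variance Student's
#' t-test and flags accessions whose seeds are significantly *larger* than
#' the control (two-sided p below `alpha` and accession mean above the
#' control mean); flagged accessions are marked for exclusion.
#'
#' @param table Tibble with columns `accession_id` and `area` (mm^2, > 0),
#'   one row per measured seed or replicate.
#' @param control_id Accession used as the reference.
#' @param alpha Significance level, default 0.01.
#' @return Tibble with one row per non-control accession: `accession_id`,
#'   `n`, `mean_area`, `p`, `larger_than_control`, `exclude`. Accessions
#'   with fewer than 2 replicates are skipped with a warning.
#' @export
seed_area_screen <- function(table, control_id, alpha = 0.01) {
  stop_if(!all(c("accession_id", "area") %in% names(table)),
          "table needs columns accession_id and area")
  stop_if(any(table$area <= 0), "areas must be > 0")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  control <- table$area[table$accession_id == control_id]
  stop_if(length(control) < 2,
          "control accession '", control_id, "' needs >= 2 replicates")
  others <- setdiff(unique(table$accession_id), control_id)
  rows <- purrr::map(others, function(acc) {
    x <- table$area[table$accession_id == acc]
    if (length(x) < 2) {
      warning("accession '", acc, "' has < 2 replicates; skipped",
              call. = FALSE)
      return(NULL)
    }
    tt <- student_t2(x, control)
    larger <- tt$p < alpha && tt$mean_x > tt$mean_y
    tibble::tibble(accession_id = acc, n = length(x),
                   mean_area = tt$mean_x, p = tt$p,
                   larger_than_control = larger, exclude = larger)
  })
  dplyr::bind_rows(rows)
}
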