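#' Simulate a cumulative germination time-course
#'
#' Generates the cumulative fraction of seeds with fully opened cotyledons as
#' a logistic curve `1 / (1 + exp(-slope * (t - t50)))` evaluated at the
#' observation schedule. The default schedule mirrors common practice for
#' Arabidopsis: scoring every 12 hours from sowing (0 HAS) up to 72 HAS,
#' with denser 4-hour scoring between 48 and 60 HAS where cotyledon opening
#' concentrates — 9 unique observation times.
#'
#' @param t50 Hours after sowing at which half of the seeds have fully opened
#'   cotyledons (the germination time).
#' @param slope Logistic steepness per hour, > 0. `Inf` gives a step
#'   function: 0 before `t50`, 1 at and after it.
#' @param obs_times Strictly increasing observation times in HAS.
#' @param line_id Line label carried into the output.
#' @return A tibble (class `germination_course`) with columns `line_id`,
#'   `time_has`, `fraction`. If `t50` falls outside the observation window
#'   the attribute `"t50_in_window"` is `FALSE` and a warning is issued.
#' @examples
#' simulate_germination(t50 = 54, slope = 0.5)
#' @export
simulate_germination <- function(t50, slope,
                                 obs_times = sort(unique(c(
                                   seq(0, 72, by = 12), seq(48, 60, by = 4)))),
                                 line_id = "line") {
  stop_if(slope <= 0, "slope must be > 0")
  stop_if(any(diff(obs_times) <= 0), "obs_times must be strictly increasing")
  if (is.infinite(slope)) {
    frac <- as.numeric(obs_times >= t50)
  } else {
    frac <- 1 / (1 + exp(-slope * (obs_times - t50)))
  }
  in_window <- t50 >= min(obs_times) && t50 <= max(obs_times)
  if (!in_window) {
    warning("t50 (", t50, " HAS) lies outside the observation window [",
            min(obs_times), ", ", max(obs_times), "]", call. = FALSE)
  }
  out <- tibble::tibble(line_id = line_id, time_has = obs_times,
                        fraction = frac)
  attr(out, "t50_in_window") <- in_window
  class(out) <- c("germination_course", class(out))
  out
}
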