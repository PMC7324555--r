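#' Tidy a fitness trajectory
#'
#' Returns the per-replicate W values underlying the per-timepoint summary.
#'
#' @param x A `plasfit_fitness` object from [fitness_trajectory()].
#' @param ... Unused.
#' @return A tibble: `replicate_id`, `time_h`, `w`, `status`.
#' @exportS3Method
tidy.plasfit_fitness <- function(x, ...) {
  attr(x, "per_replicate")
}

#' Summarise a fitness trajectory in one row
#'
#' @inheritParams tidy.plasfit_fitness
#' @return A one-row tibble: `baseline`, `n_timepoints`, `final_time_h`,
#'   `final_mean_w`, `final_sd_w`.
#' @exportS3Method
glance.plasfit_fitness <- function(x, ...) {
  last <- x[which.max(x$time_h), ]
  tibble(baseline = attr(x, "baseline"),
         n_timepoints = nrow(x),
         final_time_h = last$time_h,
         final_mean_w = last$mean_w,
         final_sd_w = last$sd_w)
}

#' @exportS3Method
tidy.plasfit_de <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' Summarise differential-expression calls in one row
#'
#' @param x A `plasfit_de` object from [call_de()].
#' @param ... Unused.
#' @return A one-row tibble: `n_orfs`, `n_up`, `n_down`, `threshold`,
#'   `floor`.
#' @exportS3Method
glance.plasfit_de <- function(x, ...) {
  tibble(n_orfs = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         threshold = attr(x, "threshold"),
         floor = attr(x, "floor"))
}

#' @exportS3Method
tidy.plasfit_enrichment <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' Summarise an enrichment table in one row
#'
#' @param x A `plasfit_enrichment` object from [enrich_table()].
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `alternative`, `correction`,
#'   `n_tested`, `n_significant`.
#' @exportS3Method
glance.plasfit_enrichment <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"),
         alternative = attr(x, "alternative"),
         correction = attr(x, "correction"),
         n_tested = sum(!is.na(x$p_value)),
         n_significant = sum(x$significant, na.rm = TRUE))
}

# strip the plasfit class so dplyr/tibble verbs see a plain tibble
unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("plasfit_fitness", "plasfit_de",
                                  "plasfit_enrichment"))
  x
}
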