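# Heat-tolerance phenotyping. Under a chronic heat-stress ramp, an
# individual's tolerance is the heat it accumulated above the baseline
# (acclimation) temperature before dying, in degree-hours; the most
# susceptible and most resistant k individuals form the case and control
# groups of the association study.

#' Accumulated degree-hours until death
#'
#' Integrates `max(T(t) - baseline, 0)` over `[0, death_time]` under
#' step-function schedule semantics (each breakpoint's temperature holds
#' until the next). By default the last breakpoint's temperature
#' persists past the end of the schedule (`final_hold = TRUE`); with
#' `final_hold = FALSE` a death time beyond the last breakpoint is an
#' error.
#'
#' The baseline defaults to 25 degrees C, a typical acclimation
#' temperature; note that published degree-hour figures rarely state
#' their baseline convention, so comparisons across studies require
#' care.
#'
#' @param schedule Tibble with `time` (hours, strictly increasing from
#'   0) and `temp` (degrees C).
#' @param death_time Hours from stress start; vectorized.
#' @param baseline Baseline temperature subtracted before accumulating.
#' @param final_hold Extend the last temperature beyond the schedule.
#' @return Degree-hours (non-negative), one value per `death_time`.
#' @examples
#' sched <- tibble::tibble(time = c(0, 24), temp = c(26, 26.5))
#' degree_hours(sched, 36)  # 24 * 1 + 12 * 1.5 = 42
#' @export
degree_hours <- function(schedule, death_time, baseline = 25,
                         final_hold = TRUE) {
  validate_schedule(schedule)
  if (any(death_time < 0)) abort("degree_hours: negative death time")
  t_end <- schedule$time[nrow(schedule)]
  if (!final_hold && any(death_time > t_end)) {
    abort(paste0("degree_hours: death time ", max(death_time),
                 " beyond schedule end ", t_end,
                 " (set final_hold = TRUE to extend the last temperature)"))
  }
  starts <- schedule$time
  excess <- pmax(schedule$temp - baseline, 0)
  map_dbl(death_time, function(td) {
    ends <- c(starts[-1], max(td, t_end))
    dur <- pmin(ends, td) - pmin(starts, td)
    sum(excess * dur)
  })
}

#' Attach degree-hours to death-time records
#'
#' Censored individuals (survivors at observation end) are evaluated at
#' their recorded `death_time` (the censoring time) and keep their
#' `censored` flag; they are eligible only for the resistant extreme in
#' [select_extremes()].
#'
#' @param deaths Tibble with `individual_id`, `death_time` and
#'   optionally `censored`.
#' @param schedule Temperature schedule (see [degree_hours()]).
#' @param baseline,final_hold Passed to [degree_hours()].
#' @param observation_times Optional increasing vector of observation
#'   checkpoint times (hours); death times are snapped up to the next
#'   checkpoint, modelling mortality checks at fixed hours of day.
#' @return `deaths` with a `degree_hours` column.
#' @export
add_degree_hours <- function(deaths, schedule, baseline = 25,
                             final_hold = TRUE, observation_times = NULL) {
  stopifnot(all(c("individual_id", "death_time") %in% names(deaths)))
  if (!"censored" %in% names(deaths)) deaths$censored <- FALSE
  td <- deaths$death_time
  if (!is.null(observation_times)) {
    ot <- sort(observation_times)
    idx <- findInterval(td, ot, left.open = TRUE) + 1L
    if (any(idx > length(ot))) {
      abort("add_degree_hours: death time beyond the last observation checkpoint")
    }
    td <- ot[idx]
  }
  deaths$degree_hours <- degree_hours(schedule, td, baseline, final_hold)
  deaths
}

#' Select extreme-phenotype groups
#'
#' Ranks individuals by `degree_hours` ascending (ties broken by
#' `individual_id`, lexicographically) and takes the `k` smallest as the
#' heat-susceptible group and the `k` largest as the heat-resistant
#' group. Censored survivors are never susceptible; both groups are
#' disjoint whenever `2k <= n`.
#'
#' @param pheno Tibble with `individual_id`, `degree_hours` and
#'   optionally `censored`.
#' @param k Group size (default 48).
#' @return A list with tibbles `susceptible` and `resistant`.
#' @export
select_extremes <- function(pheno, k = heat_config()$phenotype$k_extremes) {
  stopifnot(all(c("individual_id", "degree_hours") %in% names(pheno)))
  if (!"censored" %in% names(pheno)) pheno$censored <- FALSE
  n <- nrow(pheno)
  if (2 * k > n) {
    abort(paste0("select_extremes: 2k = ", 2 * k, " exceeds n = ", n))
  }
  if (k == 0) {
    return(list(susceptible = pheno[0, ], resistant = pheno[0, ]))
  }
  ranked <- arrange(pheno, .data$degree_hours, .data$individual_id)
  resistant <- ranked[(n - k + 1):n, ]
  eligible <- filter(ranked, !.data$censored)
  if (nrow(eligible) < k) {
    abort("select_extremes: fewer than k uncensored individuals")
  }
  susceptible <- eligible[1:k, ]
  if (length(intersect(susceptible$individual_id,
                       resistant$individual_id)) > 0) {
    abort("select_extremes: extremes overlap (heavy censoring); reduce k")
  }
  list(susceptible = susceptible, resistant = resistant)
}

#' Compare population heat tolerance (convenience wrapper)
#'
#' Thin wrapper around a one-way ANOVA of degree-hours on population,
#' for the routine "are the populations' mean tolerances different"
#' question.
#'
#' @param pheno Tibble with `degree_hours` and `population` columns.
#' @return A tibble with the ANOVA table (term, df, sumsq, meansq,
#'   statistic, p_value).
#' @export
compare_populations <- function(pheno) {
  stopifnot(all(c("degree_hours", "population") %in% names(pheno)))
  fit <- aov(degree_hours ~ population,
             data = transform(pheno, population = factor(population)))
  tab <- summary(fit)[[1]]
  tibble(
    term = trimws(rownames(tab)),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
}

#' Histogram of the degree-hour phenotype
#'
#' @param pheno Tibble with `degree_hours`; if `extremes` (a
#'   [select_extremes()] result) is given, group membership is coloured.
#' @param extremes Optional extremes list.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_degree_hours <- function(pheno, extremes = NULL, bins = 30) {
  df <- pheno
  df$group <- "middle"
  if (!is.null(extremes)) {
    df$group[df$individual_id %in% extremes$susceptible$individual_id] <-
      "susceptible"
    df$group[df$individual_id %in% extremes$resistant$individual_id] <-
      "resistant"
  }
  ggplot(df, aes(x = .data$degree_hours, fill = .data$group)) +
    geom_histogram(bins = bins, colour = "grey30", linewidth = 0.2) +
    labs(x = "accumulated heat stress (degree-hours)", y = "individuals",
         fill = NULL) +
    theme_minimal()
}
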