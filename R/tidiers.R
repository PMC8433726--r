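# broom-style tidiers for the package's result objects

#' Tidy a phenotype summary
#'
#' @param x A [summarize_phenotype()] result.
#' @param ... Unused.
#' @return A plain tibble with per-type `mean_uF` and `sem_uF` added.
#' @exportS3Method generics::tidy
tidy.phenotype_summary <- function(x, ...) {
  out <- as_tibble(x)
  mutate(out,
    mean_uF = farads_to_uF(.data$mean_F),
    sem_uF = farads_to_uF(.data$sem_F)
  )
}

#' @rdname tidy.phenotype_summary
#' @exportS3Method generics::glance
glance.phenotype_summary <- function(x, ...) {
  tibble(
    n_types = nrow(x),
    top_type = x$cell_type[x$rank == 1],
    ordering = paste(x$cell_type[order(x$rank)], collapse = " > "),
    k_lowest = x$n_used[1]
  )
}

#' Tidy a size classification
#'
#' @param x A [classify_by_size_order()] result.
#' @param ... Unused.
#' @return A plain tibble plus a `status` column.
#' @exportS3Method generics::tidy
tidy.size_classification <- function(x, ...) {
  mutate(as_tibble(x), status = attr(x, "status"))
}

#' Tidy an area comparison
#'
#' @param x A [compare_type_areas()] result.
#' @param ... Unused.
#' @return The per-type summary tibble.
#' @exportS3Method generics::tidy
tidy.area_comparison <- function(x, ...) as_tibble(x$summary)

#' @rdname tidy.area_comparison
#' @exportS3Method generics::glance
glance.area_comparison <- function(x, ...) {
  tibble(
    n_types = nrow(x$summary),
    ordering = paste(x$ordering, collapse = " > "),
    all_pairs_significant = all(x$pairwise$significant),
    alpha = x$alpha
  )
}

#' Tidy a monotonicity check
#'
#' @param x A [check_monotonicity()] result.
#' @param ... Unused.
#' @return The per-step differences tibble.
#' @exportS3Method generics::tidy
tidy.monotonicity_check <- function(x, ...) as_tibble(x$steps)

#' @rdname tidy.monotonicity_check
#' @exportS3Method generics::glance
glance.monotonicity_check <- function(x, ...) {
  tibble(
    monotone = x$monotone,
    strictly_increasing = x$strictly_increasing,
    n_steps = nrow(x$steps)
  )
}

#' Glance at a scenario result
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return One-row tibble with the headline outcomes.
#' @exportS3Method generics::glance
glance.scenario_result <- function(x, ...) {
  tibble(
    reference_time_s = x$reference_time_s,
    electrical_ordering = paste(x$electrical_ordering, collapse = " > "),
    imaging_ordering = if (is.null(x$imaging_ordering)) NA_character_ else
      paste(x$imaging_ordering, collapse = " > "),
    orderings_agree = x$orderings_agree,
    classification_correct = x$classification_correct,
    seed = x$config$seed
  )
}
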