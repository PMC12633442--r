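# broom-style tidiers.

#' Tidy an outcome table
#'
#' @param x A `saf_outcomes` tibble.
#' @param ... Ignored.
#' @return A plain tibble with one row per connection, annotated with the
#'   partitions of both endpoints.
#' @method tidy saf_outcomes
#' @export
tidy.saf_outcomes <- function(x, ...) {
  keys <- pfc_connections()
  left_join(as_tibble(x), keys, by = c("area_a", "area_b"))
}

#' One-row summary of an outcome table
#'
#' @param x A `saf_outcomes` tibble.
#' @param ... Ignored.
#' @return A one-row `saf_confusion` tibble.
#' @method glance saf_outcomes
#' @export
glance.saf_outcomes <- function(x, ...) {
  summarize_concordance(x)
}

#' @method tidy saf_confusion
#' @export
tidy.saf_confusion <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(cols = c("accuracy", "sensitivity", "specificity",
                                 "precision"),
                        names_to = "metric", values_to = "percent") |>
    select("scope", "metric", "percent")
}

#' @method glance saf_benchmark
#' @export
glance.saf_benchmark <- function(x, ...) {
  x$overall
}

#' @method tidy saf_benchmark
#' @export
tidy.saf_benchmark <- function(x, ...) {
  bind_rows(x$overall, x$partitions)
}

#' @method tidy saf_reliability
#' @export
tidy.saf_reliability <- function(x, ...) {
  x$report
}

#' @method glance saf_run
#' @export
glance.saf_run <- function(x, ...) {
  x$summary
}
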