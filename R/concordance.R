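# Per-subject presence calls, population classification against histology,
# and confusion statistics.

#' Classification configuration
#'
#' Thresholds for turning per-subject observations into a population-level
#' label: a connection is present in tractography when reconstructed in more
#' than `presence_fraction` of subjects (default 0.5, strict), robust when
#' reconstructed in more than `rtp_fraction` (default 0.8, strict), a
#' subject-level reconstruction counts as present when the cleaned bundle
#' retains at least `min_streamlines_present` streamlines (default 5 of a
#' 2,000-streamline ceiling), and the population bundle counts as plausible
#' when more than `plausibility_fraction` of the present subjects' bundles
#' are plausible (default 0.5, strict majority).
#'
#' @param presence_fraction,rtp_fraction,plausibility_fraction Fractions in
#'   (0, 1\].
#' @param min_streamlines_present Minimum cleaned streamline count.
#' @return An object of class `saf_classification_config`.
#' @export
classification_config <- function(presence_fraction = 0.5, rtp_fraction = 0.8,
                                  min_streamlines_present = 5L,
                                  plausibility_fraction = 0.5) {
  if (!(presence_fraction > 0 && presence_fraction < rtp_fraction &&
        rtp_fraction <= 1)) {
    abort("need 0 < presence_fraction < rtp_fraction <= 1",
          class = "safconn_invalid_config")
  }
  structure(list(presence_fraction = presence_fraction,
                 rtp_fraction = rtp_fraction,
                 min_streamlines_present = as.integer(min_streamlines_present),
                 plausibility_fraction = plausibility_fraction),
            class = "saf_classification_config")
}

#' Heuristic anatomical plausibility of a bundle
#'
#' Automated surrogate for visual quality assessment: a streamline is
#' flagged irregular when it loops (end-to-end distance below
#' `loop_ratio` times its path length) or when its total turning angle
#' exceeds `max_total_turn_rad`; the bundle is implausible when more than
#' half of its streamlines are irregular. Deterministic; an empty bundle
#' returns `NA` (it is absent anyway).
#'
#' @param b A `saf_bundle`.
#' @param loop_ratio Looping threshold on end-to-end / length (default 0.25).
#' @param max_total_turn_rad Turning budget in radians (default 1.5 * pi; a
#'   smooth U-arc turns by about pi).
#' @return `TRUE` (plausible), `FALSE` (implausible), or `NA` for an empty
#'   bundle.
#' @export
plausibility_heuristic <- function(b, loop_ratio = 0.25,
                                   max_total_turn_rad = 1.5 * pi) {
  if (length(b$streamlines) == 0L) return(NA)
  irregular <- vapply(b$streamlines, function(s) {
    len <- streamline_length(s)
    end_to_end <- sqrt(sum((s[nrow(s), ] - s[1, ])^2))
    if (end_to_end < loop_ratio * len) return(TRUE)
    total_turn(s) > max_total_turn_rad
  }, logical(1))
  mean(irregular) <= 0.5
}

total_turn <- function(s) {
  v <- diff(s)
  norms <- sqrt(rowSums(v * v))
  keep <- norms > 0
  v <- v[keep, , drop = FALSE] / norms[keep]
  if (nrow(v) < 2L) return(0)
  cosang <- rowSums(v[-nrow(v), , drop = FALSE] * v[-1, , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, cosang))))
}

#' Observe one subject's cleaned bundle
#'
#' Turns a cleaned bundle into a subject-level observation: the retained
#' streamline count, the presence call (`count >=
#' min_streamlines_present`), and a plausibility flag, either supplied
#' (recorded visual-QA surrogate) or computed with
#' [plausibility_heuristic()].
#'
#' @param b A cleaned `saf_bundle`.
#' @param config A [classification_config()].
#' @param plausible Optional recorded plausibility flag; when `NULL` the
#'   heuristic is used.
#' @return A one-row tibble with columns `subject_id`, `area_a`, `area_b`,
#'   `n_streamlines_clean`, `plausible`, `present`.
#' @export
observe_subject <- function(b, config = classification_config(),
                            plausible = NULL) {
  n <- length(b$streamlines)
  present <- n >= config$min_streamlines_present
  if (is.null(plausible)) plausible <- plausibility_heuristic(b)
  tibble(subject_id = b$subject_id, area_a = b$area_a, area_b = b$area_b,
         n_streamlines_clean = n, plausible = as.logical(plausible),
         present = present)
}

#' Observe every bundle of a population table
#'
#' Cleans each bundle (length filter, then outlier rejection) and derives
#' the subject-level observations in one pass.
#'
#' @param bundles Tibble with a list-column `bundle` of `saf_bundle`
#'   objects (e.g. the `bundles` element of a phantom population).
#' @param config A [classification_config()].
#' @param max_length_mm Length-filter cap (default 125).
#' @param threshold_factor Outlier-rejection threshold factor (default 3).
#' @return An observation tibble with one row per bundle.
#' @export
observe_population <- function(bundles, config = classification_config(),
                               max_length_mm = 125, threshold_factor = 3) {
  n <- nrow(bundles)
  n_clean <- integer(n)
  plausible <- logical(n)
  for (i in seq_len(n)) {
    b <- reject_outliers(filter_by_length(bundles$bundle[[i]], max_length_mm),
                         threshold_factor = threshold_factor)
    n_clean[i] <- length(b$streamlines)
    plausible[i] <- isTRUE(plausibility_heuristic(b))
  }
  tibble(subject_id = bundles$subject_id, area_a = bundles$area_a,
         area_b = bundles$area_b, n_streamlines_clean = n_clean,
         plausible = ifelse(n_clean == 0L, NA, plausible),
         present = n_clean >= config$min_streamlines_present)
}

#' Classify one connection against histology
#'
#' Applies the population decision table to a set of subject observations of
#' a single connection. With `f` the fraction of subjects in which the
#' connection is present and "plausible" a strict majority vote over the
#' present subjects:
#'
#' * histology present, `f > presence_fraction`, plausible: `TP`
#'   (`RTP` when `f > rtp_fraction`);
#' * histology present, `f > presence_fraction`, implausible: `FP`
#'   (trajectory false positive);
#' * histology present, `f <= presence_fraction`: `FN`;
#' * histology absent, `f > presence_fraction`: `FP`;
#' * histology absent, `f <= presence_fraction`: `TN`.
#'
#' @param observations Tibble of observations of one connection, as rows
#'   from [observe_subject()].
#' @param histology_status `"present"` or `"absent"`.
#' @param config A [classification_config()].
#' @return A one-row tibble with columns `area_a`, `area_b`,
#'   `population_fraction`, `population_present`, `population_plausible`,
#'   `histology_status`, `outcome_label`, `n_subjects`.
#' @export
classify_connection <- function(observations, histology_status,
                                config = classification_config()) {
  if (nrow(observations) == 0L) {
    abort("need at least one observation", class = "safconn_invalid_config")
  }
  key <- unique(observations[, c("area_a", "area_b")])
  if (nrow(key) != 1L) {
    abort("observations mix multiple connections",
          class = "safconn_invalid_config")
  }
  if (!histology_status %in% c("present", "absent")) {
    abort("histology_status must be 'present' or 'absent'",
          class = "safconn_invalid_config")
  }
  f <- mean(observations$present)
  pop_present <- f > config$presence_fraction
  plaus <- observations$plausible[observations$present]
  pop_plausible <- if (length(plaus) == 0L) NA else {
    mean(plaus, na.rm = TRUE) > config$plausibility_fraction
  }
  label <- if (histology_status == "present") {
    if (!pop_present) "FN"
    else if (isFALSE(pop_plausible)) "FP"
    else if (f > config$rtp_fraction) "RTP"
    else "TP"
  } else {
    if (pop_present) "FP" else "TN"
  }
  tibble(area_a = key$area_a, area_b = key$area_b,
         population_fraction = f, population_present = pop_present,
         population_plausible = pop_plausible,
         histology_status = histology_status, outcome_label = label,
         n_subjects = nrow(observations))
}

#' Classify every connection in an observation table
#'
#' Groups an observation table by connection, joins the histology
#' reference, and applies [classify_connection()] to each group.
#'
#' @param observations Observation tibble (rows from [observe_subject()]).
#' @param reference Histology reference tibble
#'   (default [histology_reference()]).
#' @param config A [classification_config()].
#' @return A `saf_outcomes` tibble, one row per observed connection.
#' @export
classify_connections <- function(observations,
                                 reference = histology_reference(),
                                 config = classification_config()) {
  groups <- split(observations,
                  paste(observations$area_a, observations$area_b, sep = "\r"))
  rows <- lapply(groups, function(obs) {
    ref <- semi_join(reference, obs[1, c("area_a", "area_b")],
                     by = c("area_a", "area_b"))
    if (nrow(ref) != 1L) {
      abort(paste0("connection ", obs$area_a[1], "-", obs$area_b[1],
                   " is not in the histology reference"),
            class = "safconn_reference_integrity")
    }
    classify_connection(obs, ref$histology_status, config)
  })
  out <- bind_rows(rows)
  keys <- pfc_connections()[, c("area_a", "area_b")]
  keys$.ord <- seq_len(nrow(keys))
  out <- left_join(out, keys, by = c("area_a", "area_b")) |>
    arrange(.data$.ord) |>
    select(-".ord")
  new_outcomes(out)
}

round_half_up <- function(x) floor(x + 0.5)

#' Confusion statistics of an outcome table
#'
#' Tallies RTP/TP/TN/FP/FN labels (RTP counted within TP) and derives
#' accuracy `100 (TP + TN) / n`, sensitivity `100 TP / (TP + FN)`,
#' specificity `100 TN / (TN + FP)` and precision `100 TP / (TP + FP)`.
#' Unrounded percentages are always retained; display rounding is
#' half-away-from-zero to the nearest integer. A metric whose denominator
#' is zero is reported as `NA`, never as 0 or 100.
#'
#' @param outcomes Outcome tibble with column `outcome_label` (e.g. from
#'   [connection_outcomes()] or [classify_connections()]).
#' @param scope Label describing the summarized subset.
#' @return A one-row tibble of class `saf_confusion` with the counts, the
#'   unrounded percentages (`accuracy`, `sensitivity`, `specificity`,
#'   `precision`) and their rounded displays (`*_rounded`).
#' @export
summarize_concordance <- function(outcomes, scope = "overall") {
  if (nrow(outcomes) == 0L) {
    abort("cannot summarize an empty outcome table",
          class = "safconn_outcome_integrity")
  }
  k <- outcome_counts(outcomes$outcome_label)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  res <- tibble(
    scope = scope,
    n_connections = nrow(outcomes),
    tp = k[["tp"]], rtp = k[["rtp"]], tn = k[["tn"]],
    fp = k[["fp"]], fn = k[["fn"]],
    accuracy = pct(k[["tp"]] + k[["tn"]],
                   k[["tp"]] + k[["tn"]] + k[["fp"]] + k[["fn"]]),
    sensitivity = pct(k[["tp"]], k[["tp"]] + k[["fn"]]),
    specificity = pct(k[["tn"]], k[["tn"]] + k[["fp"]]),
    precision = pct(k[["tp"]], k[["tp"]] + k[["fp"]])
  ) |>
    mutate(across(c("accuracy", "sensitivity", "specificity", "precision"),
                  round_half_up, .names = "{.col}_rounded"))
  class(res) <- c("saf_confusion", class(res))
  res
}

#' Confusion statistics for one partition
#'
#' Summarizes the connections with at least one endpoint in the given
#' partition (the same grouping convention as [partition_tally()]).
#'
#' @inheritParams partition_tally
#' @return A one-row `saf_confusion` tibble.
#' @export
summarize_partition <- function(outcomes, partition) {
  if (length(partition) != 1L || !partition %in% pfc_partitions) {
    abort(paste0("unknown partition: ", paste(partition, collapse = ", ")),
          class = "safconn_invalid_atlas")
  }
  keys <- pfc_connections()
  joined <- inner_join(as_tibble(outcomes), keys, by = c("area_a", "area_b"))
  sub <- filter(joined, .data$partition_a == partition |
                  .data$partition_b == partition)
  if (nrow(sub) == 0L) {
    abort(paste0("no outcomes fall in partition ", partition),
          class = "safconn_outcome_integrity")
  }
  summarize_concordance(sub, scope = partition)
}
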