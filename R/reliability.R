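# Within-subject (test-retest) and between-subject bundle reliability.

map_is_present <- function(map) {
  !is.null(map) && inherits(map, "saf_density") && nrow(map$voxels) > 0L
}

reliability_report <- function(pairs, comparison, n_excluded) {
  report <- tidyr::pivot_longer(pairs, cols = c("wdice", "adjacency_mm"),
                                names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (dplyr::n() > 1L) sd(.data$value) else 0,
              n_pairs = dplyr::n(), .groups = "drop") |>
    mutate(comparison = comparison, n_excluded = n_excluded) |>
    select("comparison", "metric", "mean", "sd", "n_pairs", "n_excluded")
  structure(list(report = report, pairs = pairs, comparison = comparison,
                 n_excluded = n_excluded),
            class = "saf_reliability")
}

#' @export
print.saf_reliability <- function(x, ...) {
  cat("<saf_reliability> ", x$comparison, ", ", nrow(x$pairs), " pairs (",
      x$n_excluded, " excluded)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Within-subject (test-retest) reliability
#'
#' Compares each subject's test and retest density maps of the same
#' connection with wDice and bundle adjacency, then pools mean and standard
#' deviation across subjects. Subjects in which either session's bundle is
#' absent (empty or missing map) are excluded from the means and counted.
#'
#' @param maps A tibble with columns `subject_id`, `session` (`"test"` /
#'   `"retest"`), and a list-column `map` of `saf_density` objects (or
#'   `NULL` for absent bundles); an optional `connection` column is carried
#'   through to the per-pair table.
#' @return A `saf_reliability` object: `$report` holds `comparison`,
#'   `metric`, `mean`, `sd`, `n_pairs`, `n_excluded`; `$pairs` the
#'   per-subject metric values.
#' @export
reliability_within <- function(maps) {
  have_conn <- "connection" %in% names(maps)
  split_key <- if (have_conn) {
    paste(maps$subject_id, maps$connection, sep = "\r")
  } else maps$subject_id
  groups <- split(seq_len(nrow(maps)), split_key)
  rows <- list()
  n_excluded <- 0L
  for (idx in groups) {
    sub <- maps[idx, ]
    test <- sub$map[match("test", sub$session)][[1]]
    retest <- sub$map[match("retest", sub$session)][[1]]
    if (is.na(match("test", sub$session)) || is.na(match("retest", sub$session))) {
      next  # subject without two sessions does not enter this design
    }
    if (!map_is_present(test) || !map_is_present(retest)) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      subject_id = sub$subject_id[1],
      connection = if (have_conn) sub$connection[1] else NA_character_,
      wdice = weighted_dice(test, retest),
      adjacency_mm = bundle_adjacency(test, retest)
    )
  }
  if (length(rows) == 0L) {
    abort("no subject has a present bundle in both sessions",
          class = "safconn_undefined_metric")
  }
  reliability_report(bind_rows(rows), "within_subject", n_excluded)
}

#' Between-subject variability
#'
#' Compares the same connection across subjects aligned in a common space:
#' wDice and bundle adjacency over unordered subject pairs (within each
#' connection when a `connection` column is given), pooled into mean and
#' standard deviation. Pairs in which either bundle is absent are excluded
#' and counted.
#'
#' @param maps A tibble with columns `subject_id` and list-column `map`
#'   (one session per subject), optionally `connection`.
#' @param max_pairs Optional cap on the number of pairs per connection;
#'   pairs are subsampled deterministically with `seed`.
#' @param seed Seed for pair subsampling.
#' @return A `saf_reliability` object.
#' @export
reliability_between <- function(maps, max_pairs = Inf, seed = 1L) {
  have_conn <- "connection" %in% names(maps)
  groups <- if (have_conn) {
    split(seq_len(nrow(maps)), maps$connection)
  } else list(seq_len(nrow(maps)))
  rows <- list()
  n_excluded <- 0L
  any_pairs <- FALSE
  for (idx in groups) {
    sub <- maps[idx, ]
    if (nrow(sub) < 2L) {
      abort("between-subject variability needs at least 2 subjects",
            class = "safconn_invalid_config")
    }
    pairs <- utils::combn(nrow(sub), 2L)
    any_pairs <- TRUE
    if (ncol(pairs) > max_pairs) {
      set.seed(seed)
      pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
    }
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (!map_is_present(sub$map[[i]]) || !map_is_present(sub$map[[j]])) {
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble(
        subject_a = sub$subject_id[i], subject_b = sub$subject_id[j],
        connection = if (have_conn) sub$connection[1] else NA_character_,
        wdice = weighted_dice(sub$map[[i]], sub$map[[j]]),
        adjacency_mm = bundle_adjacency(sub$map[[i]], sub$map[[j]])
      )
    }
  }
  if (length(rows) == 0L) {
    abort("no subject pair with both bundles present",
          class = "safconn_undefined_metric")
  }
  reliability_report(bind_rows(rows), "between_subject", n_excluded)
}
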