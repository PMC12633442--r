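# Orchestration: phantom pipeline runs and the packaged-benchmark
# replication.

#' Check outcome / histology mutual consistency
#'
#' Verifies the trajectory-false-positive bookkeeping between an outcome
#' table and a histology reference: every TP/RTP/FN connection must have
#' histological precedence, every TN must lack it, and the false positives
#' must split into `72 - (TP + FN)` trajectory FPs (histology present) and
#' `19 - TN` plain FPs (histology absent) when tallied over all 91 keys.
#'
#' @param outcomes Outcome tibble covering the 91 connections.
#' @param reference Histology reference tibble.
#' @return `TRUE`, invisibly; aborts with a reference-integrity error
#'   otherwise.
#' @export
check_reference_consistency <- function(outcomes = connection_outcomes(),
                                        reference = histology_reference()) {
  joined <- inner_join(as_tibble(outcomes)[, c("area_a", "area_b", "outcome_label")],
                       reference[, c("area_a", "area_b", "histology_status")],
                       by = c("area_a", "area_b"))
  if (nrow(joined) != 91L) {
    abort("outcome table and histology reference do not cover the same 91 keys",
          class = "safconn_reference_integrity")
  }
  lab <- joined$outcome_label
  hist <- joined$histology_status
  if (!all(hist[lab %in% c("TP", "RTP", "FN")] == "present") ||
      !all(hist[lab == "TN"] == "absent")) {
    abort("outcome labels contradict histology status",
          class = "safconn_reference_integrity")
  }
  k <- outcome_counts(lab)
  fp_present <- sum(lab == "FP" & hist == "present")
  fp_absent <- sum(lab == "FP" & hist == "absent")
  if (fp_present != 72L - (k[["tp"]] + k[["fn"]]) ||
      fp_absent != 19L - k[["tn"]]) {
    abort("trajectory-FP bookkeeping does not reconcile with the 72/19 split",
          class = "safconn_reference_integrity")
  }
  invisible(TRUE)
}

#' Replicate the benchmark histology comparison
#'
#' Loads the packaged outcome table and histology reference, validates
#' their integrity and mutual consistency, and computes the overall and
#' per-partition confusion statistics with both unrounded and rounded
#' percentages. This bypasses simulation entirely; it is the package's
#' replication of the benchmark study's summary surface.
#'
#' @return An object of class `saf_benchmark`: `$overall` and
#'   `$partitions` are `saf_confusion` tibbles, `$outcomes` and
#'   `$reference` the validated assets.
#' @examples
#' histology_benchmark()$overall$accuracy_rounded  # 73
#' @export
histology_benchmark <- function() {
  outcomes <- connection_outcomes()
  reference <- histology_reference()
  check_reference_consistency(outcomes, reference)
  partitions <- bind_rows(lapply(pfc_partitions, function(p) {
    summarize_partition(outcomes, p)
  }))
  structure(
    list(overall = summarize_concordance(outcomes, scope = "overall"),
         partitions = partitions, outcomes = outcomes, reference = reference),
    class = "saf_benchmark"
  )
}

#' @export
print.saf_benchmark <- function(x, ...) {
  cat("Histology concordance of the packaged 91-connection benchmark\n\n")
  all <- bind_rows(x$overall, x$partitions)
  print(as.data.frame(all[, c("scope", "n_connections", "tp", "rtp", "tn",
                              "fp", "fn", "accuracy_rounded",
                              "sensitivity_rounded", "specificity_rounded",
                              "precision_rounded")]),
        row.names = FALSE)
  cat("\n(unrounded percentages retained in $overall / $partitions)\n")
  invisible(x)
}

#' Run the full phantom pipeline
#'
#' Generates a phantom population, cleans every bundle (length filter then
#' outlier rejection), derives subject observations, classifies each
#' connection against its histology status, and summarizes the confusion
#' statistics; with two sessions it also computes within- and
#' between-subject reliability on voxelized density maps. Rerunning with
#' the same configuration reproduces identical outputs.
#'
#' @param config A [phantom_config()]; its `connections` tibble must carry
#'   a `histology_status` column.
#' @param layout A [phantom_layout()].
#' @param class_config A [classification_config()].
#' @param max_length_mm Length-filter cap applied to every bundle.
#' @param reliability Compute reliability metrics (default: when the
#'   config has two sessions).
#' @param out_dir Optional output directory for `outcomes.csv`,
#'   `observations.csv`, `summary.json`, `reliability.csv` and a manifest
#'   with checksums.
#' @return An object of class `saf_run`: observations, outcomes, summary,
#'   per-partition summaries (when all 91 connections are covered),
#'   reliability reports, truth, and the echoed config.
#' @export
run_pipeline <- function(config, layout = phantom_layout(config$seed),
                         class_config = classification_config(),
                         max_length_mm = 125,
                         reliability = config$sessions == 2L,
                         out_dir = NULL) {
  if (!"histology_status" %in% names(config$connections)) {
    abort("config$connections must carry histology_status",
          class = "safconn_invalid_config")
  }
  pop <- generate_population(layout, config)
  rows <- pop$bundles
  observations <- observe_population(
    rows[rows$session == rows$session[1], ], class_config,
    max_length_mm = max_length_mm
  )
  reference <- unique(config$connections[, c("area_a", "area_b",
                                             "histology_status")])
  outcomes <- classify_connections(observations, reference, class_config)
  summary <- summarize_concordance(outcomes, scope = "overall")
  covered <- nrow(outcomes) == 91L
  partition_summaries <- if (covered) {
    bind_rows(lapply(pfc_partitions, function(p) summarize_partition(outcomes, p)))
  } else NULL

  rel_within <- rel_between <- NULL
  if (reliability) {
    maps <- rows |>
      mutate(connection = paste0(.data$area_a, "-", .data$area_b),
             map = map(.data$bundle, function(b) {
               if (length(b) == 0L) return(NULL)
               cleaned <- reject_outliers(filter_by_length(b, max_length_mm))
               compute_density_map(cleaned, layout$grid)
             })) |>
      select("subject_id", "session", "connection", "map")
    if (config$sessions == 2L) rel_within <- reliability_within(maps)
    rel_between <- reliability_between(filter(maps, .data$session == "test"))
  }

  run <- structure(
    list(observations = observations, outcomes = outcomes, summary = summary,
         partition_summaries = partition_summaries,
         reliability_within = rel_within, reliability_between = rel_between,
         truth = pop$truth, config = config, layout = layout),
    class = "saf_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.saf_run <- function(x, ...) {
  cat("<saf_run> ", nrow(x$outcomes), " connections classified over ",
      x$config$n_subjects, " subjects\n", sep = "")
  print(x$summary)
  invisible(x)
}

# small deterministic rolling checksum over file bytes (31-bit)
file_checksum <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.size(path)))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(run$outcomes), file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  summary <- list(overall = as.list(run$summary))
  if (!is.null(run$partition_summaries)) {
    summary$partitions <- run$partition_summaries
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rel <- bind_rows(
    if (!is.null(run$reliability_within)) run$reliability_within$report,
    if (!is.null(run$reliability_between)) run$reliability_between$report
  )
  if (!is.null(rel) && nrow(rel)) {
    write.csv(rel, file.path(dir, "reliability.csv"), row.names = FALSE)
  }
  files <- list.files(dir, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- tibble(
    file = files,
    bytes = vapply(file.path(dir, files), file.size, numeric(1)),
    checksum = vapply(file.path(dir, files), file_checksum, character(1))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
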