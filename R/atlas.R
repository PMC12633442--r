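# Prefrontal atlas, connection scheme, and packaged reference tables.

#' The five prefrontal partitions
#'
#' Canonical names of the five prefrontal subdivisions used throughout the
#' package: dorsolateral (dlPFC), ventrolateral (vlPFC), frontal pole,
#' orbitofrontal (OFC) and anterior cingulate (ACC).
#' @export
pfc_partitions <- c("dlPFC", "vlPFC", "FrontalPole", "OFC", "ACC")

#' Canonical ordering of the 14 prefrontal areas
#'
#' Fixed area order used to canonicalize unordered connection keys and to
#' order rows and plot axes. Grouped by partition: dlPFC (8, 9, 46, 9/46),
#' vlPFC (44, 45, 47), frontal pole (10), OFC (11, 13, 14), ACC (24, 25, 32).
#' @export
pfc_area_order <- c("8", "9", "46", "9/46", "44", "45", "47",
                    "10", "11", "13", "14", "24", "25", "32")

asset_path <- function(file) {
  path <- system.file("extdata", file, package = "safconn")
  if (!nzchar(path)) {
    abort(paste0("packaged asset '", file, "' not found"),
          class = "safconn_reference_integrity")
  }
  path
}

#' Prefrontal atlas areas
#'
#' Returns the 14 Brodmann-style prefrontal areas with their partition
#' assignment and a brief anatomical description.
#'
#' @return A tibble with columns `area_id`, `partition`, `description`
#'   (14 rows).
#' @examples
#' pfc_atlas()
#' @export
pfc_atlas <- function() {
  atlas <- as_tibble(read.csv(asset_path("pfc_atlas.csv"),
                              colClasses = "character"))
  validate_atlas(atlas)
  atlas$area_id <- factor(atlas$area_id, levels = pfc_area_order)
  arrange(atlas, .data$area_id) |>
    mutate(area_id = as.character(.data$area_id))
}

validate_atlas <- function(atlas) {
  expected <- list(
    dlPFC = c("8", "9", "46", "9/46"),
    vlPFC = c("44", "45", "47"),
    FrontalPole = "10",
    OFC = c("11", "13", "14"),
    ACC = c("24", "25", "32")
  )
  if (anyDuplicated(atlas$area_id)) {
    abort("atlas area_id values must be unique", class = "safconn_invalid_atlas")
  }
  if (nrow(atlas) != 14L || !setequal(atlas$area_id, pfc_area_order)) {
    abort("atlas must contain exactly the 14 prefrontal areas",
          class = "safconn_invalid_atlas")
  }
  for (p in names(expected)) {
    got <- atlas$area_id[atlas$partition == p]
    if (!setequal(got, expected[[p]])) {
      abort(paste0("partition ", p, " must contain areas ",
                   paste(expected[[p]], collapse = ", ")),
            class = "safconn_invalid_atlas")
    }
  }
  invisible(atlas)
}

#' Canonicalize an unordered area pair
#'
#' Orders the two endpoints of a connection by the fixed area list
#' [pfc_area_order], so that `connection_key(a, b)` and
#' `connection_key(b, a)` are identical. Vectorized.
#'
#' @param area_a,area_b Character vectors of area ids.
#' @return A tibble with columns `area_a`, `area_b` in canonical order.
#' @examples
#' connection_key("44", "8")  # returns area_a = "8", area_b = "44"
#' @export
connection_key <- function(area_a, area_b) {
  ia <- match(area_a, pfc_area_order)
  ib <- match(area_b, pfc_area_order)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(area_a[is.na(ia)], area_b[is.na(ib)]))
    abort(paste0("unknown area id(s): ", paste(bad, collapse = ", ")),
          class = "safconn_invalid_atlas")
  }
  if (any(ia == ib)) {
    abort("a connection must join two distinct areas",
          class = "safconn_invalid_atlas")
  }
  swap <- ia > ib
  a <- ifelse(swap, area_b, area_a)
  b <- ifelse(swap, area_a, area_b)
  tibble(area_a = a, area_b = b)
}

#' All 91 prefrontal connections
#'
#' Enumerates the unordered pairs of the 14 atlas areas in deterministic
#' canonical order, annotated with the partition of each endpoint.
#'
#' @param atlas Atlas tibble as returned by [pfc_atlas()].
#' @return A tibble with columns `area_a`, `area_b`, `partition_a`,
#'   `partition_b`, `intra_partition` (91 rows for the full atlas).
#' @examples
#' nrow(pfc_connections())                    # 91
#' sum(pfc_connections()$intra_partition)     # 15
#' @export
pfc_connections <- function(atlas = pfc_atlas()) {
  if (anyDuplicated(atlas$area_id)) {
    abort("atlas area_id values must be unique", class = "safconn_invalid_atlas")
  }
  ord <- order(match(atlas$area_id, pfc_area_order))
  ids <- atlas$area_id[ord]
  part <- setNames(atlas$partition[ord], ids)
  n <- length(ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  tibble(
    area_a = ids[pairs[, "row"]],
    area_b = ids[pairs[, "col"]],
    partition_a = unname(part[ids[pairs[, "row"]]]),
    partition_b = unname(part[ids[pairs[, "col"]]])
  ) |>
    mutate(intra_partition = .data$partition_a == .data$partition_b)
}

#' Literature-derived histology reference
#'
#' Loads the packaged present/absent status of each of the 91 prefrontal
#' connections, compiled from the primate tract-tracing literature: 72
#' connections with consistent histological precedence and 19 without.
#' The reference is validated on load; a corrupt asset raises a
#' reference-integrity error.
#'
#' @return A tibble with columns `area_a`, `area_b`, `histology_status`
#'   (`"present"`/`"absent"`), `provenance` (91 rows).
#' @examples
#' table(histology_reference()$histology_status)
#' @export
histology_reference <- function() {
  ref <- as_tibble(read.csv(asset_path("histology_reference.csv"),
                            colClasses = "character"))
  keys <- pfc_connections()
  if (nrow(ref) != 91L ||
      nrow(anti_join(keys, ref, by = c("area_a", "area_b"))) > 0L) {
    abort("histology reference must cover all 91 connection keys",
          class = "safconn_reference_integrity")
  }
  n_present <- sum(ref$histology_status == "present")
  n_absent <- sum(ref$histology_status == "absent")
  if (n_present != 72L || n_absent != 19L) {
    abort(paste0("histology reference must contain 72 present and 19 absent ",
                 "entries, got ", n_present, "/", n_absent),
          class = "safconn_reference_integrity")
  }
  ref
}

# Agreement (TP + TN) expected in each partition summary of the packaged
# benchmark table; used only for asset self-validation.
benchmark_partition_agreement <- c(
  dlPFC = 34L, vlPFC = 27L, FrontalPole = 13L, OFC = 22L, ACC = 21L
)

#' Benchmark connection outcomes
#'
#' Loads the packaged per-connection classification of the 91 prefrontal
#' connections from the reference histology-guided tractography study of
#' 1,003 young adults: robust true positive (RTP), true positive (TP), true
#' negative (TN), false positive (FP) or false negative (FN). Where the
#' study's area-by-area accounts conflict with each other or with its
#' summary tallies, the packaged label follows the summary tallies and the
#' conflict is recorded in the `provenance` column.
#'
#' The table is validated on load against the study-level totals
#' (49 TP of which 41 RTP, 17 TN, 13 FP, 12 FN) and the per-partition
#' agreement counts; a mismatch raises an outcome-integrity error naming
#' the offending partition.
#'
#' @return A tibble with columns `area_a`, `area_b`, `outcome_label`,
#'   `provenance` (91 rows), of class `saf_outcomes`.
#' @examples
#' dplyr::count(connection_outcomes(), outcome_label)
#' @export
connection_outcomes <- function() {
  out <- as_tibble(read.csv(asset_path("connection_outcomes.csv"),
                            colClasses = "character"))
  keys <- pfc_connections()
  if (nrow(out) != 91L ||
      nrow(anti_join(keys, out, by = c("area_a", "area_b"))) > 0L) {
    abort("outcome table must cover all 91 connection keys",
          class = "safconn_outcome_integrity")
  }
  counts <- outcome_counts(out$outcome_label)
  expected <- c(tp = 49L, rtp = 41L, tn = 17L, fp = 13L, fn = 12L)
  if (!identical(counts[names(expected)], expected)) {
    abort("outcome table overall counts do not match the benchmark totals",
          class = "safconn_outcome_integrity")
  }
  joined <- left_join(keys, out, by = c("area_a", "area_b"))
  for (p in names(benchmark_partition_agreement)) {
    sub <- filter(joined, .data$partition_a == p | .data$partition_b == p)
    agree <- sum(sub$outcome_label %in% c("RTP", "TP", "TN"))
    if (agree != benchmark_partition_agreement[[p]]) {
      abort(paste0("outcome table tally mismatch in partition ", p),
            class = "safconn_outcome_integrity")
    }
  }
  new_outcomes(out)
}

new_outcomes <- function(x) {
  class(x) <- c("saf_outcomes", class(x))
  x
}

outcome_counts <- function(labels) {
  c(tp = sum(labels %in% c("TP", "RTP")),
    rtp = sum(labels == "RTP"),
    tn = sum(labels == "TN"),
    fp = sum(labels == "FP"),
    fn = sum(labels == "FN"))
}

#' Per-partition confusion tally
#'
#' Tallies the outcome labels of every connection with at least one endpoint
#' in the given partition (intra-partition pairs are counted once; each
#' inter-partition pair therefore contributes to two partition tallies).
#' RTP is counted within TP.
#'
#' @param outcomes Outcome tibble with columns `area_a`, `area_b`,
#'   `outcome_label` (e.g. from [connection_outcomes()]).
#' @param partition One of [pfc_partitions].
#' @return A one-row tibble with columns `partition`, `n_connections`,
#'   `tp`, `rtp`, `tn`, `fp`, `fn`.
#' @examples
#' partition_tally(connection_outcomes(), "vlPFC")$n_connections  # 36
#' @export
partition_tally <- function(outcomes, partition) {
  if (length(partition) != 1L || !partition %in% pfc_partitions) {
    abort(paste0("unknown partition: ", paste(partition, collapse = ", ")),
          class = "safconn_invalid_atlas")
  }
  if (nrow(outcomes) == 0L) {
    abort("outcome table is empty", class = "safconn_outcome_integrity")
  }
  keys <- pfc_connections()
  joined <- inner_join(as_tibble(outcomes)[, c("area_a", "area_b", "outcome_label")],
                       keys, by = c("area_a", "area_b"))
  if (nrow(joined) != nrow(outcomes)) {
    abort("outcome table contains keys outside the 91-connection scheme",
          class = "safconn_outcome_integrity")
  }
  sub <- filter(joined, .data$partition_a == partition | .data$partition_b == partition)
  counts <- outcome_counts(sub$outcome_label)
  tibble(partition = partition, n_connections = nrow(sub),
         tp = counts[["tp"]], rtp = counts[["rtp"]], tn = counts[["tn"]],
         fp = counts[["fp"]], fn = counts[["fn"]])
}
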