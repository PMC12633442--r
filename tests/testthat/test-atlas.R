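test_that("atlas defines the 14 areas in their five partitions", {
  atlas <- pfc_atlas()
  expect_equal(nrow(atlas), 14L)
  expect_setequal(atlas$area_id, pfc_area_order)
  expect_equal(atlas$partition[atlas$area_id == "10"], "FrontalPole")
  expect_setequal(atlas$area_id[atlas$partition == "dlPFC"],
                  c("8", "9", "46", "9/46"))
  expect_setequal(atlas$area_id[atlas$partition == "vlPFC"],
                  c("44", "45", "47"))
  expect_setequal(atlas$area_id[atlas$partition == "OFC"],
                  c("11", "13", "14"))
  expect_setequal(atlas$area_id[atlas$partition == "ACC"],
                  c("24", "25", "32"))
})

test_that("connection keys canonicalize and enumerate all unordered pairs", {
  expect_equal(connection_key("44", "8"), connection_key("8", "44"))
  expect_equal(connection_key("44", "8")$area_a, "8")
  # canonicalization is idempotent
  k <- connection_key("32", "9/46")
  expect_equal(connection_key(k$area_a, k$area_b), k)
  expect_error(connection_key("8", "8"), class = "safconn_invalid_atlas")
  expect_error(connection_key("8", "99"), class = "safconn_invalid_atlas")

  keys <- pfc_connections()
  expect_equal(nrow(keys), 91L)
  expect_equal(anyDuplicated(paste(keys$area_a, keys$area_b)), 0L)
  expect_equal(sum(keys$intra_partition), 15L)

  two <- pfc_atlas()[1:2, ]
  expect_equal(nrow(pfc_connections(two)), 1L)
  dup <- pfc_atlas()
  dup$area_id[2] <- dup$area_id[1]
  expect_error(pfc_connections(dup), class = "safconn_invalid_atlas")
})

test_that("histology reference has the 72/19 split and the recorded statuses", {
  ref <- histology_reference()
  expect_equal(nrow(ref), 91L)
  expect_equal(sum(ref$histology_status == "present"), 72L)
  expect_equal(sum(ref$histology_status == "absent"), 19L)
  status_of <- function(a, b) {
    key <- connection_key(a, b)
    ref$histology_status[ref$area_a == key$area_a & ref$area_b == key$area_b]
  }
  expect_equal(status_of("9", "25"), "absent")
  expect_equal(status_of("46", "24"), "present")
})

test_that("outcome table carries the benchmark labels and totals", {
  out <- connection_outcomes()
  expect_equal(nrow(out), 91L)
  label_of <- function(a, b) {
    key <- connection_key(a, b)
    out$outcome_label[out$area_a == key$area_a & out$area_b == key$area_b]
  }
  expect_equal(label_of("8", "44"), "RTP")
  expect_equal(label_of("46", "32"), "FP")
  expect_equal(sum(out$outcome_label == "RTP"), 41L)
})

test_that("partition tallies follow the endpoint convention and its identity", {
  out <- connection_outcomes()
  expect_equal(partition_tally(out, "vlPFC")$n_connections, 36L)
  expect_equal(partition_tally(out, "FrontalPole")$n_connections, 13L)
  totals <- vapply(pfc_partitions,
                   function(p) partition_tally(out, p)$n_connections,
                   integer(1))
  expect_equal(totals, c(dlPFC = 46L, vlPFC = 36L, FrontalPole = 13L,
                         OFC = 36L, ACC = 36L))
  # each inter-partition pair counted twice, each of the 15 intra pairs once
  expect_identical(sum(totals), 167L)
  expect_identical(sum(totals), 91L + 76L)

  expect_error(partition_tally(out, "parietal"), class = "safconn_invalid_atlas")
  expect_error(partition_tally(out[0, ], "ACC"),
               class = "safconn_outcome_integrity")
})

test_that("outcome table and histology reference satisfy the trajectory-FP rule", {
  out <- connection_outcomes()
  ref <- histology_reference()
  expect_true(check_reference_consistency(out, ref))
  joined <- dplyr::inner_join(as.data.frame(out), ref,
                              by = c("area_a", "area_b"))
  expect_true(all(joined$histology_status[
    joined$outcome_label %in% c("TP", "RTP", "FN")] == "present"))
  expect_true(all(joined$histology_status[joined$outcome_label == "TN"] ==
                    "absent"))
  k <- table(joined$outcome_label)
  tp <- sum(k[c("TP", "RTP")])
  expect_equal(sum(joined$outcome_label == "FP" &
                     joined$histology_status == "present"),
               72L - (tp + k[["FN"]]))
  expect_equal(sum(joined$outcome_label == "FP" &
                     joined$histology_status == "absent"),
               19L - k[["TN"]])
})
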