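tube_map <- function(shift = c(0, 0, 0), grid = grid_spec(1, c(0, 0, 0), c(24, 24, 24))) {
  b <- tube_bundle()
  b$streamlines <- lapply(b$streamlines, function(s) sweep(s, 2, shift, "+"))
  compute_density_map(b, grid)
}

test_that("identical sessions give perfect within-subject reliability", {
  maps <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    session = rep(c("test", "retest"), 3),
    map = lapply(1:6, function(i) tube_map())
  )
  rel <- reliability_within(maps)
  rep <- rel$report
  expect_equal(rep$mean[rep$metric == "wdice"], 1)
  expect_equal(rep$mean[rep$metric == "adjacency_mm"], 0)
  expect_equal(unique(rep$n_pairs), 3L)
})

test_that("a single complete subject reports sd 0 with one pair", {
  maps <- tibble::tibble(subject_id = c("s1", "s1"),
                         session = c("test", "retest"),
                         map = list(tube_map(), tube_map(c(1, 0, 0))))
  rel <- reliability_within(maps)
  expect_equal(unique(rel$report$n_pairs), 1L)
  expect_equal(unique(rel$report$sd), 0)
})

test_that("absent sessions are excluded and counted", {
  maps <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    session = rep(c("test", "retest"), 2),
    map = list(tube_map(), tube_map(), tube_map(), NULL)
  )
  rel <- reliability_within(maps)
  expect_equal(unique(rel$report$n_pairs), 1L)
  expect_equal(rel$n_excluded, 1L)

  none <- tibble::tibble(subject_id = c("s1", "s1"),
                         session = c("test", "retest"),
                         map = list(NULL, tube_map()))
  expect_error(reliability_within(none), class = "safconn_undefined_metric")
})

test_that("between-subject variability uses all unordered pairs", {
  maps <- tibble::tibble(
    subject_id = c("s1", "s2", "s3"),
    map = list(tube_map(), tube_map(), tube_map())
  )
  rel <- reliability_between(maps)
  expect_equal(unique(rel$report$n_pairs), 3L)  # C(3, 2)
  expect_equal(rel$report$mean[rel$report$metric == "wdice"], 1)

  expect_error(reliability_between(maps[1, ]), class = "safconn_invalid_config")
})

test_that("larger between- than within-subject displacement orders the metrics", {
  # deterministic construction: sessions 1 voxel apart, subjects 4 voxels apart
  subjects <- c("s1", "s2", "s3")
  subj_shift <- list(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  within_maps <- dplyr::bind_rows(lapply(seq_along(subjects), function(i) {
    tibble::tibble(subject_id = subjects[i], session = c("test", "retest"),
                   map = list(tube_map(subj_shift[[i]]),
                              tube_map(subj_shift[[i]] + c(0, 0, 1))))
  }))
  within <- reliability_within(within_maps)
  between <- reliability_between(
    within_maps[within_maps$session == "test", c("subject_id", "map")]
  )
  w <- within$report
  b <- between$report
  expect_gt(w$mean[w$metric == "wdice"], b$mean[b$metric == "wdice"])
  expect_lt(w$mean[w$metric == "adjacency_mm"],
            b$mean[b$metric == "adjacency_mm"])
})
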