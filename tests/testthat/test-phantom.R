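test_that("layouts are deterministic and validated", {
  a <- phantom_layout(5)
  b <- phantom_layout(5)
  expect_identical(a$centers, b$centers)
  expect_false(isTRUE(all.equal(phantom_layout(6)$centers, a$centers)))
  grid <- a$grid
  upper <- grid$origin + grid$shape * grid$voxel_size
  expect_true(all(a$centers >= grid$origin & a$centers <= upper))
  expect_error(phantom_layout(1, roi_radius_mm = 60),
               class = "safconn_invalid_config")
})

test_that("u-bundles are smooth short arcs anchored in their ROIs", {
  lay <- phantom_layout(1)
  cfg <- phantom_config(n_subjects = 1, n_streamlines = 25, seed = 2)
  b <- generate_u_bundle(lay, "9", "45", cfg, 77)
  lens <- bundle_lengths(b)
  expect_true(all(lens >= 38 & lens <= 125))
  expect_true(plausibility_heuristic(b))
  # every endpoint inside its ROI sphere
  ca <- lay$centers["9", ]; cb <- lay$centers["45", ]
  ends <- t(vapply(b$streamlines, function(s) {
    c(sqrt(sum((s[1, ] - ca)^2)), sqrt(sum((s[nrow(s), ] - cb)^2)))
  }, numeric(2)))
  expect_true(all(ends <= lay$roi_radius_mm))

  # zero jitter collapses the bundle onto the centroid arc
  cfg0 <- phantom_config(n_subjects = 1, n_streamlines = 5, seed = 2,
                         streamline_jitter_sd_mm = 0)
  b0 <- generate_u_bundle(lay, "9", "45", cfg0, 77)
  for (s in b0$streamlines) expect_equal(s, b0$streamlines[[1]])
})

test_that("bundles regenerate bit-identically from their seeds", {
  lay <- phantom_layout(1)
  cfg <- phantom_config(n_subjects = 1, n_streamlines = 10, seed = 4)
  f1 <- withr::local_tempfile(fileext = ".tck")
  f2 <- withr::local_tempfile(fileext = ".tck")
  write_tck(generate_u_bundle(lay, "8", "44", cfg, 555), f1)
  write_tck(generate_u_bundle(lay, "8", "44", cfg, 555), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("spurious bundles fail and u-arcs pass the heuristic almost surely", {
  lay <- phantom_layout(1)
  cfg <- phantom_config(n_subjects = 1, n_streamlines = 8, seed = 10)
  verdicts <- vapply(1:200, function(i) {
    c(plausibility_heuristic(generate_u_bundle(lay, "9", "47", cfg, 1000L + i)),
      plausibility_heuristic(generate_spurious_bundle(lay, "9", "47", cfg, 2000L + i)))
  }, logical(2))
  expect_gte(mean(verdicts[1, ]), 0.95)   # plausible mode passes
  expect_gte(mean(!verdicts[2, ]), 0.95)  # spurious mode fails
})

test_that("population presence follows the configured Bernoulli rates", {
  lay <- phantom_layout(1)
  prof <- recovery_profile()[1:2, ]
  prof$presence_probability <- c(1, 0)
  cfg <- phantom_config(n_subjects = 6, seed = 3, connections = prof,
                        n_streamlines = 4)
  pop <- generate_population(lay, cfg)
  always <- pop$truth$generated_present[
    pop$truth$area_a == prof$area_a[1] & pop$truth$area_b == prof$area_b[1]]
  never <- pop$truth$generated_present[
    pop$truth$area_a == prof$area_a[2] & pop$truth$area_b == prof$area_b[2]]
  expect_true(all(always))
  expect_false(any(never))

  # binomial concentration at p = 0.6 over 500 subjects
  prof2 <- recovery_profile()[1, ]
  prof2$presence_probability <- 0.6
  cfg2 <- phantom_config(n_subjects = 500, seed = 8, connections = prof2,
                         n_streamlines = 2)
  pop2 <- generate_population(lay, cfg2)
  expect_lt(abs(mean(pop2$truth$generated_present) - 0.6), 0.05)
})

test_that("identical configs reproduce a byte-identical file tree", {
  lay <- phantom_layout(2)
  prof <- recovery_profile()[1:3, ]
  cfg <- phantom_config(n_subjects = 2, sessions = 2, seed = 21,
                        connections = prof, n_streamlines = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_population(lay, cfg, write_dir = d1)
  generate_population(lay, cfg, write_dir = d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  tcks <- files[grepl("[.]tck$", files)]
  expect_gt(length(tcks), 0L)
  for (f in tcks) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})
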