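arr3 <- function(shape = c(6, 6, 6), cells) {
  a <- array(0L, dim = shape)
  for (c_ in cells) a[c_[1], c_[2], c_[3]] <- c_[4]
  a
}

test_that("overlap metrics honour their closed-form example values", {
  # supports {v1, v2} vs {v2, v3}: dice = 2*1/(2+2), uniform wdice = 0.5
  a <- density_from_array(arr3(cells = list(c(1, 1, 1, 1), c(2, 1, 1, 1))))
  b <- density_from_array(arr3(cells = list(c(2, 1, 1, 1), c(3, 1, 1, 1))))
  expect_equal(dice(a, b), 0.5)
  expect_equal(weighted_dice(a, b), 0.5)

  same <- density_from_array(arr3(cells = list(c(1, 2, 3, 4), c(4, 4, 4, 1))))
  expect_equal(dice(same, same), 1)
  expect_equal(weighted_dice(same, same), 1)
  expect_equal(bundle_adjacency(same, same), 0)

  disjoint_a <- density_from_array(arr3(cells = list(c(1, 1, 1, 2))))
  disjoint_b <- density_from_array(arr3(cells = list(c(6, 6, 6, 3))))
  expect_equal(dice(disjoint_a, disjoint_b), 0)
  expect_equal(weighted_dice(disjoint_a, disjoint_b), 0)

  # single-voxel supports 4 mm apart on a 1 mm grid
  pa <- density_from_array(arr3(cells = list(c(1, 1, 1, 1))))
  pb <- density_from_array(arr3(cells = list(c(5, 1, 1, 1))))
  expect_equal(bundle_adjacency(pa, pb), 4)

  # nested supports: only the non-empty direction contributes
  na_ <- density_from_array(arr3(cells = list(c(1, 1, 1, 1))))
  nb <- density_from_array(arr3(cells = list(c(1, 1, 1, 1), c(4, 1, 1, 1))))
  expect_equal(bundle_adjacency(na_, nb), 3)
})

test_that("degenerate inputs are handled per contract", {
  empty <- density_from_array(arr3(cells = list()))
  full <- density_from_array(arr3(cells = list(c(1, 1, 1, 1))))
  expect_equal(dice(empty, empty), 1)
  expect_equal(weighted_dice(full, empty), 0)
  expect_error(weighted_dice(empty, empty), class = "safconn_undefined_metric")
  expect_error(bundle_adjacency(full, empty), class = "safconn_undefined_metric")
  other_grid <- density_from_array(arr3(cells = list(c(1, 1, 1, 1))),
                                   voxel_size = 2)
  expect_error(dice(full, other_grid), class = "safconn_grid_mismatch")
})

test_that("metrics are symmetric and match brute-force enumeration to 1e-12", {
  set.seed(42)
  for (case in 1:20) {
    a <- random_density(n_occupied = sample(3:20, 1))
    b <- random_density(n_occupied = sample(3:20, 1))
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(weighted_dice(a, b), weighted_dice(b, a))
    expect_equal(bundle_adjacency(a, b), bundle_adjacency(b, a))
    expect_equal(dice(a, b), oracle_dice(a, b), tolerance = 1e-12)
    expect_equal(weighted_dice(a, b), oracle_wdice(a, b), tolerance = 1e-12)
    expect_equal(bundle_adjacency(a, b), oracle_ba(a, b), tolerance = 1e-12)
  }
})

test_that("overlap degrades monotonically under translation", {
  g <- grid_spec(1, c(0, 0, 0), c(24, 24, 24))
  base <- tube_bundle()
  ref <- compute_density_map(base, g)
  wd <- c()
  ba <- c()
  for (t_ in 0:6) {
    shifted <- base
    shifted$streamlines <- lapply(shifted$streamlines,
                                  function(s) sweep(s, 2, c(t_, 0, 0), "+"))
    m <- compute_density_map(shifted, g)
    wd <- c(wd, weighted_dice(ref, m))
    ba <- c(ba, bundle_adjacency(ref, m))
  }
  expect_equal(wd[1], 1)
  expect_equal(ba[1], 0)
  expect_true(all(diff(wd) <= 1e-12))
  expect_true(all(diff(ba) >= -1e-12))
})

test_that("rigidly translating both maps together leaves metrics unchanged", {
  g1 <- grid_spec(1, c(0, 0, 0), c(16, 16, 16))
  b1 <- tube_bundle()
  b2 <- tube_bundle(n = 6, x0 = 3.4, x1 = 10.9)
  shift <- c(3, 2, 4)
  shift_bundle <- function(b) {
    b$streamlines <- lapply(b$streamlines, function(s) sweep(s, 2, shift, "+"))
    b
  }
  m1 <- compute_density_map(b1, g1)
  m2 <- compute_density_map(b2, g1)
  s1 <- compute_density_map(shift_bundle(b1), g1)
  s2 <- compute_density_map(shift_bundle(b2), g1)
  expect_equal(dice(s1, s2), dice(m1, m2))
  expect_equal(weighted_dice(s1, s2), weighted_dice(m1, m2))
  expect_equal(bundle_adjacency(s1, s2), bundle_adjacency(m1, m2))
})
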