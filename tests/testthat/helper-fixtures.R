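# Shared fixtures and independent brute-force oracles.

# straight streamline along +x at a given y/z offset
line_streamline <- function(x0, x1, y = 0.5, z = 0.5, n = 2L) {
  cbind(seq(x0, x1, length.out = n), y, z)
}

# a smooth U-arc (half circle) in the xy plane
u_arc_streamline <- function(center = c(10, 10, 10), radius = 8, n = 25L) {
  th <- seq(0, pi, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), center[3])
}

# near-closed loop (should trip the looping rule)
loop_streamline <- function(center = c(10, 10, 10), radius = 6, n = 30L) {
  th <- seq(0, 1.8 * pi, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), center[3])
}

# a parallel "tube" bundle of straight streamlines for metric fixtures
tube_bundle <- function(n = 9L, x0 = 1.2, x1 = 8.7, spread = 1) {
  offs <- expand.grid(dy = seq(-spread, spread, length.out = 3),
                      dz = seq(-spread, spread, length.out = 3))
  offs <- offs[seq_len(n), , drop = FALSE]
  bundle(lapply(seq_len(n), function(i) {
    line_streamline(x0, x1, y = 5.5 + offs$dy[i], z = 5.5 + offs$dz[i], n = 6L)
  }))
}

# construct a density map directly from a dense array (test-only container)
density_from_array <- function(arr, voxel_size = 1, origin = c(0, 0, 0)) {
  grid <- grid_spec(voxel_size, origin, dim(arr))
  idx <- which(arr != 0, arr.ind = TRUE)
  voxels <- tibble::tibble(
    i = as.integer(idx[, 1] - 1L), j = as.integer(idx[, 2] - 1L),
    k = as.integer(idx[, 3] - 1L), count = as.integer(arr[idx])
  )
  voxels <- voxels[order(voxels$k, voxels$j, voxels$i), ]
  structure(list(grid = grid, voxels = voxels), class = "saf_density")
}

random_density <- function(shape = c(8, 8, 8), n_occupied = 12L,
                           voxel_size = 1, origin = c(0, 0, 0)) {
  arr <- array(0L, dim = shape)
  pick <- sample(prod(shape), n_occupied)
  arr[pick] <- sample(1:9, n_occupied, replace = TRUE)
  density_from_array(arr, voxel_size, origin)
}

# --- independent oracles (plain loops over dense arrays) ------------------

oracle_dice <- function(a, b) {
  A <- density_array(a) > 0
  B <- density_array(b) > 0
  if (!any(A) && !any(B)) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

oracle_wdice <- function(a, b) {
  A <- density_array(a)
  B <- density_array(b)
  wa <- A / sum(A)
  wb <- B / sum(B)
  shared <- A > 0 & B > 0
  (sum(wa[shared]) + sum(wb[shared])) / 2
}

oracle_ba <- function(a, b) {
  vs <- a$grid$voxel_size
  centers <- function(arr) {
    idx <- which(arr > 0, arr.ind = TRUE)
    sweep((idx - 0.5) * vs, 2, a$grid$origin, "+")
  }
  A <- density_array(a) > 0
  B <- density_array(b) > 0
  ca <- centers(A)
  cb <- centers(B)
  in_other <- function(arr1, arr2) arr1 & arr2
  dir_mean <- function(from_arr, to_pts, both) {
    idx <- which(from_arr & !both, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    pts <- sweep((idx - 0.5) * vs, 2, a$grid$origin, "+")
    mean(vapply(seq_len(nrow(pts)), function(r) {
      min(sqrt(colSums((t(to_pts) - pts[r, ])^2)))
    }, numeric(1)))
  }
  both <- in_other(A, B)
  d <- c(dir_mean(A, cb, both), dir_mean(B, ca, both))
  if (length(d) == 0L) return(0)
  mean(d)
}

# dense supersampling voxelization oracle: sample each segment at a fine
# step, map points to voxels, deduplicate per streamline; the step must be
# much smaller than a voxel or genuinely corner-clipped voxels are missed
oracle_voxel_counts <- function(b, grid, step_frac = 1 / 5000) {
  vs <- grid$voxel_size
  step <- vs * step_frac
  all_keys <- lapply(b$streamlines, function(s) {
    keys <- c()
    for (seg in seq_len(nrow(s) - 1L)) {
      p0 <- s[seg, ]; p1 <- s[seg + 1L, ]
      len <- sqrt(sum((p1 - p0)^2))
      ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      pts <- cbind(p0[1] + ts * (p1[1] - p0[1]),
                   p0[2] + ts * (p1[2] - p0[2]),
                   p0[3] + ts * (p1[3] - p0[3]))
      ijk <- floor(sweep(pts, 2, grid$origin) / vs)
      keys <- c(keys, ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]))
    }
    unique(keys)
  })
  tab <- table(unlist(all_keys))
  stats::setNames(as.integer(tab), names(tab))
}

# package density map as a comparable named count vector
density_count_vector <- function(map) {
  keys <- map$voxels$i + map$grid$shape[1] *
    (map$voxels$j + map$grid$shape[2] * map$voxels$k)
  stats::setNames(map$voxels$count, as.character(keys))
}

# small recovery phantom profile used across tests
recovery_profile <- function() {
  prof <- phantom_connection_profile()[1:5, ]
  prof$presence_probability <- c(0.95, 0.65, 0.30, 0.95, 0.05)
  prof$plausible_mode <- c("u_arc", "u_arc", "u_arc", "spurious", "u_arc")
  prof$histology_status <- c("present", "present", "present", "present", "absent")
  prof
}
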