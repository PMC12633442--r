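# Voxel grids and streamline density (track-density) maps.

#' Define an isotropic voxel grid
#'
#' World coordinates are RAS millimetres. Voxel indices are 0-based; voxel
#' `(i, j, k)` covers the half-open interval
#' `[origin + c(i,j,k) * voxel_size, origin + c(i+1,j+1,k+1) * voxel_size)`,
#' so a point maps to a voxel by flooring after the origin shift. Only
#' isotropic grids are supported (the reference pipeline resamples to
#' 1 mm^3).
#'
#' @param voxel_size Isotropic voxel edge in mm (single positive number).
#' @param origin World coordinate of the corner of voxel (0, 0, 0).
#' @param shape Integer vector of 3 positive extents.
#' @return An object of class `saf_grid`.
#' @export
grid_spec <- function(voxel_size = 1, origin = c(0, 0, 0), shape) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("voxel_size must be a single positive number (isotropic grids only)",
          class = "safconn_invalid_config")
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    abort("origin must be a finite 3-vector", class = "safconn_invalid_config")
  }
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape <= 0L)) {
    abort("shape must be 3 positive integers", class = "safconn_invalid_config")
  }
  structure(list(voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), shape = shape),
            class = "saf_grid")
}

#' @export
print.saf_grid <- function(x, ...) {
  cat("<saf_grid> ", paste(x$shape, collapse = " x "), " voxels at ",
      x$voxel_size, " mm, origin (", paste(x$origin, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    abs(a$voxel_size - b$voxel_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

# Linear key of 0-based voxel indices (column-major), as doubles.
voxel_key <- function(ijk, shape) {
  ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3])
}

key_to_ijk <- function(key, shape) {
  i <- key %% shape[1]
  rest <- (key - i) / shape[1]
  j <- rest %% shape[2]
  k <- (rest - j) / shape[2]
  cbind(i = i, j = j, k = k)
}

# Exact voxel traversal of one polyline: for every segment, collect the
# parameters where it crosses integer voxel planes, then identify the voxel
# of each inter-crossing interval from its midpoint. Returns unique 0-based
# voxel keys visited by the streamline.
traverse_streamline <- function(s, grid) {
  u <- sweep(s, 2, grid$origin) / grid$voxel_size  # voxel-frame coordinates
  keys <- vector("list", nrow(u) - 1L)
  for (seg in seq_len(nrow(u) - 1L)) {
    p0 <- u[seg, ]
    p1 <- u[seg + 1L, ]
    ts <- 0
    for (ax in 1:3) {
      d <- p1[ax] - p0[ax]
      if (d == 0) next
      lo <- ceiling(min(p0[ax], p1[ax]))
      hi <- floor(max(p0[ax], p1[ax]))
      if (hi >= lo) ts <- c(ts, (lo:hi - p0[ax]) / d)
    }
    ts <- sort(unique(c(ts[ts >= 0 & ts <= 1], 1)))
    mids <- (ts[-length(ts)] + ts[-1]) / 2
    pts <- cbind(p0[1] + mids * (p1[1] - p0[1]),
                 p0[2] + mids * (p1[2] - p0[2]),
                 p0[3] + mids * (p1[3] - p0[3]))
    keys[[seg]] <- voxel_key(floor(pts), grid$shape)
  }
  unique(unlist(keys))
}

#' Voxelize a bundle into a streamline density map
#'
#' Counts, for every voxel, the number of distinct streamlines whose path
#' intersects it. Intersection is determined by exact segment traversal
#' (every voxel a segment passes through counts, not only sampled points)
#' and each streamline contributes at most once per voxel, following the
#' track-density imaging convention.
#'
#' @param b A `saf_bundle`; all points must fall inside the grid.
#' @param grid A [grid_spec()].
#' @return An object of class `saf_density`: the grid plus a sparse tibble
#'   `voxels` with 0-based indices `i`, `j`, `k` and streamline `count`.
#' @export
compute_density_map <- function(b, grid) {
  for (idx in seq_along(b$streamlines)) {
    u <- sweep(b$streamlines[[idx]], 2, grid$origin) / grid$voxel_size
    if (any(u < 0) || any(sweep(u, 2, grid$shape, ">="))) {
      abort(paste0("streamline ", idx, " has points outside the grid"),
            class = "safconn_bounds_error")
    }
  }
  keys <- unlist(lapply(b$streamlines, traverse_streamline, grid = grid))
  if (is.null(keys) || length(keys) == 0L) {
    voxels <- tibble(i = integer(), j = integer(), k = integer(),
                     count = integer())
  } else {
    tab <- table(keys)
    key_vals <- as.numeric(names(tab))
    ijk <- key_to_ijk(key_vals, grid$shape)
    voxels <- tibble(i = as.integer(ijk[, "i"]), j = as.integer(ijk[, "j"]),
                     k = as.integer(ijk[, "k"]),
                     count = as.integer(tab)) |>
      arrange(.data$k, .data$j, .data$i)
  }
  new_density(grid, voxels)
}

new_density <- function(grid, voxels) {
  structure(list(grid = grid, voxels = voxels), class = "saf_density")
}

#' @export
print.saf_density <- function(x, ...) {
  cat("<saf_density> ", nrow(x$voxels), " occupied voxels, max count ",
      if (nrow(x$voxels)) max(x$voxels$count) else 0L, "\n", sep = "")
  invisible(x)
}

density_keys <- function(map) {
  voxel_key(cbind(map$voxels$i, map$voxels$j, map$voxels$k), map$grid$shape)
}

#' Convert a density map to a dense 3-D array
#'
#' @param map A `saf_density`.
#' @return An integer array with the grid's shape.
#' @export
density_array <- function(map) {
  arr <- array(0L, dim = map$grid$shape)
  if (nrow(map$voxels)) {
    arr[cbind(map$voxels$i + 1L, map$voxels$j + 1L, map$voxels$k + 1L)] <-
      map$voxels$count
  }
  arr
}

#' Write a density map as a NIfTI-1 volume
#'
#' The affine is diagonal with the isotropic voxel size and translates voxel
#' index (0, 0, 0) to the world coordinate of that voxel's centre, so a
#' round trip through [read_density_nifti()] preserves grid and counts
#' exactly.
#'
#' @param map A `saf_density`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_density_nifti <- function(map, path) {
  vs <- map$grid$voxel_size
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- map$grid$origin + vs / 2
  img <- RNifti::asNifti(density_array(map))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a density map from a NIfTI-1 volume
#'
#' Requires an axis-aligned isotropic affine, as written by
#' [write_density_nifti()].
#'
#' @param path Path to a NIfTI volume.
#' @return A `saf_density`.
#' @export
read_density_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vs <- aff[1, 1]
  if (any(abs(aff[1:3, 1:3] - diag(rep(vs, 3))) > 1e-6) || vs <= 0) {
    abort("NIfTI volume is not an axis-aligned isotropic grid",
          class = "safconn_invalid_config")
  }
  arr <- as.array(img)
  grid <- grid_spec(voxel_size = vs, origin = aff[1:3, 4] - vs / 2,
                    shape = dim(arr))
  idx <- which(arr != 0, arr.ind = TRUE)
  voxels <- tibble(i = as.integer(idx[, 1] - 1L), j = as.integer(idx[, 2] - 1L),
                   k = as.integer(idx[, 3] - 1L),
                   count = as.integer(arr[idx])) |>
    arrange(.data$k, .data$j, .data$i)
  new_density(grid, voxels)
}
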