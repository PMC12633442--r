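# Synthetic U-fiber phantom population with known ground truth.
#
# The phantom emulates the geometry the pipeline consumes -- populations of
# short, U-shaped streamline bundles between cortical patch ROIs placed on a
# hemispheric shell, generated directly in a common grid (standing in for
# template-space alignment) -- so that voxelization, cleaning, observation,
# classification and reliability can all be exercised without diffusion data.

# Deterministic sub-seed scheme: one global seed expands to a
# per-(subject, session, connection) seed through a chain of Lehmer steps,
# so any single bundle is regenerable in isolation.
phantom_subseed <- function(base, subject, session, conn_index) {
  mix <- function(h, x) ((h + x + 1) * 48271) %% 2147483647
  h <- mix(base %% 2147483647, subject)
  h <- mix(h, session)
  h <- mix(h, conn_index)
  as.integer(h)
}

unit <- function(v) v / sqrt(sum(v * v))

quad_bezier <- function(p0, ctrl, p1, n_points) {
  t <- seq(0, 1, length.out = n_points)
  b <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  b %*% rbind(p0, ctrl, p1)
}

arc_through <- function(ca, cb, apex, n_points = 64L) {
  quad_bezier(ca, 2 * apex - (ca + cb) / 2, cb, n_points)
}

#' Lay out phantom ROIs on a hemispheric shell
#'
#' Places the 14 atlas areas as spherical patch ROIs on a deterministic
#' Fibonacci lattice over a hemispheric cap, so that the U-arcs of all 91
#' area pairs have feasible short-range lengths (38-125 mm). The seed
#' rotates the lattice azimuthally; the same seed always yields the same
#' layout.
#'
#' @param seed Integer seed (azimuthal rotation of the lattice).
#' @param grid Common voxel grid (default 120^3 at 1 mm).
#' @param roi_radius_mm ROI sphere radius (default 6).
#' @param shell_radius_mm Radius of the cortical shell (default 54).
#' @param arc_depth_mm U-arc depth used for the feasibility check
#   (default 14).
#' @return An object of class `saf_layout` with the grid, the named 14 x 3
#'   matrix of ROI centres, and the shell geometry.
#' @export
phantom_layout <- function(seed = 1L, grid = grid_spec(1, c(0, 0, 0), c(120, 120, 120)),
                           roi_radius_mm = 6, shell_radius_mm = 54,
                           arc_depth_mm = 14) {
  n <- 14L
  shell_center <- grid$origin + grid$shape * grid$voxel_size / 2 -
    c(0, 0, 0.08 * grid$shape[3] * grid$voxel_size)
  golden <- pi * (3 - sqrt(5))
  phi0 <- (seed %% 997L) * 2 * pi / 997
  k <- seq_len(n)
  # polar angles over a cap of half-angle ~75 degrees
  cos_cap <- cos(75 * pi / 180)
  costheta <- 1 - (1 - cos_cap) * (k - 0.5) / n
  sintheta <- sqrt(1 - costheta^2)
  phi <- phi0 + k * golden
  centers <- shell_radius_mm * cbind(sintheta * cos(phi),
                                     sintheta * sin(phi),
                                     costheta)
  centers <- sweep(centers, 2, shell_center, "+")
  rownames(centers) <- pfc_area_order
  layout <- structure(
    list(grid = grid, centers = centers, roi_radius_mm = roi_radius_mm,
         shell_center = shell_center, shell_radius_mm = shell_radius_mm,
         arc_depth_mm = arc_depth_mm, seed = as.integer(seed)),
    class = "saf_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  grid <- layout$grid
  upper <- grid$origin + grid$shape * grid$voxel_size
  r <- layout$roi_radius_mm
  inside <- apply(layout$centers, 1, function(c) {
    all(c - r >= grid$origin) && all(c + r < upper)
  })
  if (!all(inside)) {
    abort("ROI spheres do not fit inside the grid",
          class = "safconn_invalid_config")
  }
  d <- as.matrix(stats::dist(layout$centers))
  diag(d) <- Inf
  if (min(d) <= 2 * r) {
    abort("ROI spheres overlap; reduce roi_radius_mm or enlarge the shell",
          class = "safconn_invalid_config")
  }
  keys <- pfc_connections()
  lens <- vapply(seq_len(nrow(keys)), function(i) {
    ca <- layout$centers[keys$area_a[i], ]
    cb <- layout$centers[keys$area_b[i], ]
    mid <- (ca + cb) / 2
    apex <- mid + layout$arc_depth_mm * unit(layout$shell_center - mid)
    streamline_length(arc_through(ca, cb, apex))
  }, numeric(1))
  if (any(lens < 38) || any(lens > 125)) {
    abort(paste0("layout yields arc lengths outside [38, 125] mm (range ",
                 round(min(lens), 1), "-", round(max(lens), 1), ")"),
          class = "safconn_invalid_config")
  }
  invisible(layout)
}

#' @export
print.saf_layout <- function(x, ...) {
  cat("<saf_layout> 14 ROIs (radius ", x$roi_radius_mm, " mm) on a ",
      x$shell_radius_mm, " mm shell\n", sep = "")
  invisible(x)
}

#' Per-connection generative profile from a histology reference
#'
#' Default study-condition profile: connections with histological
#' precedence are generated as plausible U-arc bundles present in 90% of
#' subjects, connections without precedence in 5%.
#'
#' @param reference Histology reference tibble.
#' @param present_probability,absent_probability Presence probabilities.
#' @return A tibble with columns `area_a`, `area_b`, `histology_status`,
#'   `presence_probability`, `plausible_mode`.
#' @export
phantom_connection_profile <- function(reference = histology_reference(),
                                       present_probability = 0.9,
                                       absent_probability = 0.05) {
  tibble(
    area_a = reference$area_a, area_b = reference$area_b,
    histology_status = reference$histology_status,
    presence_probability = ifelse(reference$histology_status == "present",
                                  present_probability, absent_probability),
    plausible_mode = "u_arc"
  )
}

#' Phantom population configuration
#'
#' @param n_subjects Number of subjects (default 50).
#' @param sessions 1 or 2 (2 adds a test-retest rescan).
#' @param seed Global seed; expands deterministically to
#'   per-(subject, session, connection) sub-seeds.
#' @param connections Per-connection profile tibble with columns `area_a`,
#'   `area_b`, `presence_probability`, `plausible_mode`
#'   (`"u_arc"`/`"spurious"`), and optionally `histology_status`;
#'   default [phantom_connection_profile()].
#' @param n_streamlines Streamlines per generated bundle (default 800).
#' @param arc_depth_mm U-arc depth below the shell chord (default 14).
#' @param streamline_jitter_sd_mm Within-bundle control-point jitter
#'   (default 1.5) giving the bundle its tubular spread.
#' @param subject_jitter_sd_mm Between-subject rigid displacement of a
#'   bundle (default 3), the anatomical individuality of the phantom.
#' @param session_jitter_sd_mm Additional test-retest displacement
#'   (default 1); smaller than the subject jitter so that within-subject
#'   agreement dominates between-subject agreement.
#' @return An object of class `saf_phantom_config`.
#' @export
phantom_config <- function(n_subjects = 50L, sessions = 1L, seed = 1L,
                           connections = phantom_connection_profile(),
                           n_streamlines = 800L, arc_depth_mm = 14,
                           streamline_jitter_sd_mm = 1.5,
                           subject_jitter_sd_mm = 3,
                           session_jitter_sd_mm = 1) {
  if (!sessions %in% c(1L, 2L)) {
    abort("sessions must be 1 or 2", class = "safconn_invalid_config")
  }
  sds <- c(streamline_jitter_sd_mm, subject_jitter_sd_mm, session_jitter_sd_mm)
  if (any(sds < 0)) {
    abort("jitter standard deviations must be >= 0",
          class = "safconn_invalid_config")
  }
  needed <- c("area_a", "area_b", "presence_probability", "plausible_mode")
  if (!all(needed %in% names(connections))) {
    abort(paste0("connections must have columns ",
                 paste(needed, collapse = ", ")),
          class = "safconn_invalid_config")
  }
  if (any(connections$presence_probability < 0 |
            connections$presence_probability > 1)) {
    abort("presence_probability must lie in [0, 1]",
          class = "safconn_invalid_config")
  }
  if (!all(connections$plausible_mode %in% c("u_arc", "spurious"))) {
    abort("plausible_mode must be 'u_arc' or 'spurious'",
          class = "safconn_invalid_config")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sessions = as.integer(sessions),
         seed = as.integer(seed), connections = as_tibble(connections),
         n_streamlines = as.integer(n_streamlines),
         arc_depth_mm = arc_depth_mm,
         streamline_jitter_sd_mm = streamline_jitter_sd_mm,
         subject_jitter_sd_mm = subject_jitter_sd_mm,
         session_jitter_sd_mm = session_jitter_sd_mm),
    class = "saf_phantom_config"
  )
}

# Gaussian offsets clamped to stay strictly inside a ball of given radius.
clamped_offsets <- function(n, sd, radius) {
  x <- matrix(rnorm(3L * n, sd = sd), n, 3L)
  norms <- sqrt(rowSums(x * x))
  scale <- pmin(1, (0.99 * radius) / pmax(norms, .Machine$double.eps))
  x * scale
}

#' Generate one plausible U-arc bundle
#'
#' Streamlines are quadratic Bezier arcs from points inside the ROI sphere
#' of one area to points inside the other, with the apex displaced
#' `arc_depth_mm` from the chord midpoint towards the shell interior and
#' per-streamline Gaussian control-point jitter. All endpoints lie inside
#' the ROI spheres and every streamline is at most 125 mm long;
#' deterministic for a given seed.
#'
#' @param layout A [phantom_layout()].
#' @param area_a,area_b Connection endpoints.
#' @param config A [phantom_config()].
#' @param seed Sub-seed for this bundle.
#' @param n_points Points per streamline (default 32).
#' @return A `saf_bundle`.
#' @export
generate_u_bundle <- function(layout, area_a, area_b, config, seed,
                              n_points = 32L) {
  key <- connection_key(area_a, area_b)
  set.seed(seed)
  ca <- layout$centers[key$area_a, ]
  cb <- layout$centers[key$area_b, ]
  mid <- (ca + cb) / 2
  apex <- mid + config$arc_depth_mm * unit(layout$shell_center - mid)
  n <- config$n_streamlines
  jit <- config$streamline_jitter_sd_mm
  e0 <- sweep(clamped_offsets(n, jit, layout$roi_radius_mm), 2, ca, "+")
  e1 <- sweep(clamped_offsets(n, jit, layout$roi_radius_mm), 2, cb, "+")
  cjit <- matrix(rnorm(3L * n, sd = jit), n, 3L)
  t <- seq(0, 1, length.out = n_points)
  basis <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  streamlines <- lapply(seq_len(n), function(i) {
    ctrl <- 2 * apex - (e0[i, ] + e1[i, ]) / 2 + cjit[i, ]
    basis %*% rbind(e0[i, ], ctrl, e1[i, ])
  })
  lens <- vapply(streamlines, streamline_length, numeric(1))
  if (any(lens > 125)) {
    abort("generated arc exceeds the 125 mm short-range cap",
          class = "safconn_invalid_config")
  }
  bundle(streamlines, area_a = key$area_a, area_b = key$area_b)
}

#' Generate one spurious (implausible) bundle
#'
#' Emulates anatomically implausible tractography output: three quarters of
#' the streamlines are near-closed loops (end-to-end distance well below a
#' quarter of their path length) and the rest are erratic piecewise-linear
#' detours with abrupt directional changes. Such bundles fail
#' [plausibility_heuristic()] by construction; deterministic per seed.
#'
#' @inheritParams generate_u_bundle
#' @return A `saf_bundle`.
#' @export
generate_spurious_bundle <- function(layout, area_a, area_b, config, seed,
                                     n_points = 40L) {
  key <- connection_key(area_a, area_b)
  set.seed(seed)
  ca <- layout$centers[key$area_a, ]
  cb <- layout$centers[key$area_b, ]
  mid <- (ca + cb) / 2
  n <- config$n_streamlines
  n_loops <- ceiling(0.75 * n)
  streamlines <- vector("list", n)
  for (i in seq_len(n)) {
    center <- mid + rnorm(3, sd = 4)
    if (i <= n_loops) {
      # near-closed planar loop
      q <- qr.Q(qr(matrix(rnorm(9), 3)))[, 1:2]
      rho <- runif(1, 7, 11)
      sweep_ang <- runif(1, 300, 340) * pi / 180
      th <- seq(0, sweep_ang, length.out = n_points)
      pts <- sweep(rho * (outer(cos(th), q[, 1]) + outer(sin(th), q[, 2])),
                   2, center, "+")
    } else {
      # erratic detour through random waypoints
      pts <- sweep(matrix(rnorm(6L * 3L, sd = 8), 6L, 3L), 2, center, "+")
    }
    streamlines[[i]] <- pts
  }
  bundle(streamlines, area_a = key$area_a, area_b = key$area_b)
}

#' Generate a phantom population
#'
#' For each subject and connection, presence is drawn once (Bernoulli with
#' the connection's `presence_probability`) and shared by both sessions --
#' the phantom's anatomy is a subject-level property that rescans
#' re-measure. Present bundles are generated in the common grid, rigidly
#' displaced by a per-subject jitter (anatomical individuality) plus a
#' per-session jitter (scan-rescan wobble), with independent streamline
#' draws per session (independent tracking runs). Everything derives
#' deterministically from `config$seed`.
#'
#' @param layout A [phantom_layout()].
#' @param config A [phantom_config()].
#' @param write_dir Optional directory; when given, one `.tck` file per
#'   present bundle, an ROI label volume, the truth table and a config echo
#'   are written there.
#' @return An object of class `saf_phantom`: `bundles` (tibble with
#'   list-column `bundle`; absent bundles are empty), `truth` (per
#'   subject x session x connection generative record), `layout`, `config`.
#' @export
generate_population <- function(layout, config, write_dir = NULL) {
  conns <- config$connections
  key <- connection_key(conns$area_a, conns$area_b)
  sessions <- if (config$sessions == 2L) c("test", "retest") else "test"
  n_rows <- config$n_subjects * nrow(conns) * length(sessions)
  col <- list(subject_id = character(n_rows), session = character(n_rows),
              area_a = character(n_rows), area_b = character(n_rows),
              present = logical(n_rows), mode = character(n_rows),
              disp_x = numeric(n_rows), disp_y = numeric(n_rows),
              disp_z = numeric(n_rows), sub_seed = integer(n_rows))
  bundles <- vector("list", n_rows)
  r <- 0L
  for (s in seq_len(config$n_subjects)) {
    subject_id <- sprintf("sub-%03d", s)
    for (ci in seq_len(nrow(conns))) {
      anat_seed <- phantom_subseed(config$seed, s, 0L, ci)
      set.seed(anat_seed)
      present <- runif(1) < conns$presence_probability[ci]
      subj_disp <- rnorm(3) * config$subject_jitter_sd_mm
      for (sess_i in seq_along(sessions)) {
        sub_seed <- phantom_subseed(config$seed, s, sess_i, ci)
        if (present) {
          gen <- if (conns$plausible_mode[ci] == "u_arc") {
            generate_u_bundle
          } else {
            generate_spurious_bundle
          }
          b <- gen(layout, key$area_a[ci], key$area_b[ci], config, sub_seed)
          set.seed(sub_seed + 1L)
          sess_disp <- rnorm(3) * config$session_jitter_sd_mm
          disp <- subj_disp + sess_disp
          b$streamlines <- lapply(b$streamlines, function(m) sweep(m, 2, disp, "+"))
        } else {
          b <- bundle(list(), area_a = key$area_a[ci], area_b = key$area_b[ci])
          disp <- c(NA_real_, NA_real_, NA_real_)
        }
        b$subject_id <- subject_id
        b$session <- sessions[sess_i]
        r <- r + 1L
        bundles[[r]] <- b
        col$subject_id[r] <- subject_id
        col$session[r] <- sessions[sess_i]
        col$area_a[r] <- key$area_a[ci]
        col$area_b[r] <- key$area_b[ci]
        col$present[r] <- present
        col$mode[r] <- conns$plausible_mode[ci]
        col$disp_x[r] <- disp[1]; col$disp_y[r] <- disp[2]; col$disp_z[r] <- disp[3]
        col$sub_seed[r] <- sub_seed
      }
    }
  }
  bundle_tbl <- tibble(subject_id = col$subject_id, session = col$session,
                       area_a = col$area_a, area_b = col$area_b,
                       bundle = bundles)
  truth <- tibble(subject_id = col$subject_id, session = col$session,
                  area_a = col$area_a, area_b = col$area_b,
                  generated_present = col$present,
                  plausible_mode = col$mode,
                  disp_x = col$disp_x, disp_y = col$disp_y,
                  disp_z = col$disp_z, sub_seed = col$sub_seed)
  pop <- structure(
    list(bundles = bundle_tbl, truth = truth, layout = layout,
         config = config),
    class = "saf_phantom"
  )
  if (!is.null(write_dir)) write_population(pop, write_dir)
  pop
}

#' @export
print.saf_phantom <- function(x, ...) {
  cat("<saf_phantom> ", x$config$n_subjects, " subjects x ",
      nrow(x$config$connections), " connections x ", x$config$sessions,
      " session(s); ", sum(x$truth$generated_present), " present bundles\n",
      sep = "")
  invisible(x)
}

roi_label_array <- function(layout) {
  grid <- layout$grid
  arr <- array(0L, dim = grid$shape)
  vs <- grid$voxel_size
  r <- layout$roi_radius_mm
  for (a in seq_len(nrow(layout$centers))) {
    c_vox <- (layout$centers[a, ] - grid$origin) / vs
    rng <- lapply(1:3, function(ax) {
      lo <- max(0L, floor(c_vox[ax] - r / vs))
      hi <- min(grid$shape[ax] - 1L, ceiling(c_vox[ax] + r / vs))
      lo:hi
    })
    idx <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    centers <- sweep(idx + 0.5, 2, c_vox)
    inside <- rowSums((centers * vs)^2) <= r^2
    arr[idx[inside, , drop = FALSE] + 1L] <- a
  }
  arr
}

write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- pop$layout$grid
  vs <- grid$voxel_size
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- grid$origin + vs / 2
  img <- RNifti::asNifti(roi_label_array(pop$layout))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file.path(dir, "roi_labels.nii.gz"))
  present <- pop$bundles[vapply(pop$bundles$bundle, length, integer(1)) > 0L, ]
  for (i in seq_len(nrow(present))) {
    b <- present$bundle[[i]]
    fname <- sprintf("%s_%s_%s-%s.tck", b$subject_id, b$session,
                     gsub("/", "x", b$area_a), gsub("/", "x", b$area_b))
    write_tck(b, file.path(dir, fname))
  }
  write.csv(pop$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- pop$config
  cfg$connections <- as.data.frame(cfg$connections)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Expected population label of a phantom connection
#'
#' The label the classifier should recover given the generative profile:
#' derived from the presence probability, plausibility mode and histology
#' status under the classification thresholds.
#'
#' @param presence_probability,plausible_mode,histology_status Generative
#'   profile columns (vectorized).
#' @param config A [classification_config()].
#' @return Character vector of expected labels.
#' @export
expected_outcome <- function(presence_probability, plausible_mode,
                             histology_status,
                             config = classification_config()) {
  pop_present <- presence_probability > config$presence_fraction
  robust <- presence_probability > config$rtp_fraction
  plausible <- plausible_mode == "u_arc"
  ifelse(histology_status == "present",
         ifelse(!pop_present, "FN",
                ifelse(!plausible, "FP", ifelse(robust, "RTP", "TP"))),
         ifelse(pop_present, "FP", "TN"))
}
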