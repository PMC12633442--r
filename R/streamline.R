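# Streamline bundles: construction, lengths, length filtering, outlier
# rejection.

#' Construct a streamline bundle
#'
#' A bundle is the set of streamlines connecting one area pair in one
#' subject (possibly empty, for an absent connection). Each streamline is an
#' n x 3 matrix of RAS world coordinates in millimetres with at least two
#' points and non-zero path length.
#'
#' @param streamlines List of numeric matrices (n_i x 3), possibly empty.
#' @param area_a,area_b Optional connection endpoints (canonicalized).
#' @param subject_id Optional subject identifier.
#' @param session Optional session label (`"test"`, `"retest"`, or `NA`).
#' @return An object of class `saf_bundle`.
#' @export
bundle <- function(streamlines = list(), area_a = NA_character_,
                   area_b = NA_character_, subject_id = NA_character_,
                   session = NA_character_) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L || nrow(s) < 2L) {
      abort("each streamline must be a matrix of >= 2 points in 3-D",
            class = "safconn_invalid_streamline")
    }
    if (!all(is.finite(s))) {
      abort("streamline coordinates must be finite",
            class = "safconn_invalid_streamline")
    }
    if (streamline_length(s) <= 0) {
      abort("streamline must have positive path length",
            class = "safconn_invalid_streamline")
    }
    dimnames(s) <- NULL
    s
  })
  if (!is.na(area_a) && !is.na(area_b)) {
    key <- connection_key(area_a, area_b)
    area_a <- key$area_a
    area_b <- key$area_b
  }
  structure(
    list(streamlines = streamlines, area_a = area_a, area_b = area_b,
         subject_id = subject_id, session = session),
    class = "saf_bundle"
  )
}

#' @export
print.saf_bundle <- function(x, ...) {
  conn <- if (is.na(x$area_a)) "<unassigned>" else paste0(x$area_a, "-", x$area_b)
  cat("<saf_bundle> ", length(x$streamlines), " streamlines, connection ",
      conn, "\n", sep = "")
  invisible(x)
}

#' @export
length.saf_bundle <- function(x) length(x$streamlines)

#' Streamline path length
#'
#' Sum of Euclidean segment lengths of one streamline, in millimetres.
#'
#' @param s An n x 3 coordinate matrix.
#' @return Length in mm.
#' @export
streamline_length <- function(s) {
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Path lengths of every streamline in a bundle
#'
#' @param b A `saf_bundle`.
#' @return Numeric vector of lengths in mm (length 0 for an empty bundle).
#' @export
bundle_lengths <- function(b) {
  vapply(b$streamlines, streamline_length, numeric(1))
}

#' Per-connection tract configuration
#'
#' Carries the per-tract maximum length used for short-range fiber
#' selection (38-125 mm, varied per tract in the reference pipeline), the
#' streamline budget (1,000 per run, two seeding runs, so a 2,000-streamline
#' ceiling per tract), and the minimum cleaned streamline count for a
#' subject-level presence call.
#'
#' @param area_a,area_b Connection endpoints (optional).
#' @param max_length_mm Maximum streamline length retained, in \[38, 125\].
#' @param streamlines_per_run Streamlines generated per seeding run.
#' @param runs Number of seeding runs summed per tract.
#' @param min_streamlines_present Presence threshold on the cleaned count.
#' @return An object of class `saf_tract_spec`.
#' @export
tract_spec <- function(area_a = NA_character_, area_b = NA_character_,
                       max_length_mm = 125, streamlines_per_run = 1000L,
                       runs = 2L, min_streamlines_present = 5L) {
  if (!is.numeric(max_length_mm) || length(max_length_mm) != 1L ||
      max_length_mm < 38 || max_length_mm > 125) {
    abort("max_length_mm must be a single value in [38, 125]",
          class = "safconn_invalid_config")
  }
  structure(
    list(area_a = area_a, area_b = area_b, max_length_mm = max_length_mm,
         streamlines_per_run = as.integer(streamlines_per_run),
         runs = as.integer(runs),
         max_streamlines = as.integer(runs) * as.integer(streamlines_per_run),
         min_streamlines_present = as.integer(min_streamlines_present)),
    class = "saf_tract_spec"
  )
}

#' Filter a bundle by streamline length
#'
#' Retains exactly the streamlines whose path length does not exceed the
#' tract's maximum length; order is preserved and the operation is
#' idempotent.
#'
#' @param b A `saf_bundle`.
#' @param spec A [tract_spec()] or a bare maximum length in mm.
#' @return The filtered `saf_bundle`.
#' @export
filter_by_length <- function(b, spec) {
  max_len <- if (inherits(spec, "saf_tract_spec")) spec$max_length_mm else {
    tract_spec(max_length_mm = spec)$max_length_mm
  }
  keep <- bundle_lengths(b) <= max_len
  b$streamlines <- b$streamlines[keep]
  b
}

# Resample a streamline to n equidistant points along its arc length.
resample_streamline <- function(s, n_points = 12L) {
  d <- sqrt(rowSums(diff(s)^2))
  cl <- c(0, cumsum(d))
  total <- cl[length(cl)]
  at <- seq(0, total, length.out = n_points)
  # drop zero-length duplicate vertices for interpolation
  keep <- c(TRUE, d > 0)
  cl <- cl[keep]
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 1L) return(matrix(s, n_points, 3, byrow = TRUE))
  cbind(
    stats::approx(cl, s[, 1], xout = at, rule = 2)$y,
    stats::approx(cl, s[, 2], xout = at, rule = 2)$y,
    stats::approx(cl, s[, 3], xout = at, rule = 2)$y
  )
}

# Mean-direct-flip distance matrix between resampled streamlines.
mdf_distance_matrix <- function(resampled) {
  n <- length(resampled)
  flat <- t(vapply(resampled, as.numeric, numeric(length(resampled[[1]]))))
  m <- nrow(resampled[[1]])
  flipped <- t(vapply(resampled, function(r) {
    as.numeric(r[m:1, , drop = FALSE])
  }, numeric(length(resampled[[1]]))))
  # mean point-wise Euclidean distance = sqrt of mean squared per-point dist;
  # compute from squared coordinate distances accumulated per point
  pair_mean_dist <- function(a, bm) {
    out <- matrix(0, nrow(a), nrow(bm))
    for (p in seq_len(m)) {
      cols <- (p - 1L) * 3L + 1:3
      dx <- outer(a[, cols[1]], bm[, cols[1]], "-")
      dy <- outer(a[, cols[2]], bm[, cols[2]], "-")
      dz <- outer(a[, cols[3]], bm[, cols[3]], "-")
      out <- out + sqrt(dx * dx + dy * dy + dz * dz)
    }
    out / m
  }
  direct <- pair_mean_dist(flat, flat)
  flip <- pair_mean_dist(flat, flipped)
  pmin(direct, flip)
}

#' Reject outlier streamlines from a bundle
#'
#' Transparent bundle-cleaning stage: every streamline is resampled to a
#' fixed number of points and compared to the bundle medoid with the
#' mean-direct-flip (MDF) distance, which is symmetric and invariant to
#' endpoint orientation. Streamlines whose distance to the medoid exceeds
#' `median + threshold_factor * MAD` (MAD with the usual 1.4826 consistency
#' scaling) are removed. The medoid itself is never removed and the result
#' is deterministic; bundles with fewer than two streamlines are returned
#' unchanged.
#'
#' @param b A `saf_bundle`.
#' @param threshold_factor Positive multiplier on the MAD (default 3).
#' @param n_points Resampling resolution for the MDF distance.
#' @return The cleaned `saf_bundle` (a subset of the input).
#' @export
reject_outliers <- function(b, threshold_factor = 3, n_points = 12L) {
  if (threshold_factor <= 0) {
    abort("threshold_factor must be > 0", class = "safconn_invalid_config")
  }
  n <- length(b$streamlines)
  if (n < 2L) return(b)
  resampled <- lapply(b$streamlines, resample_streamline, n_points = n_points)
  dmat <- mdf_distance_matrix(resampled)
  medoid <- which.min(colSums(dmat))
  d <- dmat[, medoid]
  thr <- median(d) + threshold_factor * mad(d)
  keep <- d <= thr
  keep[medoid] <- TRUE
  b$streamlines <- b$streamlines[keep]
  b
}
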