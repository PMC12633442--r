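obs_row <- function(present, plausible = TRUE, id = "s") {
  tibble::tibble(subject_id = id, area_a = "8", area_b = "44",
                 n_streamlines_clean = if (present) 100L else 0L,
                 plausible = ifelse(present, plausible, NA),
                 present = present)
}

obs_set <- function(frac_present, n = 20L, plausible = TRUE) {
  n_present <- round(frac_present * n)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    obs_row(i <= n_present, plausible, sprintf("s%02d", i))
  }))
}

test_that("subject presence follows the minimum cleaned streamline count", {
  cfg <- classification_config()
  many <- bundle(replicate(7, u_arc_streamline(), simplify = FALSE),
                 "8", "44", "sub-001")
  o <- observe_subject(many, cfg)
  expect_true(o$present)
  expect_true(o$plausible)
  expect_equal(o$n_streamlines_clean, 7L)

  none <- bundle(area_a = "8", area_b = "44", subject_id = "sub-002")
  expect_false(observe_subject(none, cfg)$present)

  few <- bundle(replicate(3, u_arc_streamline(), simplify = FALSE),
                "8", "44", "sub-003")
  expect_false(observe_subject(few, cfg)$present)
  # threshold is configurable
  expect_true(observe_subject(few, classification_config(
    min_streamlines_present = 2L))$present)
})

test_that("the plausibility heuristic separates smooth arcs from loops", {
  arcs <- bundle(replicate(6, u_arc_streamline(), simplify = FALSE))
  expect_true(plausibility_heuristic(arcs))
  loops <- bundle(replicate(6, loop_streamline(), simplify = FALSE))
  expect_false(plausibility_heuristic(loops))
  expect_true(is.na(plausibility_heuristic(bundle())))
})

test_that("the population decision table yields all five labels", {
  cfg <- classification_config()
  expect_equal(classify_connection(obs_set(0.85), "present", cfg)$outcome_label,
               "RTP")
  expect_equal(classify_connection(obs_set(0.70), "present", cfg)$outcome_label,
               "TP")
  expect_equal(classify_connection(obs_set(0.30), "present", cfg)$outcome_label,
               "FN")
  expect_equal(classify_connection(obs_set(0.70, plausible = FALSE),
                                   "present", cfg)$outcome_label, "FP")
  expect_equal(classify_connection(obs_set(0.70), "absent", cfg)$outcome_label,
               "FP")
  expect_equal(classify_connection(obs_set(0.40), "absent", cfg)$outcome_label,
               "TN")
  # boundary: exactly the presence fraction is not "more than"
  expect_equal(classify_connection(obs_set(0.50), "present", cfg)$outcome_label,
               "FN")

  mixed <- dplyr::bind_rows(obs_row(TRUE), obs_row(TRUE))
  mixed$area_b[2] <- "45"
  expect_error(classify_connection(mixed, "present", cfg),
               class = "safconn_invalid_config")
  expect_error(classification_config(presence_fraction = 0.9,
                                     rtp_fraction = 0.8),
               class = "safconn_invalid_config")
})

test_that("confusion summaries compute the four statistics with NA denominators", {
  mk <- function(labels) {
    tibble::tibble(area_a = pfc_connections()$area_a[seq_along(labels)],
                   area_b = pfc_connections()$area_b[seq_along(labels)],
                   outcome_label = labels)
  }
  even <- summarize_concordance(mk(c("TP", "TN", "FP", "FN")))
  expect_equal(even$accuracy, 50)
  expect_equal(even$sensitivity, 50)
  expect_equal(even$specificity, 50)
  expect_equal(even$precision, 50)

  all_tp <- summarize_concordance(mk(c("TP", "RTP", "TP")))
  expect_equal(all_tp$accuracy, 100)
  expect_equal(all_tp$sensitivity, 100)
  expect_true(is.na(all_tp$specificity))   # zero denominator, not 0 or 100
  expect_equal(all_tp$rtp, 1L)

  expect_error(summarize_concordance(mk(character(0))),
               class = "safconn_outcome_integrity")
})

test_that("display rounding is half-away-from-zero", {
  out <- connection_outcomes()
  s <- summarize_concordance(out)
  expect_equal(s$accuracy, 100 * 66 / 91)     # 72.53, unrounded retained
  expect_equal(s$accuracy_rounded, 73)        # 72.5 rounds up
  expect_equal(safconn:::round_half_up(72.5), 73)
  expect_equal(safconn:::round_half_up(81.25), 81)
})

test_that("partition summaries cover the right connection subsets", {
  out <- connection_outcomes()
  expect_equal(summarize_partition(out, "vlPFC")$n_connections, 36L)
  expect_equal(summarize_partition(out, "FrontalPole")$specificity, 100)
  one <- out[out$area_a == "8" & out$area_b == "9", ]
  expect_error(summarize_partition(one, "ACC"),
               class = "safconn_outcome_integrity")
})

test_that("raising the presence threshold never increases population fractions", {
  lay <- phantom_layout(3)
  prof <- recovery_profile()
  cfg <- phantom_config(n_subjects = 8, seed = 9, connections = prof,
                        n_streamlines = 10)
  pop <- generate_population(lay, cfg)
  fracs <- vapply(c(2L, 5L, 8L, 11L), function(thr) {
    obs <- observe_population(pop$bundles,
                              classification_config(min_streamlines_present = thr))
    mean(obs$present)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})
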