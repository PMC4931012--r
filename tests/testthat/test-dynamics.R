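make_series <- function(subject, days, states) {
  structure(data.frame(subject_id = subject, sample_id = paste0(subject, "_", days),
                       day = days, state = states, stringsAsFactors = FALSE),
            class = c("state_series", "data.frame"))
}

test_that("clusters are named by their top mean family", {
  cfg <- cohort_config(n_subjects = 6, days = c(1, 3, 7, 13, 19, 25))
  coh <- generate_cohort(cfg, seed = 21)
  d <- jsd_matrix(coh$table)
  sol <- pam_cluster(d, 3)
  ser <- assign_states(coh$table, coh$meta, sol)
  expect_setequal(unique(ser$state),
                  c("Bifidobacteriaceae", "Enterobacteriaceae", "Staphylococcaceae"))
  # agreement with the generating regimes at default effect sizes
  truth_name <- c(B = "Bifidobacteriaceae", E = "Enterobacteriaceae",
                  S = "Staphylococcaceae")
  truth <- truth_name[coh$truth$regime[match(ser$sample_id, coh$truth$sample_id)]]
  expect_gte(mean(ser$state == truth), 0.95)
})

test_that("ambiguous cluster naming is rejected without an explicit map", {
  tab <- abundance_table(rbind(s1 = c(A = 0.9, B = 0.1),
                               s2 = c(A = 0.8, B = 0.2),
                               s3 = c(A = 0.85, B = 0.15),
                               s4 = c(A = 0.7, B = 0.3)))
  meta <- sample_metadata(paste0("s", 1:4), "u1", 1:4)
  d <- jsd_matrix(tab)
  sol <- pam_cluster(d, 2)
  expect_error(assign_states(tab, meta, sol), "same top family")
  ser <- assign_states(tab, meta, sol,
                       state_naming = c("1" = "high", "2" = "low"))
  expect_setequal(unique(ser$state), c("high", "low"))
})

test_that("the per-sample dominance rule labels by the argmax family", {
  tab <- abundance_table(rbind(s1 = c(A = 0.9, B = 0.1),
                               s2 = c(A = 0.2, B = 0.8)))
  meta <- sample_metadata(c("s1", "s2"), "u1", 1:2)
  ser <- assign_states(tab, meta, rule = "dominance")
  expect_identical(ser$state, c("A", "B"))
})

test_that("transition counts follow consecutive observed samples", {
  ser <- make_series("u1", c(1, 2, 4, 7, 11), c("S", "S", "E", "E", "B"))
  tc <- transition_counts(ser, states = c("S", "E", "B"))
  expect_equal(tc$counts["S", "S"], 1)
  expect_equal(tc$counts["S", "E"], 1)
  expect_equal(tc$counts["E", "E"], 1)
  expect_equal(tc$counts["E", "B"], 1)
  expect_equal(sum(tc$counts), 4)
  # gaps are bridged and logged
  expect_equal(tc$pairs$gap, c(1, 2, 3, 4))
  # diagonal-only series
  tc2 <- transition_counts(make_series("u1", 1:3, rep("B", 3)))
  expect_equal(sum(tc2$counts) - sum(diag(tc2$counts)), 0)
  expect_error(transition_counts(make_series("u1", 1, "B")), "two or more")
})

test_that("transition totals equal observed samples minus subjects", {
  set.seed(91)
  coh <- generate_cohort(cohort_config(n_subjects = 5, days = c(1, 4, 9, 16, 25)),
                         seed = 14)
  ser <- data.frame(subject_id = coh$meta$subject_id, sample_id = coh$meta$sample_id,
                    day = coh$meta$day,
                    state = coh$truth$regime[match(coh$meta$sample_id,
                                                   coh$truth$sample_id)])
  tc <- transition_counts(ser)
  n_obs <- nrow(ser); n_subj <- length(unique(ser$subject_id))
  expect_equal(sum(tc$counts), n_obs - n_subj)
})

test_that("reversing time transposes the off-diagonal counts", {
  ser <- make_series("u1", 1:6, c("S", "E", "E", "B", "E", "B"))
  tc <- transition_counts(ser, states = c("S", "E", "B"))
  rev_ser <- make_series("u1", 1:6, rev(c("S", "E", "E", "B", "E", "B")))
  tc_rev <- transition_counts(rev_ser, states = c("S", "E", "B"))
  transposed <- t(tc$counts)
  names(dimnames(transposed)) <- c("from", "to")
  expect_identical(tc_rev$counts, transposed)
})

test_that("directionality computes the forward fraction over state changes", {
  counts <- matrix(0, 3, 3, dimnames = list(c("S", "E", "B"), c("S", "E", "B")))
  counts["S", "E"] <- 5; counts["E", "B"] <- 4; counts["B", "E"] <- 1
  tm <- structure(list(counts = counts, states = c("S", "E", "B")),
                  class = "transition_matrix")
  dr <- directionality(tm, order = c("S", "E", "B"))
  expect_equal(dr$forward_fraction, 0.9)
  # no off-diagonal transitions -> undefined, flagged
  tm0 <- structure(list(counts = diag(c(2, 3, 4)) * 1,
                        states = c("S", "E", "B")), class = "transition_matrix")
  dimnames(tm0$counts) <- dimnames(counts)
  dr0 <- directionality(tm0, order = c("S", "E", "B"))
  expect_false(dr0$defined)
  expect_true(is.na(dr0$forward_fraction))
  # symmetric matrix -> 0.5
  sym <- counts * 0; sym["S", "E"] <- 3; sym["E", "S"] <- 3
  tms <- structure(list(counts = sym, states = c("S", "E", "B")),
                   class = "transition_matrix")
  expect_equal(directionality(tms, c("S", "E", "B"))$forward_fraction, 0.5)
  expect_error(directionality(tm, order = c("S", "E")), "outside")
})

test_that("forward-biased synthetic cohorts show directional succession", {
  fwd_ok <- 0
  seeds <- 1:15
  for (s in seeds) {
    coh <- generate_cohort(cohort_config(n_subjects = 8,
                                         days = c(1:7, seq(9, 29, 2))), seed = s)
    ser <- data.frame(subject_id = coh$meta$subject_id,
                      sample_id = coh$meta$sample_id, day = coh$meta$day,
                      state = coh$truth$regime[match(coh$meta$sample_id,
                                                     coh$truth$sample_id)])
    tc <- transition_counts(ser, states = c("S", "E", "B"))
    dr <- directionality(tc, order = c("S", "E", "B"))
    if (isTRUE(dr$forward_fraction > 0.5)) fwd_ok <- fwd_ok + 1
  }
  expect_gte(fwd_ok / length(seeds), 0.95)
})

test_that("state grids export one row per subject with NT for unobserved days", {
  ser <- rbind(make_series("u1", c(1, 3), c("S", "B")),
               make_series("u2", c(1, 2), c("E", "E")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_state_grid(ser, path)
  grid <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  expect_identical(grid$subject_id, c("u1", "u2"))
  expect_identical(grid$day_3, c("B", "NT"))
})
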