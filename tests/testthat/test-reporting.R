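# Batch processing, session summaries and the permutation comparison.

test_that("batches run end to end and tolerate corrupt files", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(nSubjects = 2,
                        exercises = c("half_squat", "mountain_climber"),
                        seed = 9, outDir = dir)
  res <- runBatch(coh)
  expect_identical(nrow(res$metrics), 8L)
  expect_identical(nrow(res$failures), 0L)
  expect_true(all(metricColumns() %in% names(res$metrics)))

  # corrupt one file on disk and re-run from the manifest
  writeLines("garbage", file.path(dir, coh$manifest$file[1]))
  res2 <- suppressMessages(runBatch(coh$manifest, dir = dir))
  expect_identical(nrow(res2$metrics), 7L)
  expect_identical(nrow(res2$failures), 1L)
  expect_identical(res2$failures$file, coh$manifest$file[1])

  expect_error(runBatch(data.frame()), class = "configError")
})

test_that("batch tables are reproducible", {
  coh <- generateCohort(nSubjects = 1, exercises = "split_squat", seed = 3)
  t1 <- runBatch(coh)$metrics
  t2 <- runBatch(coh)$metrics
  expect_identical(t1, t2)
})

test_that("summaries aggregate cells, flag single subjects and rank paces", {
  coh <- generateCohort(nSubjects = 3, seed = 14)
  tab <- runBatch(coh)$metrics
  sm <- summarizeSessions(tab)
  expect_identical(nrow(sm), 10L)           # 5 exercises x 2 sessions
  expect_true(all(sm$n == 3L))
  expect_true(all(!sm$single_subject))
  expect_true(all(sm[paste0(metricColumns(), "_sd")] >= 0))

  # cell means close the loop on the generator's ground truth
  for (k in seq_len(nrow(sm))) {
    truth <- coh$manifest$true_cycle_duration[
      coh$manifest$exercise == sm$exercise[k] &
      coh$manifest$session == sm$session[k]]
    expect_equal(sm$cycle_duration_s_mean[k], mean(truth),
                 tolerance = 0.05)
  }

  # cohorts run faster than the demonstration: all pace ratios below 1
  expect_true(all(sm$pace_ratio < 1))

  # single-subject cells get SD 0 and a flag
  one <- summarizeSessions(tab[tab$subject == "S01", ])
  expect_true(all(one$single_subject))
  expect_true(all(one$cycle_duration_s_sd == 0))
})

test_that("summaries are invariant to row order", {
  coh <- generateCohort(nSubjects = 2, exercises = c("half_squat",
                                                     "clam_advanced"),
                        seed = 8)
  tab <- runBatch(coh)$metrics
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_identical(summarizeSessions(tab), summarizeSessions(shuffled))
})

test_that("the sign-flip permutation comparison behaves at the null", {
  subj <- sprintf("S%02d", 1:8)
  tab <- rbind(
    data.frame(subject = subj, exercise = "half_squat", session = "lab",
               cycle_duration_s = 3 + (1:8) / 10),
    data.frame(subject = subj, exercise = "half_squat", session = "home",
               cycle_duration_s = 3 + (1:8) / 10))
  res <- compareSessions(tab, "cycle_duration_s", "half_squat",
                         nPermutations = 999, seed = 1)
  expect_identical(res$pValue, 1)
  expect_identical(res$statistic, 0)
  expect_identical(res$nPairs, 8L)
})

test_that("the permutation p-value is symmetric under sign flips", {
  subj <- sprintf("S%02d", 1:10)
  set.seed(2)
  lab <- 3 + rnorm(10, 0.3, 0.2)
  home <- 3 + rnorm(10, 0, 0.2)
  mk <- function(lab, home) rbind(
    data.frame(subject = subj, exercise = "half_squat", session = "lab",
               cycle_duration_s = lab),
    data.frame(subject = subj, exercise = "half_squat", session = "home",
               cycle_duration_s = home))
  p1 <- compareSessions(mk(lab, home), "cycle_duration_s", "half_squat",
                        nPermutations = 2000, seed = 5)$pValue
  p2 <- compareSessions(mk(home, lab), "cycle_duration_s", "half_squat",
                        nPermutations = 2000, seed = 5)$pValue
  expect_identical(p1, p2)
})

test_that("unpaired subjects are dropped and tiny designs refused", {
  subj <- sprintf("S%02d", 1:6)
  tab <- rbind(
    data.frame(subject = subj, exercise = "half_squat", session = "lab",
               cycle_duration_s = 3 + (1:6) / 10),
    data.frame(subject = subj[1:5], exercise = "half_squat",
               session = "home", cycle_duration_s = 3 + (1:5) / 12))
  expect_warning(
    res <- compareSessions(tab, "cycle_duration_s", "half_squat",
                           nPermutations = 499, seed = 2),
    class = "unpairedSubjectsWarning")
  expect_identical(res$nPairs, 5L)
  expect_error(
    suppressWarnings(compareSessions(tab[tab$subject %in% subj[1:4], ],
                                     "cycle_duration_s", "half_squat",
                                     nPermutations = 99, seed = 1)),
    class = "insufficientDataError")
})

test_that("a permutation comparison is deterministic given its seed", {
  coh <- generateCohort(nSubjects = 6, exercises = "knee_extension",
                        seed = 31)
  tab <- runBatch(coh)$metrics
  p1 <- compareSessions(tab, "cycle_duration_s", "knee_extension",
                        nPermutations = 1999, seed = 4)
  p2 <- compareSessions(tab, "cycle_duration_s", "knee_extension",
                        nPermutations = 1999, seed = 4)
  expect_identical(p1, p2)
})
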