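#' @include AllClasses.R metrics.R imu-io.R synthetic.R
NULL

#' Run the pipeline over a batch of recordings
#'
#' Segments every recording and computes its metric set, producing one
#' tidy row per recording. Failures are logged to stderr per file and
#' collected in a `failures` table with the failure reason; they never
#' abort the batch.
#'
#' @param manifest either a data.frame with columns `file`, `subject`,
#'   `exercise`, `session` (files are read with `colmap` relative to
#'   `dir`), or the list returned by [generateCohort()] (in-memory
#'   recordings; no files touched).
#' @param config a [pipelineConfig()] list.
#' @param dir directory that `manifest$file` paths are relative to.
#' @param colmap a [ColumnMap-class] for reading files.
#' @return List with `metrics` (data.frame: subject, exercise, session,
#'   plus the [metricColumns()] and `n_cycles`) and `failures`
#'   (data.frame: file, reason).
#' @export
runBatch <- function(manifest, config = pipelineConfig(), dir = ".",
                     colmap = canonicalColumnMap()) {
  recs <- NULL
  if (is.list(manifest) && !is.data.frame(manifest) &&
      all(c("manifest", "recordings") %in% names(manifest))) {
    recs <- manifest$recordings
    manifest <- manifest$manifest
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    .imuStop("configError", "empty manifest")
  rows <- vector("list", nrow(manifest))
  fails <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$file[i]
    res <- tryCatch({
      rec <- if (!is.null(recs)) recs[[f]]
             else readRecording(file.path(dir, f), colmap = colmap,
                                subject = manifest$subject[i],
                                exercise = manifest$exercise[i],
                                session = manifest$session[i])
      if (is.null(rec)) .imuStop("configError", "recording '%s' missing", f)
      ms <- computeMetricSet(rec, config = config)
      cbind(data.frame(file = f,
                       subject = manifest$subject[i],
                       exercise = manifest$exercise[i],
                       session = manifest$session[i]),
            as.data.frame(ms))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[imuRehab] %s: %s", f, conditionMessage(res)))
      fails[[length(fails) + 1L]] <-
        data.frame(file = f, reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failures <- if (length(fails) > 0L) do.call(rbind, fails)
              else data.frame(file = character(0), reason = character(0))
  list(metrics = metrics, failures = failures)
}

#' Summarize metrics per exercise and session
#'
#' Aggregates a tidy per-recording metric table into a lab-vs-home
#' reporting structure: mean and SD of every metric per (exercise,
#' session) cell, subject counts, the configured demonstration pace, and
#' the pace ratio (mean cycle duration over demonstration pace; below 1
#' means participants moved faster than demonstrated).
#'
#' @param table the `metrics` data.frame from [runBatch()].
#' @param demoPaceTable named numeric vector of demonstration paces per
#'   exercise, s; default [demoPaces()].
#' @return Data.frame with one row per (exercise, session): `n`,
#'   `single_subject` flag, `<metric>_mean` / `<metric>_sd` for each of
#'   [metricColumns()], `demo_pace_s`, `pace_ratio`. Row order is
#'   independent of the input row order.
#' @export
summarizeSessions <- function(table, demoPaceTable = demoPaces()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    .imuStop("configError", "empty metric table")
  cols <- intersect(metricColumns(), names(table))
  cells <- unique(table[, c("exercise", "session")])
  cells <- cells[order(match(cells$exercise, names(demoPaceTable)),
                       cells$session), , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- table[table$exercise == cells$exercise[k] &
                 table$session == cells$session[k], , drop = FALSE]
    n <- length(unique(sub$subject))
    row <- data.frame(exercise = cells$exercise[k],
                      session = cells$session[k],
                      n = n, single_subject = n == 1L)
    for (cn in cols) {
      row[[paste0(cn, "_mean")]] <- mean(sub[[cn]])
      row[[paste0(cn, "_sd")]] <- if (nrow(sub) > 1L) stats::sd(sub[[cn]])
                                  else 0
    }
    dp <- demoPaceTable[[cells$exercise[k]]]
    row$demo_pace_s <- if (is.null(dp)) NA_real_ else dp
    row$pace_ratio <- row$cycle_duration_s_mean / row$demo_pace_s
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired lab-vs-home comparison by sign-flip permutation
#'
#' Within-subject comparison of one metric between the lab and home
#' sessions of one exercise. The statistic is the mean of the per-subject
#' (lab - home) differences; its two-sided p-value comes from random
#' sign-flip permutations of the differences (the exact null of no
#' session effect under within-subject exchangeability). Unpaired
#' subjects are dropped with a warning. This plumbing-level test yields a
#' self-contained check of simulated session effects; a full factorial
#' analysis of a real study would use standard mixed-model ANOVA on the
#' tidy metric table.
#'
#' @param table the `metrics` data.frame from [runBatch()].
#' @param metric one of [metricColumns()].
#' @param exercise one of [exerciseNames()].
#' @param nPermutations number of sign-flip permutations.
#' @param seed integer seed; results are deterministic given it.
#' @return List with `pValue`, `statistic` (mean paired difference),
#'   `nPairs`, `nPermutations`.
#' @export
compareSessions <- function(table, metric, exercise,
                            nPermutations = 10000L, seed = 1L) {
  if (!metric %in% names(table))
    .imuStop("configError", "metric '%s' not in table", metric)
  sub <- table[table$exercise == exercise &
               table$session %in% c("lab", "home"), , drop = FALSE]
  lab <- sub[sub$session == "lab", c("subject", metric)]
  home <- sub[sub$session == "home", c("subject", metric)]
  common <- intersect(lab$subject, home$subject)
  dropped <- setdiff(union(lab$subject, home$subject), common)
  if (length(dropped) > 0L)
    .imuWarn("unpairedSubjectsWarning",
             "dropping %d unpaired subject(s)", length(dropped))
  if (length(common) < 5L)
    .imuStop("insufficientDataError",
             "need >= 5 paired subjects, have %d", length(common))
  d <- lab[[metric]][match(common, lab$subject)] -
       home[[metric]][match(common, home$subject)]
  obs <- mean(d)
  perm <- .withSeed(seed, {
    flips <- matrix(sample(c(-1, 1), nPermutations * length(d),
                           replace = TRUE),
                    nPermutations, length(d))
    as.numeric(flips %*% d) / length(d)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (nPermutations + 1)
  list(pValue = p, statistic = obs, nPairs = length(common),
       nPermutations = nPermutations)
}

#' Count recording files in a directory
#'
#' Trivial adherence report: the number of recording files (canonical
#' CSV, excluding sidecars and manifest) present in a directory.
#'
#' @param dir directory path.
#' @return Integer count.
#' @export
countRecordings <- function(dir) {
  f <- list.files(dir, pattern = "\\.csv$")
  sum(f != "manifest.csv" & !grepl("\\.meta$", f))
}
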