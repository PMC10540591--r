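# Run a block with a locally seeded RNG, restoring the caller's RNG state.
# Mersenne-Twister + Inversion + Rejection sampling (the R >= 3.6 default)
# is pinned explicitly so stored values are stable across platforms.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Generate a session design of interleaved stress and calm clips
#'
#' Emulates a VR-like exposure session: each run alternates a stress clip
#' (level 2-8, lasting 60 or 90 s) with a calm clip (level 1, lasting 30 or
#' 60 s), greedily packed to exactly `run_duration_s`; the final clip is
#' truncated to a multiple of the report interval where needed. The subject
#' reports a stress level (1 = least, 8 = most stressful) every
#' `report_interval_s` seconds, i.e. every `report_interval_s / TR_s` frames.
#' Across the session, every level in `level_pool` is guaranteed to occur at
#' least once when the run count permits.
#'
#' @param n_runs number of runs (default 5).
#' @param level_pool integer levels to cover (default 1:8; level 1 is calm).
#' @param seed integer seed; identical seeds give identical designs.
#' @param run_duration_s run length in seconds (default 480, i.e. 8 min).
#' @param TR_s repetition time in seconds (default 1.5).
#' @param report_interval_s seconds between stress reports (default 15).
#' @return An object of class `session_design`: list with `runs` (each a
#'   data.frame of clips: onset_s, duration_s, level), `run_duration_s`,
#'   `TR_s`, `report_interval_s`, `frames_per_report`, `n_reports_per_run`,
#'   `n_frames_per_run`.
#' @export
make_session_design <- function(n_runs = 5, level_pool = 1:8, seed = 1,
                                run_duration_s = 480, TR_s = 1.5,
                                report_interval_s = 15) {
  stopifnot(n_runs >= 1, all(level_pool %in% 1:8))
  if (run_duration_s %% report_interval_s != 0)
    stop("impossible packing: run duration is not a multiple of the report interval")
  if (abs(report_interval_s / TR_s - round(report_interval_s / TR_s)) > 1e-9)
    stop("report interval must be a whole number of frames")
  stress_pool <- setdiff(level_pool, 1L)
  if (length(stress_pool) == 0)
    stop("level_pool must contain at least one stress level (2-8)")

  with_seed(seed, {
    # durations first: alternate stress / calm until the run is full
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      t <- 0; durs <- numeric(0); kind <- character(0); is_stress <- TRUE
      while (t < run_duration_s) {
        d <- if (is_stress) sample(c(60, 90), 1) else sample(c(30, 60), 1)
        d <- min(d, run_duration_s - t)     # truncate final clip
        durs <- c(durs, d); kind <- c(kind, if (is_stress) "stress" else "calm")
        t <- t + d; is_stress <- !is_stress
      }
      runs[[r]] <- data.frame(onset_s = cumsum(c(0, durs[-length(durs)])),
                              duration_s = durs, kind = kind)
    }
    # stress levels: guarantee pool coverage, then fill uniformly at random
    n_slots <- sum(vapply(runs, function(x) sum(x$kind == "stress"), 0L))
    guaranteed <- stress_pool[seq_len(min(length(stress_pool), n_slots))]
    fill <- if (n_slots > length(guaranteed))
      sample(stress_pool, n_slots - length(guaranteed), replace = TRUE)
    else integer(0)
    lv <- sample(c(guaranteed, fill))
    i <- 0
    for (r in seq_len(n_runs)) {
      lev <- integer(nrow(runs[[r]]))
      for (j in seq_len(nrow(runs[[r]]))) {
        if (runs[[r]]$kind[j] == "stress") {
          i <- i + 1; lev[j] <- lv[i]
        } else lev[j] <- 1L
      }
      runs[[r]]$level <- lev
      runs[[r]]$kind <- NULL
    }
    structure(list(runs = runs,
                   run_duration_s = run_duration_s, TR_s = TR_s,
                   report_interval_s = report_interval_s,
                   frames_per_report = as.integer(report_interval_s / TR_s),
                   n_reports_per_run = as.integer(run_duration_s / report_interval_s),
                   n_frames_per_run = as.integer(run_duration_s / TR_s)),
              class = "session_design")
  })
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf(paste0("session_design: %d runs of %d s (TR %.2g s, report every",
                     " %d s -> %d reports, %d frames per run)\n"),
              length(x$runs), x$run_duration_s, x$TR_s, x$report_interval_s,
              x$n_reports_per_run, x$n_frames_per_run))
  invisible(x)
}

#' Per-report ground-truth labels of a session design
#'
#' Each 15 s report interval falls entirely inside one clip (clip durations
#' are multiples of the report interval), and the reported level is that
#' clip's stress level.
#'
#' @param design a [make_session_design] result.
#' @param session session index recorded in the output (default 1).
#' @return A data.frame (class `label_schedule`): session, run, report_index
#'   (1-based within run), stress_level, onset_s, duration_s.
#' @export
design_label_schedule <- function(design, session = 1L) {
  out <- do.call(rbind, lapply(seq_along(design$runs), function(r) {
    clips <- design$runs[[r]]
    n_rep <- design$n_reports_per_run
    rep_end <- seq_len(n_rep) * design$report_interval_s
    idx <- findInterval(rep_end - 1e-9, clips$onset_s)
    data.frame(session = as.integer(session), run = as.integer(r),
               report_index = seq_len(n_rep),
               stress_level = clips$level[idx],
               onset_s = (seq_len(n_rep) - 1) * design$report_interval_s,
               duration_s = design$report_interval_s)
  }))
  attr(out, "frames_per_report") <- design$frames_per_report
  attr(out, "TR_s") <- design$TR_s
  class(out) <- c("label_schedule", "data.frame")
  out
}

#' Write a label schedule as a BIDS-style events table
#'
#' Columns: onset, duration, stress_level, run, session (tab-separated).
#'
#' @param schedule a [design_label_schedule] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  d <- data.frame(onset = schedule$onset_s, duration = schedule$duration_s,
                  stress_level = schedule$stress_level,
                  run = schedule$run, session = schedule$session)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table into a label schedule
#'
#' @param path events TSV with columns onset, duration, stress_level, run,
#'   session.
#' @param TR_s repetition time (default 1.5 s).
#' @param report_interval_s report spacing (default 15 s).
#' @return A `label_schedule` data.frame as in [design_label_schedule].
#' @export
read_events_tsv <- function(path, TR_s = 1.5, report_interval_s = 15) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("onset", "duration", "stress_level", "run", "session")
                %in% names(d)))
  d <- d[order(d$session, d$run, d$onset), ]
  out <- do.call(rbind, lapply(split(d, list(d$session, d$run), drop = TRUE),
    function(g) data.frame(session = g$session, run = g$run,
                           report_index = seq_len(nrow(g)),
                           stress_level = as.integer(g$stress_level),
                           onset_s = g$onset, duration_s = g$duration)))
  out <- out[order(out$session, out$run, out$report_index), ]
  rownames(out) <- NULL
  attr(out, "frames_per_report") <- as.integer(report_interval_s / TR_s)
  attr(out, "TR_s") <- TR_s
  class(out) <- c("label_schedule", "data.frame")
  out
}
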