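#' @title Behavioral episode logs and stereotypy rates
#' @description Stereotyped (anxious) behavior is scored from timed video
#'   episodes: each episode is an interval `[start_s, stop_s]` within a
#'   recording session; a subject's stereotypy rate is the summed episode
#'   duration in seconds divided by the total recorded minutes, giving an
#'   s/min rate bounded above by 60.
#' @name behavior
NULL

#' Read an episode log table
#'
#' Expects a TSV/CSV with header columns `subject_id, group, sex,
#' session_id, start_s, stop_s` (extra columns, e.g. a free-text behavior
#' label, are carried through unmodified). Subjects with zero episodes may
#' appear as rows with empty `session_id` and `NA` start/stop.
#'
#' @param path path to the table; the delimiter is inferred from the
#'   extension (`.tsv` = tab, otherwise comma).
#' @return a data.frame of episodes.
#' @export
read_episode_log <- function(path) {
  if (!file.exists(path)) stop("episode log not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "group", "sex", "session_id", "start_s", "stop_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("episode log missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

validate_episodes <- function(ep) {
  ep <- ep[!is.na(ep$start_s), , drop = FALSE]
  if (!nrow(ep)) return(invisible(ep))
  if (any(ep$stop_s <= ep$start_s))
    stop("episode with stop_s <= start_s")
  for (ses in unique(ep$session_id)) {
    e <- ep[ep$session_id == ses, , drop = FALSE]
    e <- e[order(e$start_s), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$stop_s[-nrow(e)]))
      stop("overlapping episodes in session ", ses)
  }
  invisible(ep)
}

#' Per-subject stereotypy rate (s/min)
#'
#' Sums episode durations per subject and divides by the total recorded
#' time in minutes. Episodes within a session must not overlap and must
#' have `stop_s > start_s`.
#'
#' @param episodes a data.frame as returned by [read_episode_log()] (may
#'   cover many subjects).
#' @param total_recorded_min total recorded minutes per subject. The
#'   default 120 corresponds to eight 15-minute videos; it is exposed as an
#'   option because published protocols sometimes normalize by a different
#'   nominal total.
#' @return a data.frame with columns `subject_id, group, sex,
#'   rate_s_per_min`, one row per subject.
#' @export
stereotypy_rates <- function(episodes, total_recorded_min = 120) {
  if (total_recorded_min <= 0) stop("total_recorded_min must be > 0")
  subjects <- unique(episodes[, c("subject_id", "group", "sex")])
  rate <- vapply(subjects$subject_id, function(sid) {
    ep <- episodes[episodes$subject_id == sid, , drop = FALSE]
    validate_episodes(ep)
    ep <- ep[!is.na(ep$start_s), , drop = FALSE]
    tot_s <- if (nrow(ep)) sum(ep$stop_s - ep$start_s) else 0
    tot_s / total_recorded_min
  }, numeric(1))
  if (any(rate > 60 + 1e-9))
    stop("rate exceeds 60 s/min: episodes exceed recorded time")
  out <- data.frame(subjects, rate_s_per_min = unname(rate),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Group comparison of behavior scores
#'
#' Screens each group for normality (Shapiro-Wilk at `alpha`); if both
#' groups pass, a pooled-variance t test is used, otherwise the exact
#' Mann-Whitney rank-sum test. The result records which branch ran.
#'
#' @param scores numeric vector of per-subject scores.
#' @param groups factor/character vector of group labels (exactly two
#'   levels, each with >= 2 subjects).
#' @param alpha normality-screen level (default .05).
#' @return an `amyg_test`; its `method` names the branch taken.
#' @export
compare_groups <- function(scores, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups")
  x <- scores[groups == lev[1]]
  y <- scores[groups == lev[2]]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 subjects per group")
  normal <- normality_check(x, alpha) && normality_check(y, alpha)
  res <- if (normal) pooled_t_test(x, y) else rank_sum_test(x, y)
  res$note <- paste0(res$note %||% "",
                     if (!is.null(res$note)) "; ",
                     "branch: ", if (normal) "t-test (both groups normal)"
                     else "rank-sum (normality rejected)",
                     "; groups: ", lev[1], " vs ", lev[2])
  res
}
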