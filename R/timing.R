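# Timing-trial aggregation and reference-sample-size selection.
#
# Per-task times are estimated by timing a sample of tasks repeatedly and
# averaging; the reference sample size is chosen where the trial variance has
# collapsed and the per-task mean has reached steady state, so that one
# profiled number per architecture is trustworthy input to the scheduler.

#' Bundle repeated timing trials at one sample size
#'
#' @param sample_size Number of tasks timed in each trial.
#' @param trial_times Numeric vector of at least two positive measurements
#'   (seconds). Whether they are total sample times or already per-task times
#'   is up to the caller; [per_task_trials()] converts between the two.
#'
#' @return Object of class `timing_trials` with elements `sample_size`,
#'   `trial_times`, `mean` and `variance` (population variance, divisor
#'   \eqn{N}).
#' @export
timing_trial_set <- function(sample_size, trial_times) {
  if (!is.numeric(sample_size) || length(sample_size) != 1L || sample_size < 1) {
    stop("'sample_size' must be >= 1", call. = FALSE)
  }
  stats <- aggregate_trials(trial_times)
  structure(list(sample_size = as.numeric(sample_size),
                 trial_times = as.numeric(trial_times),
                 mean = stats$mean, variance = stats$variance),
            class = "timing_trials")
}

#' @export
print.timing_trials <- function(x, ...) {
  cat(sprintf("<timing_trials> %d trials at %g tasks: mean %s s, variance %s\n",
              length(x$trial_times), x$sample_size,
              format_seconds(x$mean), format_seconds(x$variance)))
  invisible(x)
}

#' Mean and population variance of repeated timing trials
#'
#' Repeated measurements of the same sample are averaged to suppress system
#' noise; the variance across trials is the convergence signal used by
#' [select_reference_sample_size()]. The population divisor (\eqn{N}) is used:
#' the trials are the entire set of measurements being summarised, not a
#' sample from a larger set, and the magnitude only serves as a convergence
#' signal.
#'
#' @param times Numeric vector of at least two positive measurements.
#' @return List with elements `mean` and `variance`.
#' @export
#' @examples
#' aggregate_trials(c(1, 2, 3))  # mean 2, variance 2/3
aggregate_trials <- function(times) {
  if (!is.numeric(times) || length(times) < 2L) {
    stop("need at least 2 trials to aggregate", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all trial times must be finite and > 0", call. = FALSE)
  }
  m <- mean(times)
  list(mean = m, variance = mean((times - m)^2))
}

#' Convert total-time trials to per-task (per-core) trials
#'
#' A trial that timed `sample_size` tasks on `cores` cores corresponds to
#' `sample_size / cores` tasks per core, so each total time divided by that
#' count is the single-task time of one core — the same normalisation as
#' [per_task_time()], applied trial by trial.
#'
#' @param trials A [timing_trial_set()] of total times.
#' @param cores Core count of the architecture that produced the trials.
#' @return A [timing_trial_set()] of per-task times at the same sample size.
#' @export
per_task_trials <- function(trials, cores) {
  stopifnot(inherits(trials, "timing_trials"))
  if (!is.numeric(cores) || length(cores) != 1L || cores < 1) {
    stop("'cores' must be >= 1", call. = FALSE)
  }
  timing_trial_set(trials$sample_size,
                   trials$trial_times / (trials$sample_size / cores))
}

#' Select the reference sample size by variance convergence
#'
#' Scans per-architecture timing curves for the smallest sample size from
#' which, for every architecture and every size onwards, (a) the trial
#' variance is at most `var_tol` and (b) the mean differs from the mean at
#' the largest size by at most a relative `stab_tol` ("steady state"). The
#' trial sets should contain per-task times (see [per_task_trials()]) so the
#' tolerances are comparable across architectures with different core counts.
#'
#' There is no universally correct pair of tolerances: published profiling
#' studies pick the reference size by inspecting where variance "tends to
#' zero", and this function turns that inspection into two explicit knobs.
#' If no size qualifies the largest available size is returned with a
#' warning, mirroring the practice of taking the longest-run measurement when
#' convergence is not demonstrated.
#'
#' @param curves Named list (one entry per architecture) of lists of
#'   [timing_trial_set()] objects, each inner list covering the same
#'   ascending sample sizes.
#' @param var_tol Variance threshold (seconds squared).
#' @param stab_tol Relative mean-stability threshold (fraction, e.g. 0.05).
#' @return The selected sample size (task count).
#' @export
select_reference_sample_size <- function(curves, var_tol, stab_tol) {
  if (!is.list(curves) || length(curves) == 0L) {
    stop("'curves' must be a non-empty list of per-architecture trial sets",
         call. = FALSE)
  }
  sizes_per_arch <- lapply(curves, function(tsets) {
    stopifnot(all(vapply(tsets, inherits, logical(1), "timing_trials")))
    vapply(tsets, `[[`, numeric(1), "sample_size")
  })
  sizes <- sizes_per_arch[[1L]]
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sample sizes must be strictly ascending", call. = FALSE)
  }
  same <- vapply(sizes_per_arch, function(s) identical(s, sizes), logical(1))
  if (!all(same)) {
    stop("every architecture must be profiled at the same sample sizes",
         call. = FALSE)
  }
  k <- length(sizes)
  ok <- rep(TRUE, k)
  for (tsets in curves) {
    means <- vapply(tsets, `[[`, numeric(1), "mean")
    vars <- vapply(tsets, `[[`, numeric(1), "variance")
    ref <- means[k]
    good <- vars <= var_tol & abs(means - ref) / ref <= stab_tol
    # a size qualifies only if it and all larger sizes are good
    ok <- ok & rev(cumprod(rev(good)) > 0)
  }
  if (!any(ok)) {
    warning("no sample size met the convergence tolerances; ",
            "returning the largest size", call. = FALSE)
    return(sizes[k])
  }
  sizes[which(ok)[1L]]
}

#' Read timing curves from CSV
#'
#' Expected columns: `sample_size`, `architecture`, `trial_index`,
#' `total_time_s`. Rows are grouped into one [timing_trial_set()] per
#' architecture and sample size.
#'
#' @param path Path to the CSV file.
#' @return Named list (architecture) of lists of [timing_trial_set()],
#'   ordered by ascending sample size, as accepted by
#'   [select_reference_sample_size()] after [per_task_trials()] conversion.
#' @export
read_timing_curves <- function(path) {
  if (!file.exists(path)) stop("timing curve file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_size", "architecture", "trial_index", "total_time_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("timing curve CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (arch in unique(df$architecture)) {
    sub <- df[df$architecture == arch, , drop = FALSE]
    sizes <- sort(unique(sub$sample_size))
    out[[arch]] <- lapply(sizes, function(s) {
      rows <- sub[sub$sample_size == s, , drop = FALSE]
      rows <- rows[order(rows$trial_index), , drop = FALSE]
      timing_trial_set(s, rows$total_time_s)
    })
  }
  out
}
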