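#' Construct an architecture profile
#'
#' An architecture profile describes one compute resource available to the
#' scheduler: its name, its core count \eqn{n_i}, the measured total wall time
#' \eqn{T_i} it needed for a reference sample of \eqn{C'} tasks, and the
#' effective per-task time \eqn{t_i} of a single core. When `per_task_time`
#' is not supplied it is derived as \eqn{t_i = T_i / (C'/n_i)} via
#' [per_task_time()]. When it *is* supplied, the stored value always wins for
#' scheduling: published profile tables are not always internally consistent
#' with the derivation (measurement noise, rounding, or per-architecture
#' overheads), and the measured single-task time is the quantity the round
#' model needs.
#'
#' @param name Short unique label, e.g. `"CPU"`.
#' @param cores Number of cores \eqn{n_i} (positive integer).
#' @param sample_total_time Total seconds \eqn{T_i} for the reference sample.
#' @param sample_size Number of tasks \eqn{C'} in the reference sample.
#' @param per_task_time Seconds one core needs for one task (\eqn{t_i}).
#'   Derived from the other fields when `NULL`.
#' @param ref_per_task_time Optional per-task time measured on a small
#'   (1 M-task) sample; used by the speed-based baseline scheduler, which
#'   profiles on such a sample instead of the converged reference sample.
#'
#' @return An object of class `arch_profile`.
#' @seealso [profile_table()], [per_task_time()], [sort_profiles()]
#' @export
#' @examples
#' arch_profile("MIC", cores = 60, sample_total_time = 362.83,
#'              sample_size = 4e7)
arch_profile <- function(name, cores, sample_total_time, sample_size,
                         per_task_time = NULL, ref_per_task_time = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(cores) || length(cores) != 1L || cores < 1 ||
      cores != floor(cores)) {
    stop("'cores' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(sample_total_time) || sample_total_time <= 0) {
    stop("'sample_total_time' must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_size) || sample_size < 1) {
    stop("'sample_size' must be >= 1", call. = FALSE)
  }
  if (is.null(per_task_time)) {
    per_task_time <- per_task_time(sample_total_time, sample_size, cores)
  }
  if (!is.numeric(per_task_time) || per_task_time <= 0) {
    stop("'per_task_time' must be > 0", call. = FALSE)
  }
  if (!is.null(ref_per_task_time) &&
      (!is.numeric(ref_per_task_time) || ref_per_task_time <= 0)) {
    stop("'ref_per_task_time' must be > 0 when supplied", call. = FALSE)
  }
  structure(
    list(name = name, cores = as.numeric(cores),
         sample_total_time = as.numeric(sample_total_time),
         sample_size = as.numeric(sample_size),
         per_task_time = as.numeric(per_task_time),
         ref_per_task_time = if (is.null(ref_per_task_time)) NA_real_
                             else as.numeric(ref_per_task_time)),
    class = "arch_profile"
  )
}

#' @export
print.arch_profile <- function(x, ...) {
  cat(sprintf("<arch_profile> %s: %g cores, T = %g s over %g tasks, t = %s s/task\n",
              x$name, x$cores, x$sample_total_time, x$sample_size,
              format_seconds(x$per_task_time)))
  invisible(x)
}

#' Bundle architecture profiles that share a reference sample size
#'
#' @param profiles List of [arch_profile()] objects with unique names, all
#'   profiled on the same reference sample size.
#'
#' @return An object of class `profile_table` with elements `profiles` and
#'   `reference_sample_size`.
#' @export
profile_table <- function(profiles) {
  if (length(profiles) == 0L) {
    stop("a profile table needs at least one profile", call. = FALSE)
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "arch_profile")))
  nms <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("profile names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sizes <- vapply(profiles, `[[`, numeric(1), "sample_size")
  if (length(unique(sizes)) != 1L) {
    stop("all profiles must share the same reference sample size", call. = FALSE)
  }
  structure(list(profiles = profiles, reference_sample_size = sizes[[1L]]),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("<profile_table> %d architectures, reference sample %g tasks\n",
              length(x$profiles), x$reference_sample_size))
  for (p in x$profiles) print(p)
  invisible(x)
}

#' @export
length.profile_table <- function(x) length(x$profiles)

#' Per-task execution time of one core
#'
#' Converts a measured total time for a reference sample into the effective
#' time one core needs for one task, accounting for the parallelism of the
#' architecture: a sample of `c_prime` tasks spread over `n` cores means each
#' core processed `c_prime / n` tasks, so
#' \deqn{t = T / (C'/n) = T \cdot n / C'.}
#'
#' @param T Total execution time in seconds for the reference sample (> 0).
#' @param c_prime Number of tasks in the reference sample (>= 1).
#' @param n Number of cores (>= 1).
#'
#' @return Per-task time in seconds.
#' @export
#' @examples
#' per_task_time(362.83, 4e7, 60)   # ~5.442e-4 s on a 60-core coprocessor
per_task_time <- function(T, c_prime, n) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("'T' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(c_prime) || length(c_prime) != 1L || c_prime < 1) {
    stop("'c_prime' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be >= 1", call. = FALSE)
  }
  T * n / c_prime
}

#' Order architectures by total reference-sample time
#'
#' The scheduler considers architectures in ascending order of the total wall
#' time each needed for the shared reference sample: the resource that
#' finished the sample fastest (highest aggregate throughput) seeds the
#' hybrid pool. Ties are broken alphabetically by name so the order is
#' deterministic.
#'
#' @param table A [profile_table()].
#' @return The same table with `profiles` reordered.
#' @export
sort_profiles <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  tt <- vapply(table$profiles, `[[`, numeric(1), "sample_total_time")
  nm <- vapply(table$profiles, `[[`, character(1), "name")
  table$profiles <- table$profiles[order(tt, nm)]
  table
}

#' Read architecture profiles from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `cores`,
#' `sample_total_time_s`, `sample_size`, and optionally `per_task_time_s`
#' (stored measured value, takes precedence over the derived one) and
#' `ref_per_task_time_s` (1 M-sample time for the baseline scheduler).
#'
#' @param path Path to the JSON file.
#' @return A [profile_table()].
#' @export
load_profiles_config <- function(path) {
  if (!file.exists(path)) {
    stop("profile config not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("profile config must be a non-empty JSON array of objects", call. = FALSE)
  }
  profiles <- lapply(seq_along(raw), function(i) {
    rec <- raw[[i]]
    for (f in c("name", "cores", "sample_total_time_s", "sample_size")) {
      if (is.null(rec[[f]])) {
        stop(sprintf("profile record %d is missing required field '%s'", i, f),
             call. = FALSE)
      }
    }
    arch_profile(name = rec$name, cores = rec$cores,
                 sample_total_time = rec$sample_total_time_s,
                 sample_size = rec$sample_size,
                 per_task_time = rec$per_task_time_s,
                 ref_per_task_time = rec$ref_per_task_time_s)
  })
  profile_table(profiles)
}

#' Format seconds in the 5-significant-digit scientific style of the
#' published validation tables.
#' @param x Numeric vector of seconds.
#' @return Character vector like `"2.1768E-03"`.
#' @export
format_seconds <- function(x) {
  toupper(formatC(x, format = "e", digits = 4))
}
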