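# Throughput-proportional partitioning of C independent tasks across
# heterogeneous architectures, under a whole-round completion model:
# an architecture with n cores and per-task time t finishes c tasks in
# ceil(c/n) rounds of duration t. The architecture-aware scheduler tests
# each candidate resource against the *hybrid* makespan T' as the pool grows;
# the speed-based baseline tests once against the static makespan of the
# fastest architecture alone.

#' Build a scheduling request
#'
#' @param total_tasks Number of independent tasks \eqn{C} to distribute
#'   (for brute-force motif search over length-`L` candidates,
#'   \eqn{C = 4^L}; see [task_count()]).
#' @param profiles A [profile_table()].
#' @return Object of class `schedule_request`.
#' @export
schedule_request <- function(total_tasks, profiles) {
  if (!is.numeric(total_tasks) || length(total_tasks) != 1L ||
      total_tasks < 1 || total_tasks != floor(total_tasks)) {
    stop("'total_tasks' must be a positive integer", call. = FALSE)
  }
  stopifnot(inherits(profiles, "profile_table"))
  structure(list(total_tasks = as.numeric(total_tasks), profiles = profiles),
            class = "schedule_request")
}

#' Throughput weights of a set of architectures
#'
#' An architecture with \eqn{n_i} cores and per-task time \eqn{t_i} sustains
#' \eqn{n_i / t_i} tasks per second. Work shares proportional to this
#' throughput equalise (up to round granularity) the completion times of all
#' pool members, which is what minimises the hybrid makespan.
#'
#' @param eligible List of [arch_profile()] objects (non-empty).
#' @param per_task_times Optional named numeric vector overriding each
#'   profile's stored per-task time (used by the baseline scheduler, which
#'   profiles on a small sample).
#' @return Named numeric vector of shares summing to 1.
#' @export
throughput_weights <- function(eligible, per_task_times = NULL) {
  if (length(eligible) == 0L) {
    stop("'eligible' must contain at least one profile", call. = FALSE)
  }
  nms <- vapply(eligible, `[[`, character(1), "name")
  n <- vapply(eligible, `[[`, numeric(1), "cores")
  t <- vapply(eligible, `[[`, numeric(1), "per_task_time")
  if (!is.null(per_task_times)) {
    miss <- setdiff(nms, names(per_task_times))
    if (length(miss)) {
      stop("no per-task time supplied for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    t <- as.numeric(per_task_times[nms])
  }
  if (any(t <= 0)) stop("per-task times must be > 0", call. = FALSE)
  w <- n / t
  stats::setNames(w / sum(w), nms)
}

#' Apportion an integer task count by fractional shares
#'
#' Largest-remainder apportionment: each architecture gets
#' `floor(share * total_tasks)` tasks and the leftover tasks go one each to
#' the largest fractional remainders. Remainder ties are broken toward the
#' larger share (the higher-throughput architecture), then by position, so
#' the split is deterministic and always conserves the total.
#'
#' @param total_tasks Total task count \eqn{C} (>= 0).
#' @param shares Numeric vector of non-negative shares summing to 1 (within
#'   1e-12).
#' @return Integer-valued numeric vector of task counts summing to
#'   `total_tasks`.
#' @export
#' @examples
#' integer_partition(1024, c(0.8201032, 0.1798968))  # 840 and 184
integer_partition <- function(total_tasks, shares) {
  if (!is.numeric(total_tasks) || total_tasks < 0 ||
      total_tasks != floor(total_tasks)) {
    stop("'total_tasks' must be a non-negative integer", call. = FALSE)
  }
  if (any(shares < 0)) stop("shares must be non-negative", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-12) {
    stop("shares must sum to 1 (got ", format(sum(shares)), ")", call. = FALSE)
  }
  exact <- shares * total_tasks
  counts <- floor(exact)
  residual <- round(total_tasks - sum(counts))
  if (residual > 0) {
    frac <- exact - counts
    ord <- order(-frac, -shares, seq_along(shares))
    take <- ord[seq_len(residual)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(counts, names(shares))
}

#' Completion time of one architecture under the round model
#'
#' `task_count` tasks on `cores` cores complete in `ceiling(task_count /
#' cores)` waves, each lasting one per-task time: cores inside an
#' architecture run in lockstep on equal-cost tasks, so a partially filled
#' final wave still costs a whole round.
#'
#' @param task_count Tasks assigned (>= 0).
#' @param profile An [arch_profile()].
#' @param per_task_time Optional override of the profile's per-task time.
#' @return Completion time in seconds (0 for an empty assignment).
#' @export
makespan_component <- function(task_count, profile, per_task_time = NULL) {
  stopifnot(inherits(profile, "arch_profile"))
  if (!is.numeric(task_count) || task_count < 0) {
    stop("'task_count' must be >= 0", call. = FALSE)
  }
  if (task_count == 0) return(0)
  t <- if (is.null(per_task_time)) profile$per_task_time else per_task_time
  t * ceiling(task_count / profile$cores)
}

#' Contiguous chunk ranges from per-architecture task counts
#'
#' Tasks are indexed 0-based in a single candidate space; each architecture
#' receives one contiguous half-open range `[start, end)`, in the order the
#' counts are given.
#'
#' @param counts Integer-valued task counts.
#' @param total_tasks Total task count; must equal `sum(counts)`.
#' @return Data frame with columns `start` and `end` (0-based, half-open).
#' @export
chunk_ranges <- function(counts, total_tasks) {
  if (abs(sum(counts) - total_tasks) > 0.5) {
    stop("counts sum to ", format(sum(counts)), ", expected ",
         format(total_tasks), call. = FALSE)
  }
  ends <- cumsum(as.numeric(counts))
  starts <- c(0, ends[-length(ends)])
  data.frame(start = starts, end = ends, row.names = NULL)
}

# Assemble assignments / makespan for a fixed pool of member profiles.
plan_members <- function(members, total_tasks, per_task_times = NULL) {
  shares <- throughput_weights(members, per_task_times)
  counts <- integer_partition(total_tasks, shares)
  ranges <- chunk_ranges(counts, total_tasks)
  nms <- vapply(members, `[[`, character(1), "name")
  cores <- vapply(members, `[[`, numeric(1), "cores")
  t <- if (is.null(per_task_times)) {
    vapply(members, `[[`, numeric(1), "per_task_time")
  } else {
    as.numeric(per_task_times[nms])
  }
  rounds <- ceiling(counts / cores)
  local_time <- ifelse(counts == 0, 0, t * rounds)
  assignments <- data.frame(
    architecture = nms, cores = cores, per_task_time = t,
    share = as.numeric(shares), tasks = as.numeric(counts),
    chunk_start = ranges$start, chunk_end = ranges$end,
    rounds = as.numeric(rounds), local_time = local_time,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(assignments = assignments, makespan = max(local_time), shares = shares)
}

new_schedule_plan <- function(core, excluded, total_tasks, algorithm) {
  structure(
    list(assignments = core$assignments, excluded = excluded,
         makespan = core$makespan, weights = core$shares,
         total_tasks = total_tasks, algorithm = algorithm),
    class = "schedule_plan"
  )
}

#' Architecture-aware scheduling of a data-parallel workload
#'
#' Implements the hybrid-makespan admission rule. Profiles are first sorted
#' by ascending reference-sample total time ([sort_profiles()]); the fastest
#' seeds the pool with makespan \eqn{T = t_1 \cdot \lceil C/n_1 \rceil}. Each
#' subsequent architecture is admitted iff its single-task time \eqn{t_i} is
#' below the *current hybrid* makespan \eqn{T'} — otherwise it could not
#' finish even one task before the existing pool finishes everything, so it
#' is excluded and left free for other jobs. On every admission all \eqn{C}
#' tasks are re-partitioned by [throughput_weights()] and \eqn{T'} is
#' recomputed as the maximum per-member round time. Exclusions are final:
#' the pass over the sorted profiles is single and architectures are never
#' revisited.
#'
#' @param req A [schedule_request()].
#' @param verbose If `TRUE`, message each eligibility decision (architecture,
#'   its \eqn{t_i}, the current \eqn{T'}, verdict).
#' @return Object of class `schedule_plan`: `assignments` (data frame with
#'   one row per pool member: share, tasks, 0-based half-open chunk, rounds,
#'   local completion time), `excluded` (data frame of name/reason),
#'   `makespan` (seconds), `weights`, `total_tasks`, `algorithm`.
#' @export
#' @examples
#' plan <- schedule_architecture_aware(
#'   schedule_request(task_count(5), profile_fixture()))
#' plan$makespan  # 2.1768e-3 s: four 60-core coprocessor rounds
schedule_architecture_aware <- function(req, verbose = FALSE) {
  stopifnot(inherits(req, "schedule_request"))
  tab <- sort_profiles(req$profiles)
  profs <- tab$profiles
  C <- req$total_tasks
  members <- profs[1L]
  current <- plan_members(members, C)
  if (verbose) {
    message(sprintf("seed pool with %s: T = %s s",
                    profs[[1L]]$name, format_seconds(current$makespan)))
  }
  excluded <- data.frame(name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (p in profs[-1L]) {
    if (p$per_task_time < current$makespan) {
      if (verbose) {
        message(sprintf("%s eligible: t = %s s < T' = %s s", p$name,
                        format_seconds(p$per_task_time),
                        format_seconds(current$makespan)))
      }
      members <- c(members, list(p))
      current <- plan_members(members, C)
      if (verbose) {
        message(sprintf("  new hybrid T' = %s s", format_seconds(current$makespan)))
      }
    } else {
      reason <- sprintf(
        "single-task time %s s >= hybrid makespan %s s: cannot finish one task before the pool finishes all %s",
        format_seconds(p$per_task_time), format_seconds(current$makespan),
        format(C, scientific = FALSE))
      if (verbose) {
        message(sprintf("%s excluded: t = %s s >= T' = %s s", p$name,
                        format_seconds(p$per_task_time),
                        format_seconds(current$makespan)))
      }
      excluded <- rbind(excluded,
                        data.frame(name = p$name, reason = reason,
                                   stringsAsFactors = FALSE))
    }
  }
  new_schedule_plan(current, excluded, C, "architecture-aware")
}

#' Speed-based baseline scheduling
#'
#' The prior strategy this package's scheduler improves upon. It profiles
#' every architecture on a small (1 M-task) sample and tests eligibility
#' *once* against the static makespan \eqn{T} of the fastest architecture
#' alone — it never re-tests against the shrinking hybrid makespan \eqn{T'},
#' and so can retain slow architectures the architecture-aware rule would
#' drop. Shares are throughput-proportional over the retained set, unless
#' explicit `ratios` are supplied (e.g. to reproduce a published split
#' exactly); explicit ratios bypass the eligibility test and apportion over
#' all profiles they name.
#'
#' @param req A [schedule_request()].
#' @param ref_times Named numeric vector of per-task times measured on the
#'   small reference sample, one per profile. Defaults to the
#'   `ref_per_task_time` stored in the profiles.
#' @param ratios Optional named numeric vector of explicit shares summing
#'   to 1.
#' @param verbose If `TRUE`, message each eligibility decision.
#' @return A `schedule_plan` (see [schedule_architecture_aware()]).
#' @export
schedule_speed_based <- function(req, ref_times = NULL, ratios = NULL,
                                 verbose = FALSE) {
  stopifnot(inherits(req, "schedule_request"))
  profs <- req$profiles$profiles
  nms <- vapply(profs, `[[`, character(1), "name")
  C <- req$total_tasks
  if (is.null(ref_times)) {
    ref_times <- stats::setNames(
      vapply(profs, `[[`, numeric(1), "ref_per_task_time"), nms)
  }
  miss <- setdiff(nms, names(ref_times))
  if (length(miss) || any(!is.finite(ref_times[nms]))) {
    stop("reference per-task times are required for every profile",
         call. = FALSE)
  }
  if (any(ref_times[nms] <= 0)) {
    stop("reference per-task times must be > 0", call. = FALSE)
  }

  # fastest architecture = smallest stand-alone makespan on the reference times
  alone <- vapply(profs, function(p) {
    makespan_component(C, p, per_task_time = ref_times[[p$name]])
  }, numeric(1))
  ord <- order(alone, nms)
  profs <- profs[ord]
  nms <- nms[ord]

  if (!is.null(ratios)) {
    if (abs(sum(ratios) - 1) > 1e-6) {
      stop("'ratios' must sum to 1", call. = FALSE)
    }
    miss <- setdiff(nms, names(ratios))
    if (length(miss)) {
      stop("'ratios' missing entries for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    shares <- ratios[nms] / sum(ratios[nms])
    counts <- integer_partition(C, shares)
    ranges <- chunk_ranges(counts, C)
    cores <- vapply(profs, `[[`, numeric(1), "cores")
    t <- as.numeric(ref_times[nms])
    rounds <- ceiling(counts / cores)
    local_time <- ifelse(counts == 0, 0, t * rounds)
    assignments <- data.frame(
      architecture = nms, cores = cores, per_task_time = t,
      share = as.numeric(shares), tasks = as.numeric(counts),
      chunk_start = ranges$start, chunk_end = ranges$end,
      rounds = as.numeric(rounds), local_time = local_time,
      stringsAsFactors = FALSE, row.names = NULL
    )
    core <- list(assignments = assignments, makespan = max(local_time),
                 shares = stats::setNames(as.numeric(shares), nms))
    excluded <- data.frame(name = character(), reason = character(),
                           stringsAsFactors = FALSE)
    return(new_schedule_plan(core, excluded, C, "speed-based"))
  }

  T_static <- alone[ord][1L]
  if (verbose) {
    message(sprintf("static reference: %s alone finishes in T = %s s",
                    nms[1L], format_seconds(T_static)))
  }
  eligible <- list(profs[[1L]])
  excluded <- data.frame(name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (p in profs[-1L]) {
    ti <- ref_times[[p$name]]
    if (ti < T_static) {
      if (verbose) {
        message(sprintf("%s eligible: t = %s s < T = %s s", p$name,
                        format_seconds(ti), format_seconds(T_static)))
      }
      eligible <- c(eligible, list(p))
    } else {
      if (verbose) {
        message(sprintf("%s excluded: t = %s s >= T = %s s", p$name,
                        format_seconds(ti), format_seconds(T_static)))
      }
      excluded <- rbind(excluded, data.frame(
        name = p$name,
        reason = sprintf("single-task time %s s >= static makespan %s s of %s alone",
                         format_seconds(ti), format_seconds(T_static), nms[1L]),
        stringsAsFactors = FALSE))
    }
  }
  core <- plan_members(eligible, C, per_task_times = ref_times)
  new_schedule_plan(core, excluded, C, "speed-based")
}

#' Percentage improvement of one makespan over another
#'
#' @param baseline_makespan Baseline completion time in seconds (> 0).
#' @param proposed_makespan Proposed completion time in seconds (> 0).
#' @return `100 * (baseline - proposed) / baseline`; negative when the
#'   proposed schedule is slower.
#' @export
#' @examples
#' enhancement_percent(2.6542e-2, 2.1768e-3)  # ~91.8
enhancement_percent <- function(baseline_makespan, proposed_makespan) {
  if (!is.numeric(baseline_makespan) || baseline_makespan <= 0) {
    stop("'baseline_makespan' must be > 0", call. = FALSE)
  }
  if (!is.numeric(proposed_makespan) || proposed_makespan <= 0) {
    stop("'proposed_makespan' must be > 0", call. = FALSE)
  }
  100 * (baseline_makespan - proposed_makespan) / baseline_makespan
}

#' @export
print.schedule_plan <- function(x, ...) {
  cat(sprintf("<schedule_plan> %s: %s tasks over %d architecture(s), makespan %s s\n",
              x$algorithm, format(x$total_tasks, scientific = FALSE),
              nrow(x$assignments), format_seconds(x$makespan)))
  df <- x$assignments
  df$share <- sprintf("%.2f%%", 100 * df$share)
  df$per_task_time <- format_seconds(df$per_task_time)
  df$local_time <- format_seconds(df$local_time)
  print(df, row.names = FALSE)
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("excluded %s: %s\n", x$excluded$name[i], x$excluded$reason[i]))
    }
  }
  invisible(x)
}

#' Write a schedule plan as TSV
#'
#' One row per assignment with the chunk indices each executor needs;
#' commented footer lines carry the makespan and any exclusions.
#'
#' @param plan A `schedule_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan_tsv <- function(plan, path) {
  stopifnot(inherits(plan, "schedule_plan"))
  df <- plan$assignments
  out <- data.frame(
    architecture = df$architecture, cores = df$cores,
    per_task_time_s = format_seconds(df$per_task_time),
    share = sprintf("%.6f", df$share), tasks = format(df$tasks, scientific = FALSE),
    chunk_start = format(df$chunk_start, scientific = FALSE),
    chunk_end = format(df$chunk_end, scientific = FALSE),
    rounds = df$rounds, local_time_s = format_seconds(df$local_time),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# makespan_s\t%s", format_seconds(plan$makespan)), con)
  if (nrow(plan$excluded)) {
    writeLines(sprintf("# excluded\t%s\t%s",
                       plan$excluded$name, plan$excluded$reason), con)
  }
  invisible(path)
}
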