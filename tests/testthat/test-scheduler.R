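fx <- fixture_table()

test_that("throughput weights reproduce the published two-way split", {
  profs <- sort_profiles(fx)$profiles
  cpu_mic <- Filter(function(p) p$name %in% c("CPU", "MIC"), profs)
  w <- throughput_weights(cpu_mic)
  expect_equal(unname(w[c("CPU", "MIC")]), c(0.8201, 0.1799), tolerance = 1e-4)
  expect_equal(round(100 * unname(w)), c(82, 18))
  expect_equal(sum(w), 1)
})

test_that("throughput weights handle degenerate pools", {
  solo <- list(arch_profile("X", 8, 1, 100, per_task_time = 1e-3))
  expect_equal(unname(throughput_weights(solo)), 1)
  pair <- list(arch_profile("A", 8, 1, 100, per_task_time = 1e-3),
               arch_profile("B", 8, 1, 100, per_task_time = 1e-3))
  expect_equal(unname(throughput_weights(pair)), c(0.5, 0.5))
  expect_error(throughput_weights(list()), "at least one")
})

test_that("integer partition apportions by largest remainder and conserves C", {
  expect_equal(unname(integer_partition(1024, c(0.8201032, 0.1798968))),
               c(840, 184))
  expect_equal(unname(integer_partition(10, c(0.5, 0.5))), c(5, 5))
  # remainder tie goes to the higher-throughput (larger-share) architecture
  expect_equal(unname(integer_partition(2, c(0.25, 0.75))), c(0, 2))
  expect_error(integer_partition(10, c(-0.1, 1.1)), "non-negative")
  expect_error(integer_partition(10, c(0.6, 0.6)), "sum to 1")
})

test_that("integer partition conserves the total on random shares", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    raw <- runif(k)
    shares <- raw / sum(raw)
    C <- sample(0:1e6, 1)
    counts <- integer_partition(C, shares)
    expect_equal(sum(counts), C)
    expect_true(all(counts >= floor(shares * C)))
  }
})

test_that("the round model charges whole rounds", {
  mic <- arch_profile("MIC", 60, 362.83, 4e7, per_task_time = 5.442e-4)
  expect_equal(makespan_component(184, mic), 4 * 5.442e-4)
  expect_equal(makespan_component(0, mic), 0)
  expect_equal(makespan_component(60, mic), 5.442e-4)
  expect_equal(makespan_component(61, mic), 2 * 5.442e-4)
})

test_that("chunk ranges are contiguous, disjoint, and cover the task space", {
  r <- chunk_ranges(c(6, 4), 10)
  expect_equal(r$start, c(0, 6))
  expect_equal(r$end, c(6, 10))
  expect_error(chunk_ranges(c(6, 5), 10), "sum to")
  set.seed(31)
  for (rep in 1:10) {
    counts <- sample(0:50, sample(2:5, 1), replace = TRUE)
    r <- chunk_ranges(counts, sum(counts))
    expect_equal(r$end - r$start, as.numeric(counts))
    expect_equal(r$start[1], 0)
    expect_equal(r$end[length(counts)], sum(counts))
    if (length(counts) > 1) expect_equal(r$start[-1], r$end[-length(counts)])
  }
})

test_that("architecture-aware scheduling reproduces the small-L hybrid plans", {
  plan5 <- schedule_architecture_aware(schedule_request(task_count(5), fx))
  expect_equal(plan5$assignments$architecture, c("CPU", "MIC"))
  expect_equal(plan5$assignments$tasks, c(840, 184))
  expect_equal(plan5$makespan, 2.1768e-3, tolerance = 1e-6)
  expect_equal(plan5$excluded$name, "GPU")

  plan6 <- schedule_architecture_aware(schedule_request(task_count(6), fx))
  expect_equal(plan6$excluded$name, "GPU")
  expect_equal(plan6$makespan, 7.0746e-3, tolerance = 1e-6)

  # at L = 7 the GPU clears the CPU-alone makespan and all three pool up;
  # one GPU round is the maximum
  plan7 <- schedule_architecture_aware(schedule_request(task_count(7), fx))
  expect_setequal(plan7$assignments$architecture, c("CPU", "GPU", "MIC"))
  expect_equal(plan7$makespan, 2.447e-2, tolerance = 1e-6)
})

test_that("a single-architecture request gets everything", {
  solo <- profile_table(list(arch_profile("only", 16, 5, 1e5)))
  plan <- schedule_architecture_aware(schedule_request(1000, solo))
  expect_equal(plan$assignments$tasks, 1000)
  expect_equal(plan$makespan,
               makespan_component(1000, solo$profiles[[1]]))
  expect_equal(nrow(plan$excluded), 0)
})

test_that("plans conserve tasks and partition the index space", {
  for (seed in 1:15) {
    tab <- random_profile_table(sample(2:5, 1), seed)
    C <- sample(1:1e5, 1)
    plan <- schedule_architecture_aware(schedule_request(C, tab))
    a <- plan$assignments
    expect_equal(sum(a$tasks), C)
    expect_equal(a$chunk_end - a$chunk_start, a$tasks)
    expect_equal(a$chunk_start[1], 0)
    expect_equal(a$chunk_end[nrow(a)], C)
    expect_equal(sum(plan$weights), 1)
    expect_equal(plan$makespan, max(a$local_time))
  }
})

test_that("excluded architectures could not beat the final makespan", {
  for (L in 5:15) {
    plan <- schedule_architecture_aware(schedule_request(task_count(L), fx))
    if (nrow(plan$excluded)) {
      t_exc <- vapply(plan$excluded$name, function(nm) {
        Filter(function(p) p$name == nm, fx$profiles)[[1]]$per_task_time
      }, numeric(1))
      expect_true(all(t_exc >= plan$makespan))
    }
  }
  for (seed in 1:15) {
    tab <- random_profile_table(4, seed)
    C <- sample(1e4:1e6, 1)
    plan <- schedule_architecture_aware(schedule_request(C, tab))
    if (nrow(plan$excluded)) {
      t_exc <- vapply(plan$excluded$name, function(nm) {
        Filter(function(p) p$name == nm, tab$profiles)[[1]]$per_task_time
      }, numeric(1))
      expect_true(all(t_exc >= plan$makespan))
    }
  }
})

test_that("the hybrid never loses to the fastest architecture alone on the fixture", {
  sorted <- sort_profiles(fx)$profiles
  for (L in 5:15) {
    C <- task_count(L)
    plan <- schedule_architecture_aware(schedule_request(C, fx))
    alone <- makespan_component(C, sorted[[1]])
    expect_lte(plan$makespan, alone)
  }
})

test_that("without round granularity the hybrid makespan has the closed form", {
  for (seed in 1:10) {
    tab <- random_profile_table(sample(2:4, 1), seed)
    profs <- tab$profiles
    w <- throughput_weights(profs)
    C <- 1e6
    n <- vapply(profs, `[[`, numeric(1), "cores")
    t <- vapply(profs, `[[`, numeric(1), "per_task_time")
    continuous <- unname(w * C / n * t)
    expect_equal(continuous, rep(C / sum(n / t), length(profs)))
    # adding any architecture can only reduce the continuous makespan
    expect_true(all(C / sum(n / t) <= C / (n / t)))
  }
})

test_that("round-model completion matches an event-driven dispatch simulation", {
  set.seed(77)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    cores <- sample(1:8, k, replace = TRUE)
    times <- runif(k, 0.1, 2)
    counts <- sample(0:60, k, replace = TRUE)
    if (sum(counts) == 0 || sum(counts) > 200) next
    profs <- lapply(seq_len(k), function(i) {
      arch_profile(LETTERS[i], cores[i], 1, 100, per_task_time = times[i])
    })
    model <- max(vapply(seq_len(k), function(i) {
      makespan_component(counts[i], profs[[i]])
    }, numeric(1)))
    expect_equal(model, simulate_dispatch(counts, cores, times))
  }
})

test_that("the speed-based baseline reproduces the published makespans from fixed ratios", {
  ratios <- published_baseline_ratios()
  b8 <- schedule_speed_based(schedule_request(task_count(8), fx), ratios = ratios)
  gpu8 <- b8$assignments[b8$assignments$architecture == "GPU", ]
  expect_equal(gpu8$tasks, 10254)
  expect_equal(gpu8$rounds, 5)
  expect_equal(b8$makespan, 1.3271e-1, tolerance = 1e-6)
  b5 <- schedule_speed_based(schedule_request(task_count(5), fx), ratios = ratios)
  expect_equal(b5$makespan, 2.6542e-2, tolerance = 1e-6)  # one GPU round
  expect_error(
    schedule_speed_based(schedule_request(1024, fx), ratios = c(CPU = 0.5, MIC = 0.4, GPU = 0.2)),
    "sum to 1")
})

test_that("the baseline tests eligibility once against the static reference", {
  # on the 1 M-sample times the CPU cluster alone is fastest; the GPU's
  # single-task time exceeds that static makespan at small C and is dropped
  b <- schedule_speed_based(schedule_request(1024, fx))
  expect_equal(b$excluded$name, "GPU")
  expect_setequal(b$assignments$architecture, c("CPU", "MIC"))
  # with one architecture the two algorithms coincide
  solo <- profile_table(list(arch_profile("only", 16, 5, 1e5,
                                          per_task_time = 2e-3,
                                          ref_per_task_time = 2e-3)))
  a <- schedule_architecture_aware(schedule_request(500, solo))
  s <- schedule_speed_based(schedule_request(500, solo))
  expect_equal(s$assignments$tasks, a$assignments$tasks)
  expect_equal(s$makespan, a$makespan)
})

test_that("enhancement percentages match the published comparison", {
  expect_equal(enhancement_percent(2.6542e-2, 2.1768e-3), 91.80, tolerance = 1e-4)
  expect_equal(enhancement_percent(1.3271e-1, 9.790e-2), 26.23, tolerance = 1e-3)
  expect_equal(enhancement_percent(5, 5), 0)
  expect_lt(enhancement_percent(1, 2), 0)
  expect_error(enhancement_percent(0, 1), "> 0")
})

test_that("the proposed scheduler beats the baseline on the fixture for L >= 7", {
  ratios <- published_baseline_ratios()
  for (L in 7:15) {
    req <- schedule_request(task_count(L), fx)
    prop <- schedule_architecture_aware(req)
    base <- schedule_speed_based(req, ratios = ratios)
    expect_gt(enhancement_percent(base$makespan, prop$makespan), 0)
  }
})

test_that("plans serialise to TSV with makespan and exclusion footers", {
  plan <- schedule_architecture_aware(schedule_request(1024, fx))
  path <- tempfile(fileext = ".tsv")
  write_plan_tsv(plan, path)
  lines <- readLines(path)
  body <- read.delim(text = lines[!startsWith(lines, "#")])
  expect_equal(body$architecture, c("CPU", "MIC"))
  expect_equal(body$tasks, c(840, 184))
  expect_true(any(grepl("^# makespan_s\t2.1768E-03", lines)))
  expect_true(any(grepl("^# excluded\tGPU", lines)))
})
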