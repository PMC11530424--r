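# archsched

Architecture-aware scheduling of data-parallel workloads on heterogeneous
compute resources, with an exact brute-force (l,d) DNA motif finder as the
bundled benchmark workload.

## The problem

HPC clusters mix resources with very different shapes — here a 480-core Xeon
CPU partition, a 60-core Xeon Phi (MIC) coprocessor and a 2496-core K20
GPU. Given `C` independent, equal-cost tasks, which resources should run the
job at all, and how should the tasks be split? A device can be *harmful* to
include: if its single-task latency exceeds the time the rest of the pool
needs for the whole job, pooling it only delays completion.

`archsched` profiles each architecture empirically and schedules under a
whole-round completion model. Architecture `i` with `n_i` cores and per-task
time `t_i` (derived from a variance-converged reference sample as
`t_i = T_i / (C'/n_i)`) finishes `c_i` tasks in

```
local_i = t_i * ceil(c_i / n_i)        makespan = max_i local_i
```

Work is split proportionally to throughput `n_i / t_i`. The admission rule
is the package's core idea: architectures are considered in ascending order
of reference-sample total time, and each joins the pool only if its `t_i` is
below the **current hybrid makespan T'**, which is re-computed after every
admission. The speed-based baseline scheduler (also implemented, for
comparison) instead profiles on a small 1 M-task sample and tests everyone
once against the static makespan of the fastest architecture alone.

The benchmark workload is exact planted (l,d) motif search: all `4^L`
candidate L-mers are scored against every window of every sequence, ranked
by occurrence count within the mismatch budget `d`, then total minimum
Hamming distance, then candidate index. Candidates are base-4 indexed
(A=0..T=3), so a scheduler chunk `[start, end)` is a contiguous slice of the
search space and chunk results merge exactly to the monolithic answer.

## Worked example

Schedule the `4^5 = 1024` candidate tasks of an L=5 motif search over the
bundled published profile table:

```r
library(archsched)
plan <- schedule_architecture_aware(
  schedule_request(task_count(5), profile_fixture()), verbose = TRUE)
#> seed pool with CPU: T = 2.8650E-03 s
#> GPU excluded: t = 2.4470E-02 s >= T' = 2.8650E-03 s
#> MIC eligible: t = 5.4420E-04 s < T' = 2.8650E-03 s
#>   new hybrid T' = 2.1768E-03 s
plan
#> <schedule_plan> architecture-aware: 1024 tasks over 2 architecture(s), makespan 2.1768E-03 s
#>  architecture cores per_task_time  share tasks chunk_start chunk_end rounds local_time
#>           CPU   480    9.5500E-04 82.01%   840           0       840      2 1.9100E-03
#>           MIC    60    5.4420E-04 17.99%   184         840      1024      4 2.1768E-03
#> excluded GPU: single-task time 2.4470E-02 s >= hybrid makespan 2.8650E-03 s: ...
```

Reading: the CPU cluster alone would need 3 rounds (2.8650e-3 s). The GPU
cannot finish even one task in that window, so it is excluded and stays free
for other jobs. The MIC joins; the 82%/18% throughput split gives the CPU
840 tasks (2 rounds, 1.9100e-3 s) and the MIC 184 tasks (4 rounds,
2.1768e-3 s), so the job completes in 2.1768e-3 s — a 24% improvement over
the CPU alone and 91.8% over the speed-based baseline, which keeps the GPU
and is pinned to one 2.6542e-2 s GPU round.

Compare both schedulers across motif lengths:

```r
reproduce_validation_tables(L_range = 5:8)$enhancement
#>   L tasks baseline_s proposed_s enhancement_pct
#> 1 5  1024   0.026542  0.0021768        91.79866
#> 2 6  4096   0.026542  0.0070746        73.34564
#> 3 7 16384   0.053084  0.0244700        53.90325
#> 4 8 65536   0.132710  0.0978800        26.24520
```

And run the full pipeline — schedule, solve each chunk, merge — on a
synthetic planted-motif instance:

```r
gp <- generate_planted_instance(num_sequences = 10, sequence_length = 40,
                                motif_length = 6, mutations_per_copy = 1,
                                seed = 7)
out <- run_end_to_end(gp$instance, profile_fixture())
out$result
#> <motif_result> CGGTGC: occurrences 10, total distance 10 (1433600 comparisons)
gp$motif
#> [1] "CGGTGC"
```

The planted motif is recovered: it occurs (within 1 mismatch) in all 10
sequences at total Hamming distance 10 — one substitution per planted copy —
after 4^6 x 10 x 35 = 1,433,600 window comparisons.

A thin command-line wrapper is installed at `inst/cli/archsched` with verbs
`schedule`, `motif`, `generate`, `validate-tables` and `profile`; run it
with `--help` for usage.

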