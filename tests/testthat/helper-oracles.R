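# Independent reference implementations used as test oracles. These stay
# deliberately naive (character-level double loops, event-driven dispatch)
# and never share code with the package internals they check.

# minimum-Hamming score of one candidate, counting every window comparison
naive_score <- function(candidate, sequences, d) {
  cand <- strsplit(candidate, "", fixed = TRUE)[[1]]
  L <- length(cand)
  best_dist <- integer(length(sequences))
  best_pos <- integer(length(sequences))
  comparisons <- 0L
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    dmin <- Inf
    pmin <- NA_integer_
    for (w in seq_len(length(chars) - L + 1L)) {
      dd <- sum(chars[w:(w + L - 1L)] != cand)
      comparisons <- comparisons + 1L
      if (dd < dmin) {
        dmin <- dd
        pmin <- w
      }
    }
    best_dist[i] <- dmin
    best_pos[i] <- pmin
  }
  list(occurrence_count = sum(best_dist <= d),
       total_distance = sum(best_dist),
       positions = best_pos, distances = best_dist,
       comparisons = comparisons)
}

# all L-mers in lexicographic (= candidate index) order, built by recursion
naive_all_lmers <- function(L) {
  if (L == 0L) return("")
  shorter <- naive_all_lmers(L - 1L)
  as.vector(t(outer(shorter, c("A", "C", "G", "T"), paste0)))
}

# exhaustive solve under (occ desc, total asc, lexicographic asc) ranking,
# with an instrumented comparison counter
naive_solve <- function(sequences, L, d) {
  candidates <- naive_all_lmers(L)
  best <- NULL
  comparisons <- 0
  for (cand in candidates) {
    sc <- naive_score(cand, sequences, d)
    comparisons <- comparisons + sc$comparisons
    if (is.null(best) ||
        sc$occurrence_count > best$occurrence_count ||
        (sc$occurrence_count == best$occurrence_count &&
         sc$total_distance < best$total_distance)) {
      best <- list(motif = cand,
                   occurrence_count = sc$occurrence_count,
                   total_distance = sc$total_distance)
    }
  }
  best$comparisons <- comparisons
  best
}

# event-driven dispatch: each architecture assigns its tasks one at a time to
# its earliest-free core; completion time is the latest core finish
simulate_dispatch <- function(counts, cores, times) {
  finish <- 0
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    free <- numeric(cores[i])
    for (task in seq_len(counts[i])) {
      j <- which.min(free)
      free[j] <- free[j] + times[i]
    }
    finish <- max(finish, max(free))
  }
  finish
}

# random profile tables for property tests (internally consistent T)
random_profile_table <- function(k, seed) {
  set.seed(seed)
  profiles <- lapply(seq_len(k), function(i) {
    cores <- sample(1:64, 1)
    t <- stats::runif(1, 1e-4, 1e-1)
    size <- 1e6
    arch_profile(LETTERS[i], cores, t * size / cores, size)
  })
  profile_table(profiles)
}

fixture_table <- function() profile_fixture()
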