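# Exact brute-force (l,d) motif finding over DNA. Every length-L string over
# {A,C,G,T} is a candidate, indexed 0..4^L-1 in base 4 (A=0, C=1, G=2, T=3,
# leftmost character most significant), so lexicographic candidate order is
# numeric index order and a contiguous index range is a meaningful work chunk.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Number of candidate L-mers
#'
#' The brute-force search space over motifs of length `L` on an alphabet of
#' `alphabet_size` symbols contains `alphabet_size^L` candidates; this is the
#' total task count \eqn{C} handed to the scheduler.
#'
#' @param L Motif length (>= 0).
#' @param alphabet_size Alphabet size (default 4 for DNA).
#' @return The candidate count as a double (exact for all supported `L`).
#' @export
#' @examples
#' task_count(15)  # 1,073,741,824 candidate 15-mers
task_count <- function(L, alphabet_size = 4) {
  if (!is.numeric(L) || length(L) != 1L || L < 0 || L != floor(L)) {
    stop("'L' must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(alphabet_size) || alphabet_size < 1) {
    stop("'alphabet_size' must be >= 1", call. = FALSE)
  }
  alphabet_size^L
}

#' Decode a candidate index into an L-mer
#'
#' @param index Candidate index in `[0, 4^L)` (0-based).
#' @param L Motif length.
#' @return The L-mer string.
#' @seealso [encode_candidate()]
#' @export
#' @examples
#' decode_candidate(27, 4)  # "AACT"... see encode_candidate("ACGT")
decode_candidate <- function(index, L) {
  if (!is.numeric(index) || length(index) != 1L || index < 0 ||
      index != floor(index) || index >= task_count(L)) {
    stop("'index' must be an integer in [0, 4^L)", call. = FALSE)
  }
  paste(DNA_ALPHABET[decode_codes(index, L) + 1L], collapse = "")
}

# integer codes 0..3 of a candidate index, most significant first
decode_codes <- function(index, L) {
  codes <- integer(L)
  v <- index
  for (j in seq(L, 1L)) {
    codes[j] <- v %% 4
    v <- v %/% 4
  }
  codes
}

#' Encode an L-mer as its candidate index
#'
#' Base-4 positional code with A=0, C=1, G=2, T=3 and the leftmost character
#' most significant, so `encode_candidate(decode_candidate(i, L)) == i`.
#'
#' @param lmer String over A,C,G,T.
#' @return The 0-based candidate index (double).
#' @export
#' @examples
#' encode_candidate("ACGT")  # 0*64 + 1*16 + 2*4 + 3 = 27
encode_candidate <- function(lmer) {
  codes <- lmer_codes(lmer)
  sum(codes * 4^seq(length(codes) - 1L, 0L))
}

lmer_codes <- function(lmer) {
  stopifnot(is.character(lmer), length(lmer) == 1L)
  chars <- strsplit(lmer, "", fixed = TRUE)[[1L]]
  codes <- match(chars, DNA_ALPHABET) - 1L
  if (anyNA(codes)) {
    stop("candidate contains non-ACGT characters: ", lmer, call. = FALSE)
  }
  codes
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Strings of equal length.
#' @return Number of mismatching positions.
#' @export
hamming <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("'a' and 'b' must have equal length", call. = FALSE)
  }
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Construct a motif-finding instance
#'
#' Holds the five dimensions of the problem: the sequence set (its size
#' \eqn{S}), the common sequence length \eqn{N}, the motif length \eqn{L},
#' the permitted number of mismatches \eqn{d}, and the alphabet.
#'
#' @param sequences Character vector of DNA sequences, all the same length,
#'   uppercase A/C/G/T only.
#' @param motif_length Motif length `L` with `1 <= L <= N`.
#' @param max_mismatches Permitted mismatches `d` (>= 0). `d` does not change
#'   which candidates are enumerated (brute force scans all of them); it
#'   defines which sequences count as occurrences in the score.
#' @return Object of class `motif_instance`.
#' @export
motif_instance <- function(sequences, motif_length, max_mismatches) {
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("'sequences' must be a non-empty character vector", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all sequences must have equal length (got lengths ",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  N <- lens[[1L]]
  if (!is.numeric(motif_length) || motif_length < 1 || motif_length > N ||
      motif_length != floor(motif_length)) {
    stop("'motif_length' must be an integer in [1, sequence length]",
         call. = FALSE)
  }
  if (!is.numeric(max_mismatches) || max_mismatches < 0 ||
      max_mismatches != floor(max_mismatches)) {
    stop("'max_mismatches' must be a non-negative integer", call. = FALSE)
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  codes <- vapply(chars, function(cc) {
    m <- match(cc, DNA_ALPHABET) - 1L
    if (anyNA(m)) {
      stop("sequences may only contain A, C, G, T (found: ",
           paste(unique(cc[is.na(m)]), collapse = ", "), ")", call. = FALSE)
    }
    m
  }, integer(N))
  structure(
    list(sequences = sequences,
         seq_codes = t(codes),                 # S x N integer matrix
         num_sequences = length(sequences),
         sequence_length = N,
         motif_length = as.integer(motif_length),
         max_mismatches = as.integer(max_mismatches),
         alphabet = DNA_ALPHABET),
    class = "motif_instance"
  )
}

#' @export
print.motif_instance <- function(x, ...) {
  cat(sprintf("<motif_instance> S=%d sequences of N=%d bp; L=%d, d=%d (%s candidates)\n",
              x$num_sequences, x$sequence_length, x$motif_length,
              x$max_mismatches,
              format(task_count(x$motif_length), scientific = FALSE, big.mark = ",")))
  invisible(x)
}

#' Read a motif-finding instance from FASTA
#'
#' Sequences are read with `Biostrings::readDNAStringSet()`, uppercased, and
#' required to be equal-length strings over A/C/G/T.
#'
#' @param path Path to a plain multi-record FASTA file.
#' @param motif_length,max_mismatches See [motif_instance()].
#' @return A [motif_instance()].
#' @export
read_fasta_instance <- function(path, motif_length, max_mismatches) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  motif_instance(unname(toupper(as.character(set))), motif_length,
                 max_mismatches)
}

# per-offset mismatch slices reused across all candidates of one chunk:
# slices[[a]][[j]][i, w] == 1 iff sequence i, window starting at w (1-based),
# position j differs from letter code a-1
window_mismatch_slices <- function(instance) {
  codes <- instance$seq_codes
  L <- instance$motif_length
  W <- instance$sequence_length - L + 1L
  lapply(0:3, function(a) {
    M <- codes != a
    lapply(seq_len(L), function(j) {
      m <- M[, j:(j + W - 1L), drop = FALSE]
      storage.mode(m) <- "integer"
      m
    })
  })
}

# distances of one candidate (codes 0..3) against every window: S x W matrix
candidate_window_distances <- function(cand_codes, slices, S, W) {
  D <- matrix(0L, S, W)
  for (j in seq_along(cand_codes)) {
    D <- D + slices[[cand_codes[j] + 1L]][[j]]
  }
  D
}

score_from_distances <- function(D, d) {
  S <- nrow(D)
  pos <- integer(S)
  dist <- integer(S)
  for (i in seq_len(S)) {
    r <- D[i, ]
    p <- which.min(r)    # earliest window wins ties
    pos[i] <- p
    dist[i] <- r[p]
  }
  list(occurrence_count = sum(dist <= d),
       total_distance = sum(dist),
       positions = pos, distances = dist)
}

#' Score one candidate motif against an instance
#'
#' For each sequence the candidate is compared with every length-`L` window
#' (all `N - L + 1` of them); the sequence's contribution is its minimum
#' Hamming distance and the earliest window achieving it. A sequence is an
#' *occurrence* when that minimum distance is at most `d`. Candidates are
#' ranked by occurrence count (descending), then total distance (ascending),
#' then candidate index (ascending) — a deterministic order that respects the
#' (l,d) semantics of the mismatch budget.
#'
#' @param candidate L-mer string of length `instance$motif_length`.
#' @param instance A [motif_instance()].
#' @return List with `occurrence_count`, `total_distance`, `positions`
#'   (data frame: sequence, position (1-based window start), distance) and
#'   `comparisons_done` (always `S * (N - L + 1)`).
#' @export
score_candidate <- function(candidate, instance) {
  stopifnot(inherits(instance, "motif_instance"))
  cand_codes <- lmer_codes(candidate)
  if (length(cand_codes) != instance$motif_length) {
    stop("candidate length ", length(cand_codes), " != motif length ",
         instance$motif_length, call. = FALSE)
  }
  S <- instance$num_sequences
  W <- instance$sequence_length - instance$motif_length + 1L
  slices <- window_mismatch_slices(instance)
  D <- candidate_window_distances(cand_codes, slices, S, W)
  sc <- score_from_distances(D, instance$max_mismatches)
  list(occurrence_count = sc$occurrence_count,
       total_distance = sc$total_distance,
       positions = data.frame(sequence = seq_len(S),
                              position = sc$positions,
                              distance = sc$distances),
       comparisons_done = S * W)
}

#' Total comparison count of a full brute-force solve
#'
#' Every one of the \eqn{D_5^{D_3}} candidates is compared with every window
#' of every sequence:
#' \deqn{D_5^{D_3} \cdot D_1 \cdot (D_2 - D_3 + 1).}
#'
#' @param D1 Number of sequences.
#' @param D2 Sequence length.
#' @param D3 Motif length (`D3 <= D2`).
#' @param D5 Alphabet size.
#' @return Comparison count as a double.
#' @export
#' @examples
#' count_comparisons(20, 600, 15, 4)  # ~1.26e13 window comparisons
count_comparisons <- function(D1, D2, D3, D5) {
  if (!all(vapply(list(D1, D2, D3, D5), function(x)
    is.numeric(x) && length(x) == 1L && x >= 1 && x == floor(x), logical(1)))) {
    stop("all dimensions must be positive integers", call. = FALSE)
  }
  if (D3 > D2) {
    stop("motif length D3 must not exceed sequence length D2", call. = FALSE)
  }
  D5^D3 * D1 * (D2 - D3 + 1)
}

# (occ desc, total asc, index asc); NULL = neutral element
better_candidate <- function(occ, tot, idx, best) {
  if (is.null(best)) return(TRUE)
  if (occ != best$occurrence_count) return(occ > best$occurrence_count)
  if (tot != best$total_distance) return(tot < best$total_distance)
  idx < best$index
}

#' Solve a contiguous chunk of the candidate space
#'
#' Scores every candidate index in `[start, end)` and keeps the best under
#' the ranking of [score_candidate()]. Chunks are the unit of work the
#' scheduler assigns to architectures; any disjoint full partition of
#' `[0, 4^L)`, solved chunk by chunk and merged with [merge_results()],
#' yields exactly the monolithic [brute_force_solve()] answer.
#'
#' @param instance A [motif_instance()].
#' @param start,end 0-based half-open candidate-index bounds,
#'   `0 <= start <= end <= 4^L`.
#' @return Object of class `chunk_result`: `start`, `end`, `best_index`,
#'   `best_candidate`, `occurrence_count`, `total_distance`, `positions`,
#'   `comparisons_done`. An empty range gives the neutral result
#'   (`best_candidate = NA`, zero comparisons).
#' @export
solve_chunk <- function(instance, start, end) {
  stopifnot(inherits(instance, "motif_instance"))
  C <- task_count(instance$motif_length)
  if (!is.numeric(start) || !is.numeric(end) || start != floor(start) ||
      end != floor(end) || start < 0 || end > C || start > end) {
    stop("need 0 <= start <= end <= 4^L (got [", start, ", ", end, "))",
         call. = FALSE)
  }
  S <- instance$num_sequences
  W <- instance$sequence_length - instance$motif_length + 1L
  d <- instance$max_mismatches
  L <- instance$motif_length
  best <- NULL
  if (end > start) {
    slices <- window_mismatch_slices(instance)
    for (idx in seq(start, end - 1)) {
      cand_codes <- decode_codes(idx, L)
      D <- candidate_window_distances(cand_codes, slices, S, W)
      sc <- score_from_distances(D, d)
      if (better_candidate(sc$occurrence_count, sc$total_distance, idx, best)) {
        best <- list(index = idx,
                     occurrence_count = sc$occurrence_count,
                     total_distance = sc$total_distance,
                     positions = sc$positions, distances = sc$distances)
      }
    }
  }
  structure(
    list(start = start, end = end,
         best_index = if (is.null(best)) NA_real_ else best$index,
         best_candidate = if (is.null(best)) NA_character_
                          else decode_candidate(best$index, L),
         occurrence_count = if (is.null(best)) NA_integer_ else best$occurrence_count,
         total_distance = if (is.null(best)) NA_integer_ else best$total_distance,
         positions = if (is.null(best)) NULL else
           data.frame(sequence = seq_len(S), position = best$positions,
                      distance = best$distances),
         comparisons_done = (end - start) * S * W),
    class = "chunk_result"
  )
}

#' @export
print.chunk_result <- function(x, ...) {
  cat(sprintf("<chunk_result> [%s, %s): best %s (occ %s, dist %s), %s comparisons\n",
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              x$best_candidate, x$occurrence_count, x$total_distance,
              format(x$comparisons_done, scientific = FALSE)))
  invisible(x)
}

#' Merge chunk results into a motif result
#'
#' Reduction step for scheduled chunks: picks the best candidate across the
#' parts under the same (occurrence count, total distance, index) order used
#' within each chunk, and sums the comparison counters. The operation is
#' associative and commutative, and empty-range results are neutral, so any
#' grouping of a full partition gives the monolithic answer.
#'
#' @param parts List of `chunk_result` objects with pairwise disjoint ranges.
#' @return Object of class `motif_result`.
#' @export
merge_results <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L) {
    stop("'parts' must be a non-empty list of chunk results", call. = FALSE)
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "chunk_result")))
  starts <- vapply(parts, `[[`, numeric(1), "start")
  ends <- vapply(parts, `[[`, numeric(1), "end")
  ord <- order(starts, ends)
  nonempty <- which(ends[ord] > starts[ord])
  if (length(nonempty) > 1L) {
    s <- starts[ord][nonempty]
    e <- ends[ord][nonempty]
    if (any(s[-1L] < e[-length(e)])) {
      stop("chunk ranges overlap", call. = FALSE)
    }
  }
  best <- NULL
  for (p in parts) {
    if (is.na(p$best_index)) next
    if (better_candidate(p$occurrence_count, p$total_distance, p$best_index, best)) {
      best <- list(index = p$best_index,
                   candidate = p$best_candidate,
                   occurrence_count = p$occurrence_count,
                   total_distance = p$total_distance,
                   positions = p$positions)
    }
  }
  if (is.null(best)) {
    stop("all chunks are empty; nothing to merge", call. = FALSE)
  }
  structure(
    list(motif = best$candidate,
         index = best$index,
         score = list(occurrence_count = best$occurrence_count,
                      total_distance = best$total_distance),
         occurrences = best$positions,
         comparisons_done = sum(vapply(parts, `[[`, numeric(1),
                                       "comparisons_done"))),
    class = "motif_result"
  )
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result> %s: occurrences %d, total distance %d (%s comparisons)\n",
              x$motif, x$score$occurrence_count, x$score$total_distance,
              format(x$comparisons_done, scientific = FALSE)))
  invisible(x)
}

#' Exact brute-force motif search
#'
#' Scores all `4^L` candidates and returns the global optimum under the
#' deterministic ranking of [score_candidate()]. A guard rail refuses
#' candidate spaces beyond `max_candidates` (default `4^12`): larger spaces
#' should be solved in chunks ([solve_chunk()]) distributed by the scheduler.
#'
#' @param instance A [motif_instance()].
#' @param max_candidates Largest candidate space this function will scan in
#'   one call.
#' @return A `motif_result` (see [merge_results()]).
#' @export
brute_force_solve <- function(instance, max_candidates = 4^12) {
  stopifnot(inherits(instance, "motif_instance"))
  C <- task_count(instance$motif_length)
  if (C > max_candidates) {
    stop(sprintf(paste0(
      "candidate space 4^%d = %s exceeds the budget of %s; ",
      "solve in chunks with solve_chunk()/merge_results() or raise 'max_candidates'"),
      instance$motif_length, format(C, scientific = FALSE),
      format(max_candidates, scientific = FALSE)), call. = FALSE)
  }
  merge_results(list(solve_chunk(instance, 0, C)))
}
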