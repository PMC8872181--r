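# Independent oracles used to cross-check the TDRL search.
#
# oracle_apply / oracle_min_scenarios re-implement the event semantics
# from scratch (plain index arithmetic, exhaustive subset enumeration
# via combn) and share no code with the package's search. Frontier
# states are collapsed per level — the same collapse the scenario
# dedup-by-state-sequence semantics implies — because the raw subset
# space at two events is astronomically larger than the distinct-state
# space; the collapse does not affect reachability or minimal counts.

oracle_apply <- function(segment, i, j, losses) {
  dup <- c(segment[seq_len(j)], segment[i:j],
           if (j < length(segment)) segment[(j + 1):length(segment)])
  out <- if (length(losses)) dup[-losses] else dup
  if (length(setdiff(setdiff(unique(segment), "CR"), out))) return(NULL)
  out
}

# All distinct states reachable from `seg` in one event (full subset
# enumeration over loss positions).
oracle_successors <- function(seg) {
  seen <- character(); out <- list()
  n <- length(seg)
  for (i in seq_len(n)) for (j in i:n) {
    d <- n + (j - i + 1L)
    for (k in 0:(d - 1L)) {
      subsets <- if (k == 0L) matrix(integer(), 0L, 1L) else utils::combn(d, k)
      for (col in seq_len(ncol(subsets))) {
        res <- oracle_apply(seg, i, j, subsets[, col])
        if (is.null(res)) next
        key <- paste(res, collapse = "|")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- res
        }
      }
    }
  }
  out
}

# Can `seg` be turned into exactly `target` by one event?  Only loss
# subsets of the cardinality that matches the target length can do so,
# which keeps the enumeration exhaustive but tractable.
oracle_one_event_hit <- function(seg, target) {
  n <- length(seg); t <- length(target)
  for (i in seq_len(n)) for (j in i:n) {
    d <- n + (j - i + 1L)
    k <- d - t
    if (k < 0L || k >= d) next
    subsets <- if (k == 0L) matrix(0L, 0L, 1L) else utils::combn(d, k)
    for (col in seq_len(ncol(subsets))) {
      res <- oracle_apply(seg, i, j, subsets[, col])
      if (!is.null(res) && identical(res, target)) return(TRUE)
    }
  }
  FALSE
}

# Minimal event count and the set of minimal state sequences (iterative
# deepening over exhaustively enumerated events).
oracle_min_scenarios <- function(from, to, max_events = 2L) {
  if (identical(from, to)) {
    return(list(min_events = 0L, sequences = list(list(from))))
  }
  frontier <- list(list(from))
  for (k in seq_len(max_events)) {
    hits <- Filter(function(p) oracle_one_event_hit(p[[length(p)]], to),
                   frontier)
    if (length(hits)) {
      return(list(min_events = k,
                  sequences = lapply(hits, function(p) c(p, list(to)))))
    }
    if (k == max_events) break
    nxt <- list()
    for (p in frontier) {
      prior <- vapply(p, paste, character(1L), collapse = "|")
      for (succ in oracle_successors(p[[length(p)]])) {
        if (paste(succ, collapse = "|") %in% prior) next
        nxt[[length(nxt) + 1L]] <- c(p, list(succ))
      }
    }
    frontier <- nxt
  }
  list(min_events = NA_integer_, sequences = list())
}

# Normalise a list of state sequences to a sorted character key set.
sequence_keys <- function(seqs) {
  sort(vapply(seqs, function(states) {
    paste(vapply(states, paste, character(1L), collapse = "|"),
          collapse = " -> ")
  }, character(1L)))
}
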