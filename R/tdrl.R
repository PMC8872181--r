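# Tandem duplication / random loss (TDRL) event model on a linear gene
# segment.
#
# An event duplicates a contiguous block in tandem and then deletes an
# arbitrary subset of positions of the post-duplication segment (loss of
# redundant copies is genome-wide, not confined to the duplicated block:
# a duplication elsewhere can render an older copy redundant). The only
# constraint is essentiality: every gene name other than CR that was
# present before the event must retain at least one copy; control-region
# copies may be freely gained or lost. Segments are linear because all
# of the rearrangement variation handled here is confined to the
# hotspot between the fixed anchors tRNA-Thr and rrnS, which bounds the
# combinatorics.

#' Construct a TDRL event
#'
#' @param block Integer pair `c(i, j)`, 1-based inclusive indices of the
#'   duplicated block in the segment the event is applied to.
#' @param losses Integer vector of 1-based positions deleted from the
#'   post-duplication segment (which has `length(segment) + j - i + 1`
#'   positions); may be empty, which retains both copies.
#' @return An object of class `tdrl_event`.
#' @export
tdrl_event <- function(block, losses = integer()) {
  block <- as.integer(block)
  if (length(block) != 2L || anyNA(block) || block[1L] > block[2L] ||
      block[1L] < 1L) {
    stop("block must be c(i, j) with 1 <= i <= j")
  }
  losses <- sort(unique(as.integer(losses)))
  if (length(losses) && losses[1L] < 1L) stop("loss positions must be >= 1")
  structure(list(block = block, losses = losses), class = "tdrl_event")
}

# Segment helpers: tokens are canonical labels; short tokens accepted.
.as_segment <- function(tokens) {
  if (inherits(tokens, "gene_order")) tokens <- tokens$tokens$name
  if (is.data.frame(tokens)) tokens <- tokens$name
  .from_short(as.character(tokens))
}

#' Positional copy labels of a segment
#'
#' @param segment Character vector of gene tokens.
#' @return Display strings with `a`, `b`, `c` copy letters attached to
#'   duplicated names in left-to-right order (e.g. `"CR(a)"`).
#' @export
label_copies <- function(segment) {
  segment <- .as_segment(segment)
  out <- short_token(segment)
  for (nm in unique(segment)) {
    idx <- which(segment == nm)
    if (length(idx) >= 2L) {
      out[idx] <- paste0(out[idx], "(", letters[seq_along(idx)], ")")
    }
  }
  out
}

#' Apply one TDRL event to a linear segment
#'
#' Inserts a tandem copy of `segment[i..j]` immediately after position
#' `j`, then deletes the loss positions. An event that would extinguish
#' every copy of a non-CR gene is invalid.
#'
#' @param segment Character vector of gene tokens (canonical labels or
#'   short tokens).
#' @param event A [tdrl_event()].
#' @return The resulting segment (character vector of canonical labels).
#' @examples
#' apply_tdrl_event(c("P", "CR", "F"), tdrl_event(c(1, 3)))
#' @export
apply_tdrl_event <- function(segment, event) {
  segment <- .as_segment(segment)
  i <- event$block[1L]; j <- event$block[2L]
  if (j > length(segment)) {
    stop(sprintf("block [%d, %d] exceeds segment length %d", i, j,
                 length(segment)))
  }
  dup <- append(segment, segment[i:j], after = j)
  if (length(event$losses) && max(event$losses) > length(dup)) {
    stop(sprintf("loss position %d exceeds post-duplication length %d",
                 max(event$losses), length(dup)))
  }
  out <- if (length(event$losses)) dup[-event$losses] else dup
  essential <- setdiff(unique(segment), "CR")
  gone <- setdiff(essential, out)
  if (length(gone)) {
    stop("event extinguishes essential gene(s): ",
         paste(short_token(gone), collapse = ", "))
  }
  out
}

#' Construct a TDRL scenario
#'
#' @param start Character vector of gene tokens, the starting segment.
#' @param events List of [tdrl_event()] objects, applied in order.
#' @param end Optional expected final segment (checked lazily by
#'   [validate_tdrl_scenario()]).
#' @param name Optional scenario name.
#' @return An object of class `tdrl_scenario`.
#' @export
tdrl_scenario <- function(start, events = list(), end = NULL, name = NULL) {
  start <- .as_segment(start)
  stopifnot(all(vapply(events, inherits, logical(1L), "tdrl_event")))
  if (!is.null(end)) end <- .as_segment(end)
  structure(list(start = start, events = events, end = end, name = name),
            class = "tdrl_scenario")
}

#' Apply a TDRL scenario
#'
#' @param scenario A [tdrl_scenario()].
#' @return The final segment, with attribute `"trace"`: list of every
#'   intermediate segment from the start state to the final state.
#' @export
apply_tdrl_scenario <- function(scenario) {
  seg <- scenario$start
  trace <- list(seg)
  for (ev in scenario$events) {
    seg <- apply_tdrl_event(seg, ev)
    trace[[length(trace) + 1L]] <- seg
  }
  attr(seg, "trace") <- trace
  seg
}

#' Validate a TDRL scenario against a target order
#'
#' @param from Starting segment; must equal `scenario$start` (token
#'   names), otherwise an error (not `FALSE`) is raised.
#' @param to Target segment.
#' @param scenario A [tdrl_scenario()].
#' @return List with `valid` (`TRUE` iff the scenario transforms `from`
#'   into `to`, comparing token names and ignoring copy labels) and
#'   `trace` (list of intermediate segments, including start and end).
#' @export
validate_tdrl_scenario <- function(from, to, scenario) {
  from <- .as_segment(from); to <- .as_segment(to)
  if (!identical(from, scenario$start)) {
    stop("scenario start order does not match 'from'")
  }
  final <- apply_tdrl_scenario(scenario)
  list(valid = identical(as.character(final), to),
       trace = attr(final, "trace"))
}

#' Render a TDRL trace as arrow-joined token lists
#'
#' @param trace List of segments (e.g. from [validate_tdrl_scenario()]).
#' @return Single string like `"P-CR-F -> P(a)-CR(a)-F(a)-P(b)-CR(b)-F(b)"`.
#' @export
render_trace <- function(trace) {
  paste(vapply(trace, function(s) paste(label_copies(s), collapse = "-"),
               character(1L)),
        collapse = " -> ")
}

#' Search configuration for minimal-scenario search
#'
#' @param max_events Maximum number of duplication events (default 3).
#' @param max_segment_length Maximum segment length admitted anywhere in
#'   the search (default 12).
#' @param max_paths Safety cap on the number of candidate event paths
#'   held at any search depth.
#' @return A `tdrl_search_config` list.
#' @export
tdrl_search_config <- function(max_events = 3L, max_segment_length = 12L,
                               max_paths = 200000L) {
  stopifnot(max_events >= 1L, max_segment_length >= 1L, max_paths >= 1L)
  structure(list(max_events = as.integer(max_events),
                 max_segment_length = as.integer(max_segment_length),
                 max_paths = as.integer(max_paths)),
            class = "tdrl_search_config")
}

# Is `sub` a subsequence of `seq`? (greedy two-pointer)
.is_subsequence <- function(sub, seq) {
  i <- 1L
  for (x in seq) {
    if (i <= length(sub) && identical(sub[i], x)) i <- i + 1L
  }
  i > length(sub)
}

# Greedy leftmost embedding of `sub` in `seq`; returns kept positions.
.embed_positions <- function(sub, seq) {
  kept <- integer(length(sub))
  i <- 1L
  for (p in seq_along(seq)) {
    if (i <= length(sub) && identical(sub[i], seq[p])) {
      kept[i] <- p
      i <- i + 1L
    }
  }
  if (i <= length(sub)) stop("not a subsequence")  # caller guarantees
  kept
}

# First block (i ascending, then j ascending) whose post-duplication
# segment contains `to` as a subsequence; NULL if none.
.one_event_block <- function(from, to) {
  n <- length(from)
  if (length(setdiff(setdiff(unique(from), "CR"), to))) return(NULL)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dup <- append(from, from[i:j], after = j)
      if (length(to) <= length(dup) && .is_subsequence(to, dup)) {
        return(c(i, j))
      }
    }
  }
  NULL
}

# Deterministic witness event for the step `from` -> `to`.
.witness_event <- function(from, to) {
  blk <- .one_event_block(from, to)
  if (is.null(blk)) stop("no single event transforms the given states")
  dup <- append(from, from[blk[1L]:blk[2L]], after = blk[2L])
  kept <- .embed_positions(to, dup)
  tdrl_event(blk, setdiff(seq_along(dup), kept))
}

# All distinct subsequences of `x` (each exactly once), as a list, in a
# deterministic order (first-occurrence expansion).
.distinct_subsequences <- function(x) {
  n <- length(x)
  memo <- vector("list", n + 1L)
  rec <- function(pos) {
    if (pos > n) return(list(character()))
    if (!is.null(memo[[pos]])) return(memo[[pos]])
    out <- list(character())
    seen <- character()
    for (q in pos:n) {
      if (x[q] %in% seen) next
      seen <- c(seen, x[q])
      for (tail in rec(q + 1L)) {
        out[[length(out) + 1L]] <- c(x[q], tail)
      }
    }
    memo[[pos]] <<- out
    out
  }
  rec(1L)
}

# All distinct successor segments of `seg` under one TDRL event,
# respecting essentiality and the segment-length bound. Deterministic
# order: block (i asc, j asc), then subsequence enumeration order;
# deduplicated across blocks.
.distinct_successors <- function(seg, max_len) {
  essential <- setdiff(unique(seg), "CR")
  seen <- new.env(parent = emptyenv())
  out <- list()
  n <- length(seg)
  for (i in seq_len(n)) {
    for (j in i:n) {
      dup <- append(seg, seg[i:j], after = j)
      for (cand in .distinct_subsequences(dup)) {
        if (length(cand) == 0L || length(cand) > max_len) next
        if (length(setdiff(essential, cand))) next
        key <- paste(cand, collapse = "\r")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- cand
        if (length(out) > 100000L) {
          stop("successor enumeration exceeded 100000 distinct states; ",
               "reduce the segment or max_segment_length")
        }
      }
    }
  }
  out
}

#' Search for minimal TDRL scenarios between two segments
#'
#' Breadth-first search over TDRL events for the smallest number of
#' duplication events transforming `from` into `to` (token names; copy
#' labels play no role). The cost of a scenario is its number of
#' duplication events; losses are free byproducts. Scenarios are
#' deduplicated by their sequence of intermediate segments: distinct
#' block/loss choices that pass through identical states count as one
#' scenario, and each returned scenario carries the deterministic
#' witness event for every step (first feasible block, leftmost
#' embedding of the next state).
#'
#' @param from,to Character vectors of gene tokens.
#' @param config A [tdrl_search_config()].
#' @return List with `reachable` (logical), `min_events` (smallest event
#'   count, `NA` when unreachable within `config$max_events`) and
#'   `scenarios` (list of [tdrl_scenario()] objects; all minimal
#'   scenarios). Unreachability is a result, not an error.
#' @examples
#' search_min_scenarios(c("P", "CR", "F"),
#'                      c("CR", "P", "F", "CR"))$min_events  # 2
#' @export
search_min_scenarios <- function(from, to, config = tdrl_search_config()) {
  from <- .as_segment(from); to <- .as_segment(to)
  if (length(from) > config$max_segment_length ||
      length(to) > config$max_segment_length) {
    stop("segment exceeds config$max_segment_length")
  }
  missing <- setdiff(unique(to), unique(from))
  if (length(missing)) {
    stop("genes in 'to' absent from 'from': ",
         paste(short_token(missing), collapse = ", "))
  }
  as_result <- function(k, paths) {
    scenarios <- lapply(paths, function(states) {
      events <- lapply(seq_len(length(states) - 1L), function(s) {
        .witness_event(states[[s]], states[[s + 1L]])
      })
      tdrl_scenario(from, events, end = to)
    })
    list(reachable = TRUE, min_events = k, scenarios = scenarios)
  }
  if (identical(from, to)) {
    return(as_result(0L, list(list(from))))
  }
  # frontier: all event paths of length d-1, as state sequences
  frontier <- list(list(from))
  for (k in seq_len(config$max_events)) {
    hits <- Filter(function(states) {
      !is.null(.one_event_block(states[[length(states)]], to))
    }, frontier)
    if (length(hits)) {
      return(as_result(k, lapply(hits, function(s) c(s, list(to)))))
    }
    if (k == config$max_events) break
    nxt <- list()
    for (states in frontier) {
      last <- states[[length(states)]]
      prior <- vapply(states, paste, character(1L), collapse = "\r")
      for (succ in .distinct_successors(last, config$max_segment_length)) {
        # a state revisit can never lie on a minimal path
        if (paste(succ, collapse = "\r") %in% prior) next
        nxt[[length(nxt) + 1L]] <- c(states, list(succ))
      }
      if (length(nxt) > config$max_paths) {
        stop("search exceeded config$max_paths candidate paths")
      }
    }
    frontier <- nxt
  }
  list(reachable = FALSE, min_events = NA_integer_, scenarios = list())
}

#' Read a TDRL scenario from JSON
#'
#' The format has fields `start` (token array), `events` (array of
#' objects with `block` = 1-based `[i, j]` and `losses` = array of
#' 1-based post-duplication positions), and optionally `end` and
#' `name`. Two scenario files encoding the duplication pathway from the
#' ancestral Pro–CR–Phe hotspot to the type V and type IX arrangements
#' ship with the package under `inst/extdata/`.
#'
#' @param path JSON path.
#' @return A [tdrl_scenario()].
#' @export
read_tdrl_scenario <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  events <- lapply(x$events, function(e) {
    tdrl_event(unlist(e$block), unlist(e$losses))
  })
  tdrl_scenario(unlist(x$start), events,
                end = if (!is.null(x$end)) unlist(x$end) else NULL,
                name = x$name)
}

#' Write a TDRL scenario as JSON
#'
#' @param scenario A [tdrl_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tdrl_scenario <- function(scenario, path) {
  x <- list(
    name = scenario$name,
    start = short_token(scenario$start),
    events = lapply(scenario$events, function(e) {
      list(block = e$block, losses = e$losses)
    }),
    end = if (!is.null(scenario$end)) short_token(scenario$end) else NULL
  )
  jsonlite::write_json(x[!vapply(x, is.null, logical(1L))], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
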