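# Attractor enumeration under synchronous updating.
#
# Under a deterministic synchronous update the state space is a functional
# graph: every state has exactly one successor, so every trajectory ends in a
# cycle (period 1 = fixed point). Exhaustive mode walks every integer code
# with memoized attractor assignment (each state visited O(1) amortized);
# sampled mode follows trajectories from random initial states.

new_attractor <- function(codes, net, basin_size = NA_real_,
                          basin_fraction = NA_real_, n_hits = NA_integer_) {
  codes <- canonical_rotation(as.numeric(codes))
  n <- length(net$nodes)
  states <- codes_to_states(codes, n)
  colnames(states) <- net$nodes
  structure(list(codes = codes, states = states,
                 period = length(codes),
                 basin_size = basin_size,
                 basin_fraction = basin_fraction,
                 n_hits = n_hits),
            class = "attractor")
}

attractor_key <- function(codes) paste(codes, collapse = ",")

canonical_rotation <- function(codes) {
  i <- which.min(codes)
  if (i == 1L) codes else c(codes[i:length(codes)], codes[seq_len(i - 1L)])
}

#' Canonicalize a cycle of states
#'
#' Rotates a cycle so that the state with the smallest integer code comes
#' first; two discoveries of the same cycle from different entry points then
#' compare equal. The input must be a genuine minimal cycle: all states
#' distinct, and (when `net` is given) each state's synchronous successor is
#' the next state, wrapping around.
#'
#' @param states a matrix of 0/1 rows (one state per row) or a list of 0/1
#'   vectors.
#' @param net optional [boolean_network()]; if supplied the succession is
#'   verified and violations are an error.
#' @return a matrix of 0/1 rows in canonical rotation.
#' @export
canonicalize_cycle <- function(states, net = NULL) {
  if (is.list(states)) states <- do.call(rbind, states)
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop("states must be 0/1")
  codes <- states_to_codes(states)
  if (anyDuplicated(codes)) stop("input is not a cycle: duplicate states")
  if (!is.null(net)) {
    if (ncol(states) != length(net$nodes)) {
      stop("state width does not match network size")
    }
    p <- nrow(states)
    nxt <- step_states(net, states == 1L)
    nxt_codes <- states_to_codes(nxt)
    want <- codes[c(seq_len(p)[-1L], 1L)]
    if (!isTRUE(all.equal(nxt_codes, want))) {
      stop("input is not a cycle of the network under synchronous updating")
    }
  }
  ord <- canonical_rotation(codes)
  out <- states[match(ord, codes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Follow one trajectory to its attractor
#'
#' Iterates [synchronous_step()] from `state`, recording visited states until
#' one repeats; the repeated segment is the attractor (canonicalized) and the
#' number of steps taken before first entering it is the transient length.
#'
#' @param net a [boolean_network()].
#' @param state 0/1 initial state.
#' @param max_steps safety bound on the number of steps. The default `2^n`
#'   guarantees termination; smaller overrides raise an error if no repeat is
#'   seen in time.
#' @return `list(attractor = <attractor>, transient = <integer>)`.
#' @export
trajectory_to_attractor <- function(net, state,
                                    max_steps = 2^length(net$nodes)) {
  state <- validate_state(net, state)
  res <- trajectories_batch(net, matrix(state, nrow = 1L), max_steps)
  list(attractor = new_attractor(res$cycles[[1L]], net),
       transient = res$transients[1L])
}

# Batch trajectory follower: one synchronous step per iteration, vectorized
# over all still-active trajectories. `starts` is an m x n 0/1 matrix.
# Returns list(cycles = list of code vectors (entry order), transients).
trajectories_batch <- function(net, starts, max_steps) {
  m <- nrow(starts)
  n <- length(net$nodes)
  cur <- starts == 1L
  if (!is.matrix(cur)) cur <- matrix(cur, nrow = m)
  codes <- states_to_codes(cur)
  hist <- lapply(seq_len(m), function(i) codes[i])
  active <- seq_len(m)
  cycles <- vector("list", m)
  transients <- integer(m)
  steps <- 0L
  while (length(active)) {
    if (steps >= max_steps) {
      stop(sprintf("no repeat within max_steps = %s; raise max_steps", max_steps))
    }
    nxt <- step_states(net, cur)
    nxt_codes <- states_to_codes(nxt)
    done <- logical(length(active))
    for (k in seq_along(active)) {
      i <- active[k]
      hit <- match(nxt_codes[k], hist[[i]])
      if (!is.na(hit)) {
        cycles[[i]] <- hist[[i]][hit:length(hist[[i]])]
        transients[i] <- hit - 1L
        done[k] <- TRUE
      } else {
        hist[[i]] <- c(hist[[i]], nxt_codes[k])
      }
    }
    keep <- !done
    active <- active[keep]
    cur <- nxt[keep, , drop = FALSE]
    steps <- steps + 1L
  }
  list(cycles = cycles, transients = transients)
}

#' Enumerate the attractors of a Boolean network
#'
#' In `"exhaustive"` mode every state code in `[0, 2^n)` is assigned to its
#' attractor by following the successor table with memoization (path
#' compression), giving the exact attractor set and exact basin sizes; basin
#' sizes sum to `2^n`. Exhaustive mode refuses networks above `ceiling` nodes
#' (default 22) and directs to sampled mode.
#'
#' In `"sampled"` mode, `n_samples` initial states are drawn uniformly with
#' `seed` and each trajectory is followed to its attractor; the result is a
#' subset of the exhaustive attractor set with basin fractions estimated as
#' hit frequencies. Samples are drawn as a sequential stream, so increasing
#' `n_samples` under the same seed only ever adds attractors.
#'
#' @param net a [boolean_network()].
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_samples number of initial states (sampled mode).
#' @param seed RNG seed (required in sampled mode).
#' @param ceiling maximum node count for exhaustive mode.
#' @return an `attractor_set`: list with `attractors` (each an `attractor`
#'   with `codes`, `states`, `period` and basin statistics, ordered by
#'   canonical first code), `mode`, `coverage` (states explored) and `seed`.
#' @examples
#' net <- boolean_network(c("X", "Y"), list(X = "!Y", Y = "!X"))
#' aset <- enumerate_attractors(net)
#' sapply(aset$attractors, function(a) a$period)  # 1 1 2
#' @export
enumerate_attractors <- function(net, mode = c("exhaustive", "sampled"),
                                 n_samples = NULL, seed = NULL,
                                 ceiling = 22L) {
  mode <- match.arg(mode)
  n <- length(net$nodes)
  if (mode == "exhaustive") {
    if (n > ceiling) {
      stop(sprintf(paste("network has %d nodes, above the exhaustive ceiling",
                         "of %d; use mode = 'sampled' with a seed"),
                   n, ceiling))
    }
    return(enumerate_exhaustive(net))
  }
  if (is.null(n_samples) || n_samples < 1L) {
    stop("sampled mode requires n_samples >= 1")
  }
  if (is.null(seed)) stop("sampled mode requires an explicit seed")
  enumerate_sampled(net, as.integer(n_samples), as.integer(seed))
}

enumerate_exhaustive <- function(net) {
  n <- length(net$nodes)
  N <- as.integer(2^n)
  succ <- successor_table(net)
  assign_id <- integer(N)      # 0 = unvisited, -1 marks the current path
  path <- integer(N)
  cycles <- list()
  for (s0 in seq_len(N)) {
    if (assign_id[s0] != 0L) next
    plen <- 0L
    s <- s0
    while (assign_id[s] == 0L) {
      assign_id[s] <- -1L
      plen <- plen + 1L
      path[plen] <- s
      s <- succ[s] + 1L
    }
    if (assign_id[s] == -1L) {
      # closed a new cycle on the current path
      i <- which(path[seq_len(plen)] == s)
      cycles[[length(cycles) + 1L]] <- path[i:plen] - 1L
      id <- length(cycles)
    } else {
      id <- assign_id[s]
    }
    assign_id[path[seq_len(plen)]] <- id
  }
  basins <- tabulate(assign_id, nbins = length(cycles))
  atts <- lapply(seq_along(cycles), function(i) {
    new_attractor(cycles[[i]], net, basin_size = basins[i])
  })
  ord <- order(vapply(atts, function(a) a$codes[1L], numeric(1)))
  structure(list(network = net, attractors = atts[ord],
                 mode = "exhaustive", coverage = N, seed = NULL),
            class = "attractor_set")
}

enumerate_sampled <- function(net, n_samples, seed) {
  n <- length(net$nodes)
  set.seed(seed)
  codes <- if (n <= 30L) {
    as.numeric(sample.int(2^n, n_samples, replace = TRUE) - 1L)
  } else {
    floor(stats::runif(n_samples) * 2^n)
  }
  uniq <- sort(unique(codes))
  counts <- tabulate(match(codes, uniq), nbins = length(uniq))
  starts <- codes_to_states(uniq, n)
  res <- trajectories_batch(net, starts, max_steps = 2^min(n, 52))
  keys <- vapply(res$cycles, function(cyc) {
    attractor_key(canonical_rotation(cyc))
  }, character(1))
  hit <- tapply(counts, keys, sum)
  atts <- lapply(names(hit), function(k) {
    cyc <- as.numeric(strsplit(k, ",", fixed = TRUE)[[1L]])
    new_attractor(cyc, net,
                  basin_fraction = unname(hit[[k]]) / n_samples,
                  n_hits = as.integer(hit[[k]]))
  })
  ord <- order(vapply(atts, function(a) a$codes[1L], numeric(1)))
  structure(list(network = net, attractors = atts[ord],
                 mode = "sampled", coverage = n_samples, seed = seed),
            class = "attractor_set")
}

#' @export
print.attractor <- function(x, ...) {
  bits <- apply(x$states, 1L, paste, collapse = "")
  basin <- if (!is.na(x$basin_size)) {
    sprintf("basin %d", as.integer(x$basin_size))
  } else if (!is.na(x$basin_fraction)) {
    sprintf("basin ~%.3f", x$basin_fraction)
  } else ""
  cat(sprintf("<attractor> period %d %s\n  %s\n", x$period, basin,
              paste(bits, collapse = " -> ")))
  invisible(x)
}

#' @export
print.attractor_set <- function(x, ...) {
  periods <- vapply(x$attractors, function(a) a$period, integer(1))
  cat(sprintf("Attractor set (%s): %d attractors over %d nodes\n",
              x$mode, length(x$attractors), length(x$network$nodes)))
  cat("  periods:", paste(sort(unique(periods)), collapse = ", "), "\n")
  cat(sprintf("  fixed points: %d, cycles: %d\n",
              sum(periods == 1L), sum(periods > 1L)))
  invisible(x)
}

#' Export an attractor set
#'
#' `"json"` writes the full structure (states as bit strings in node order,
#' period, basin statistics, mode/coverage/seed); `"tsv"` writes a one-row-
#' per-attractor summary table. Both are byte-stable for a given set.
#'
#' @param aset an `attractor_set` from [enumerate_attractors()].
#' @param path output file.
#' @param format `"json"` or `"tsv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_attractors <- function(aset, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- list(
      nodes = aset$network$nodes,
      mode = aset$mode,
      coverage = aset$coverage,
      seed = aset$seed,
      attractors = lapply(aset$attractors, function(a) {
        out <- list(states = apply(a$states, 1L, paste, collapse = ""),
                    period = a$period)
        if (!is.na(a$basin_size)) out$basin_size <- a$basin_size
        if (!is.na(a$basin_fraction)) {
          out$basin_fraction <- a$basin_fraction
          out$n_hits <- a$n_hits
        }
        out
      })
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               path, useBytes = TRUE)
  } else {
    df <- attractor_table(aset)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

attractor_table <- function(aset) {
  data.frame(
    id = seq_along(aset$attractors),
    period = vapply(aset$attractors, function(a) a$period, integer(1)),
    states = vapply(aset$attractors, function(a) {
      paste(apply(a$states, 1L, paste, collapse = ""), collapse = "/")
    }, character(1)),
    basin_size = vapply(aset$attractors, function(a) a$basin_size, numeric(1)),
    basin_fraction = vapply(aset$attractors, function(a) a$basin_fraction,
                            numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Compare an attractor census against expected headline counts
#'
#' Convenience check for external validation against a published rule set:
#' verifies total attractor count, fixed-point count and the distribution of
#' cycle periods. The shipped synthetic macrophage fixture does *not* claim
#' to reproduce any published census; this is for users who load the original
#' published rules.
#'
#' @param aset an `attractor_set`.
#' @param total expected number of attractors (NA to skip).
#' @param fixed expected number of fixed points (NA to skip).
#' @param periods optional named vector, e.g. `c("2" = 2, "4" = 6)`, of
#'   expected cycle-period counts.
#' @return logical; attributes `observed` carries the observed census.
#' @export
validate_census <- function(aset, total = NA, fixed = NA, periods = NULL) {
  p <- vapply(aset$attractors, function(a) a$period, integer(1))
  obs <- list(total = length(p), fixed = sum(p == 1L),
              periods = table(p[p > 1L]))
  ok <- TRUE
  if (!is.na(total)) ok <- ok && obs$total == total
  if (!is.na(fixed)) ok <- ok && obs$fixed == fixed
  if (!is.null(periods)) {
    for (per in names(periods)) {
      got <- if (per %in% names(obs$periods)) obs$periods[[per]] else 0L
      ok <- ok && got == periods[[per]]
    }
  }
  structure(ok, observed = obs)
}
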