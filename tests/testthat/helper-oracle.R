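# Independent brute-force oracle for synchronous Boolean dynamics.
#
# Deliberately shares no machinery with the package implementation:
# - rules are re-parsed with R's own parser (expression rules) or indexed
#   directly (truth-table rules), and evaluated one state at a time;
# - attractors are extracted from the functional graph by pointer doubling
#   (composing the successor table with itself n times gives f^(2^n), which
#   maps every state into its terminal cycle), not by memoized traversal.

oracle_successors <- function(net) {
  n <- length(net$nodes)
  N <- 2^n
  exprs <- lapply(net$nodes, function(nm) {
    r <- net$rules[[nm]]
    if (r$kind == "expr") str2lang(r$text) else r
  })
  succ <- integer(N)
  for (code in 0:(N - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    env <- as.list(setNames(bits, net$nodes))
    val <- 0
    for (j in seq_len(n)) {
      e <- exprs[[j]]
      b <- if (inherits(e, "bool_rule")) {
        idx <- 1 + sum(as.integer(unlist(env[e$regulators])) *
                         2^(seq_along(e$regulators) - 1))
        e$outputs[idx] == 1L
      } else {
        as.logical(eval(e, env))
      }
      val <- val + as.numeric(b) * 2^(j - 1)
    }
    succ[code + 1] <- as.integer(val)
  }
  succ
}

oracle_attractors <- function(succ) {
  N <- length(succ)
  n <- round(log2(N))
  t <- succ
  for (i in seq_len(n)) t <- t[t + 1L]      # t = f^(2^n)
  atts <- list()
  seen <- character(0)
  for (r in unique(t)) {
    cyc <- r
    s <- succ[r + 1L]
    while (s != r) {
      cyc <- c(cyc, s)
      s <- succ[s + 1L]
    }
    i <- which.min(cyc)
    cyc <- c(cyc[i:length(cyc)], cyc[seq_len(i - 1)])
    key <- paste(cyc, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      atts[[length(atts) + 1L]] <- cyc
    }
  }
  keys <- vapply(atts, paste, character(1), collapse = ",")
  id_of <- new.env(parent = emptyenv())
  for (i in seq_along(atts)) {
    for (s in atts[[i]]) assign(as.character(s), i, envir = id_of)
  }
  landing <- vapply(t, function(s) get(as.character(s), envir = id_of),
                    integer(1))
  basins <- tabulate(landing, nbins = length(atts))
  ord <- order(vapply(atts, `[`, numeric(1), 1L))
  list(cycles = atts[ord], keys = keys[ord], basins = basins[ord])
}

# canonical key/basin comparison between package output and oracle output
expect_matches_oracle <- function(aset, oracle) {
  impl_keys <- vapply(aset$attractors, function(a) {
    paste(a$codes, collapse = ",")
  }, character(1))
  impl_basins <- vapply(aset$attractors, function(a) a$basin_size, numeric(1))
  expect_identical(impl_keys, oracle$keys)
  expect_identical(as.numeric(impl_basins), as.numeric(oracle$basins))
}
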