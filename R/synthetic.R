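# Synthetic networks: random N-K test beds, analytic fixtures with known
# attractor structure, and a curated miniature macrophage polarization
# network. Everything here is generated in code so the rest of the package is
# testable without any download.

#' Random N-K Boolean network
#'
#' Classic Kauffman ensemble: each node receives `k` distinct regulators
#' drawn uniformly from all nodes, and an independent random truth table over
#' those regulators with `P(output = 1) = bias`. Fully reproducible: the same
#' `(n, k, bias, seed)` always gives a byte-identical network. Rules are kept
#' as explicit truth tables (uniform sampling is well defined over tables,
#' not over expression syntax) and serialize natively in the JSON dialect.
#'
#' @param n number of nodes (named `G1..Gn`).
#' @param k regulators per node, `1 <= k <= n`.
#' @param bias probability that a truth-table entry is 1, in (0, 1).
#' @param seed RNG seed.
#' @return a [boolean_network()].
#' @export
random_nk_network <- function(n, k, bias = 0.5, seed) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 1L) stop("n must be >= 1")
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n")
  if (!(bias > 0 && bias < 1)) stop("bias must be strictly between 0 and 1")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  nodes <- paste0("G", seq_len(n))
  rules <- list()
  for (nm in nodes) {
    regs <- nodes[sample.int(n, k)]
    outputs <- as.integer(stats::runif(2^k) < bias)
    rules[[nm]] <- new_rule_table(regs, outputs)
  }
  boolean_network(nodes, rules,
                  metadata = sprintf("random N-K network n=%d k=%d bias=%g seed=%d",
                                     n, k, bias, as.integer(seed)))
}

#' Analytic fixtures with known attractor structure
#'
#' Small networks whose exact attractor census is known in closed form (or
#' frozen once from brute force) and shipped alongside the network:
#'
#' * `identity_n` — every rule is the node itself; all `2^n` states are fixed
#'   points with basin 1 (`n` via the `n` argument, default 3).
#' * `toggle` — `X = !Y, Y = !X`; two fixed points (01, 10, basin 1 each) and
#'   one period-2 cycle \{00, 11\} with basin 2.
#' * `negation_ring_3` — `X1 = !X3, X2 = !X1, X3 = !X2`; no fixed points, one
#'   period-2 cycle \{000, 111\} and one period-6 cycle through the remaining
#'   six states.
#' * `and_chain_4` — `Xi = X(i-1) & Xi` on a ring of 4; updates are monotone
#'   non-increasing, so the only attractors are the fixed points 0000
#'   (basin 15) and 1111 (basin 1).
#'
#' @param name fixture name.
#' @param n node count for `identity_n`.
#' @return a `fixture_bundle`: list with `network`, `scheme` (NULL here) and
#'   `expected` (`n_attractors`, `periods` = named period -> count vector,
#'   `basins` = sorted basin sizes).
#' @export
analytic_fixture <- function(name = c("identity_n", "toggle",
                                      "negation_ring_3", "and_chain_4"),
                             n = 3L) {
  name <- match.arg(name)
  if (name == "identity_n") {
    n <- as.integer(n)
    nodes <- paste0("A", seq_len(n))
    net <- boolean_network(nodes, stats::setNames(as.list(nodes), nodes),
                           metadata = sprintf("identity network n=%d", n))
    expected <- list(n_attractors = 2L^n,
                     periods = stats::setNames(2L^n, "1"),
                     basins = rep(1L, 2L^n))
  } else if (name == "toggle") {
    net <- boolean_network(c("X", "Y"), list(X = "!Y", Y = "!X"),
                           metadata = "toggle (mutual negation)")
    expected <- list(n_attractors = 3L,
                     periods = stats::setNames(c(2L, 1L), c("1", "2")),
                     basins = c(1L, 1L, 2L))
  } else if (name == "negation_ring_3") {
    net <- boolean_network(c("X1", "X2", "X3"),
                           list(X1 = "!X3", X2 = "!X1", X3 = "!X2"),
                           metadata = "3-node negation ring")
    expected <- list(n_attractors = 2L,
                     periods = stats::setNames(c(1L, 1L), c("2", "6")),
                     basins = c(2L, 6L))
  } else {
    net <- boolean_network(
      c("X1", "X2", "X3", "X4"),
      list(X1 = "X4 & X1", X2 = "X1 & X2", X3 = "X2 & X3", X4 = "X3 & X4"),
      metadata = "AND chain on a 4-ring")
    # frozen from brute force: monotone dynamics, only the two uniform fixed
    # points survive
    expected <- list(n_attractors = 2L,
                     periods = stats::setNames(2L, "1"),
                     basins = c(1L, 15L))
  }
  structure(list(network = net, scheme = NULL, expected = expected),
            class = "fixture_bundle")
}

#' Curated synthetic macrophage polarization network
#'
#' A 17-node Boolean network over the transcription factors and cytokines of
#' the macrophage polarization literature. It encodes, in the package's own
#' words, the directed interactions the field states for this system:
#'
#' * `STAT1 = IFNG & !STAT6` — interferon-gamma drives the M1 program;
#'   STAT6 represses the M1 transcription factors.
#' * `STAT3 = (IL10 | IL6 | TGFB) & !SOCS3` — IL-10, IL-6 and TGF-beta each
#'   activate STAT3; SOCS3 shuts it down.
#' * `STAT6 = IL4 | PPARG | KLF4` — the M2a program, driven by IL-4 and
#'   eventually by PPAR-gamma or KLF4.
#' * `NFKB = (TNFA | IL1B | GMCSF) & !STAT6` — pro-inflammatory activation by
#'   TNF-alpha, IL-1-beta and GM-CSF, repressed by STAT6. (Whether GM-CSF
#'   acts through NF-kB is an interpretation; it is included here.)
#' * `AP1 = (IL6 | IL1B) & !(STAT6 | PPARG)` — IL-6 / IL-1-beta drive AP-1;
#'   STAT6 and PPAR-gamma (negative feedback) repress it.
#' * `SOCS3 = STAT1 | NFKB | STAT3` — SOCS3 induction through STAT1 or NF-kB;
#'   the STAT3 term is the classical JAK/STAT negative feedback (STAT3
#'   induces its own inhibitor), which is what makes the monocyte/M2c
#'   oscillations possible at all.
#' * `PPARG = HIF1A`, `KLF4 = HIF1A` — both are switched on under hypoxia,
#'   sensed by HIF1-alpha.
#' * Inputs held at their initial value (identity rules), modeling the tumor
#'   microenvironment: `HIF1A, IFNG, GMCSF, IL4, IL6, IL10, IL1B, TNFA,
#'   TGFB`.
#'
#' This fixture stands in for the unpublished curated network of the
#' original macrophage studies: it claims only to encode the interactions
#' above, and its attractor census is a frozen regression surface, not a
#' literature-truth claim.
#'
#' @return a `fixture_bundle` with `network`, the default
#'   [phenotype_scheme()], and `expected` — the frozen exhaustive census
#'   (`n_attractors` and `periods`), generated once by the brute-force oracle
#'   and changed only by explicitly rerunning `tools/make_snapshots.R`.
#' @export
macrophage_fixture <- function() {
  nodes <- c("STAT1", "STAT3", "STAT6", "NFKB", "AP1", "SOCS3",
             "PPARG", "KLF4", "HIF1A",
             "IFNG", "GMCSF", "IL4", "IL6", "IL10", "IL1B", "TNFA", "TGFB")
  rules <- list(
    STAT1 = "IFNG & !STAT6",
    STAT3 = "(IL10 | IL6 | TGFB) & !SOCS3",
    STAT6 = "IL4 | PPARG | KLF4",
    NFKB  = "(TNFA | IL1B | GMCSF) & !STAT6",
    AP1   = "(IL6 | IL1B) & !(STAT6 | PPARG)",
    SOCS3 = "STAT1 | NFKB | STAT3",
    PPARG = "HIF1A",
    KLF4  = "HIF1A"
  )
  net <- boolean_network(
    nodes, rules,
    metadata = paste("synthetic macrophage polarization TRN;",
                     "cytokine/hypoxia inputs held (identity rules)"))
  structure(list(network = net,
                 scheme = default_phenotype_scheme(),
                 expected = .MACROPHAGE_CENSUS),
            class = "fixture_bundle")
}

# Frozen exhaustive census of the macrophage fixture (2^17 states), computed
# once by the independent successor-table oracle in tools/make_snapshots.R.
# Regenerate only by rerunning that script.
.MACROPHAGE_CENSUS <- list(
  n_attractors = 512L,
  periods = c("1" = 169L, "4" = 343L)
)

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Fixture bundle\n")
  print(x$network)
  if (!is.null(x$expected)) {
    cat(sprintf("  expected: %d attractors; periods: %s\n",
                x$expected$n_attractors,
                paste(sprintf("%sx period %s", x$expected$periods,
                              names(x$expected$periods)), collapse = ", ")))
  }
  invisible(x)
}
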