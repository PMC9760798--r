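# Shared fixtures for the test files.

toggle_net <- function() analytic_fixture("toggle")$network

ring3_net <- function() analytic_fixture("negation_ring_3")$network

# parameters for the 100-network random N-K suite (seeds 0..99); n cycles
# over the full allowed range and k over 1..3
nk_params <- function(seed, n_max = 12L) {
  span <- n_max - 4L + 1L
  list(n = 4L + (seed %% span), k = 1L + (seed %% 3L), seed = seed)
}

# a tiny generic scheme usable on G1.. random networks
generic_scheme <- function() {
  phenotype_scheme(
    labels = c("OFF", "ON"),
    conditions = c(ON = "G1"),
    fallback_label = "OFF",
    outcome_class = c(OFF = "neutral", ON = "tumor-eliminating")
  )
}

# memoized exhaustive results for the standard suite, shared across
# acceptance criteria so the suite is enumerated once
.suite_cache <- new.env(parent = emptyenv())
nk_suite <- function(n_max = 12L) {
  key <- paste0("suite", n_max)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  out <- lapply(0:99, function(s) {
    p <- nk_params(s, n_max)
    net <- random_nk_network(p$n, p$k, bias = 0.5, seed = p$seed)
    list(params = p, net = net, aset = enumerate_attractors(net))
  })
  .suite_cache[[key]] <- out
  out
}
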