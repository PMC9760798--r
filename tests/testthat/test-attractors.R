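# attractor enumeration, trajectories, canonicalization

test_that("trajectory_to_attractor finds fixed points and cycles", {
  tog <- toggle_net()
  r <- trajectory_to_attractor(tog, c(0, 1))
  expect_equal(r$attractor$period, 1L)
  expect_equal(r$transient, 0L)
  expect_equal(r$attractor$codes, 2)          # (0,1) -> code 2

  r2 <- trajectory_to_attractor(tog, c(0, 0))
  expect_equal(r2$attractor$period, 2L)
  expect_equal(r2$attractor$codes, c(0, 3))

  ring <- ring3_net()
  r3 <- trajectory_to_attractor(ring, c(0, 0, 1))
  expect_equal(r3$attractor$period, 6L)
  # the 6-cycle visits exactly the six states outside {000, 111}
  expect_setequal(r3$attractor$codes, setdiff(0:7, c(0, 7)))

  expect_error(trajectory_to_attractor(ring, c(0, 0, 1), max_steps = 2),
               "max_steps")
})

test_that("exhaustive enumeration matches the analytic fixtures", {
  idn <- analytic_fixture("identity_n", n = 3)
  aset <- enumerate_attractors(idn$network)
  expect_length(aset$attractors, 8L)
  expect_true(all(vapply(aset$attractors, function(a) a$period, 1L) == 1L))
  expect_true(all(vapply(aset$attractors, function(a) a$basin_size, 1) == 1))

  tog <- enumerate_attractors(toggle_net())
  expect_equal(sort(vapply(tog$attractors, function(a) a$period, 1L)),
               c(1L, 1L, 2L))
  expect_equal(sort(vapply(tog$attractors, function(a) a$basin_size, 1)),
               c(1, 1, 2))

  ring <- enumerate_attractors(ring3_net())
  expect_length(ring$attractors, 2L)
  expect_equal(sort(vapply(ring$attractors, function(a) a$period, 1L)),
               c(2L, 6L))
  two <- ring$attractors[[which(vapply(ring$attractors, function(a) a$period,
                                       1L) == 2L)]]
  expect_equal(two$codes, c(0, 7))           # {000, 111}
})

test_that("exhaustive mode refuses oversize networks and points to sampling", {
  net <- random_nk_network(8, 2, bias = 0.5, seed = 1)
  expect_error(enumerate_attractors(net, ceiling = 6), "sampled")
})

test_that("canonicalize_cycle rotates to the minimal code and validates", {
  m <- rbind(c(1L, 1L), c(0L, 0L))
  out <- canonicalize_cycle(m)
  expect_equal(out, rbind(c(0L, 0L), c(1L, 1L)))
  # fixed point is its own canonical form
  expect_equal(canonicalize_cycle(rbind(c(1L, 0L))), rbind(c(1L, 0L)))
  # all rotations of the ring's 6-cycle canonicalize identically
  ring <- ring3_net()
  cyc <- trajectory_to_attractor(ring, c(0, 0, 1))$attractor$states
  for (k in 0:5) {
    rot <- cyc[c((k + seq_len(6) - 1) %% 6 + 1), , drop = FALSE]
    expect_equal(canonicalize_cycle(rot, ring), canonicalize_cycle(cyc, ring))
  }
  expect_error(canonicalize_cycle(rbind(c(0L, 1L), c(0L, 1L))), "duplicate")
  expect_error(canonicalize_cycle(rbind(c(0L, 1L), c(0L, 0L)), ring3_net()),
               "width|not a cycle")
  # succession check: (0,1) and (1,0) are both fixed points of the toggle
  # net, not a 2-cycle
  expect_error(canonicalize_cycle(rbind(c(0L, 1L), c(1L, 0L)), toggle_net()),
               "not a cycle")
})

test_that("period is minimal: no cycle equals a rotation at smaller period", {
  for (seed in 0:9) {
    net <- random_nk_network(8, 3, bias = 0.5, seed = seed)
    aset <- enumerate_attractors(net)
    for (a in aset$attractors) {
      expect_false(anyDuplicated(a$codes) > 0)
      if (a$period > 1L) {
        for (d in seq_len(a$period - 1)) {
          rot <- c(a$codes[(d + 1):a$period], a$codes[seq_len(d)])
          expect_false(identical(rot, a$codes))
        }
      }
      # states cycle: step maps states[i] to states[(i mod p) + 1]
      nxt <- t(apply(a$states, 1L, function(s) synchronous_step(net, s)))
      expect_equal(unname(nxt),
                   unname(a$states[c(seq_len(a$period)[-1], 1L), ,
                                   drop = FALSE]))
    }
  }
})

test_that("sampled enumeration is a subset of exhaustive, monotone in size", {
  for (seed in c(2, 9)) {
    net <- random_nk_network(10, 3, bias = 0.5, seed = seed)
    ex_keys <- vapply(enumerate_attractors(net)$attractors,
                      function(a) paste(a$codes, collapse = ","), "")
    small <- enumerate_attractors(net, "sampled", n_samples = 50, seed = 7)
    big <- enumerate_attractors(net, "sampled", n_samples = 400, seed = 7)
    k_small <- vapply(small$attractors,
                      function(a) paste(a$codes, collapse = ","), "")
    k_big <- vapply(big$attractors,
                    function(a) paste(a$codes, collapse = ","), "")
    expect_true(all(k_small %in% ex_keys))
    expect_true(all(k_big %in% ex_keys))
    expect_true(all(k_small %in% k_big))    # same seed stream, more samples
    fr <- vapply(big$attractors, function(a) a$basin_fraction, 1)
    expect_equal(sum(fr), 1)
  }
  expect_error(enumerate_attractors(toggle_net(), "sampled", n_samples = 10),
               "seed")
  expect_error(enumerate_attractors(toggle_net(), "sampled", seed = 1),
               "n_samples")
})

test_that("attractor sets export to JSON and TSV deterministically", {
  aset <- enumerate_attractors(ring3_net())
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_attractors(aset, fj)
  write_attractors(aset, ft)
  obj <- jsonlite::fromJSON(fj, simplifyVector = FALSE)
  expect_equal(length(obj$attractors), 2L)
  expect_equal(obj$attractors[[1]]$states[[1]], "000")
  expect_equal(obj$attractors[[1]]$period, 2L)
  tab <- read.delim(ft, colClasses = "character")
  expect_equal(nrow(tab), 2L)
  fj2 <- withr::local_tempfile(fileext = ".json")
  write_attractors(enumerate_attractors(ring3_net()), fj2)
  expect_identical(readLines(fj), readLines(fj2))
})

test_that("validate_census checks totals, fixed points and period counts", {
  aset <- enumerate_attractors(ring3_net())
  expect_true(validate_census(aset, total = 2, fixed = 0,
                              periods = c("2" = 1, "6" = 1)))
  expect_false(validate_census(aset, total = 27))
  obs <- attr(validate_census(aset), "observed")
  expect_equal(obs$total, 2L)
})
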