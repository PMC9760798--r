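# network construction, file dialects, synchronous stepping, state codec,
# clamping

test_that("bnet dialect parses the minimal cases", {
  net <- parse_network("targets, factors\nA, B\nB, !A", "bnet")
  expect_identical(net$nodes, c("A", "B"))
  expect_identical(macpol:::rule_text(net$rules$A), "B")
  expect_identical(macpol:::rule_text(net$rules$B), "!A")
  one <- parse_network("targets, factors\nA, A", "bnet")
  expect_identical(synchronous_step(one, 1L), 1L)
  expect_identical(synchronous_step(one, 0L), 0L)
})

test_that("bnet parse errors name the offender and the line", {
  expect_error(parse_network("targets, factors\nA, B | C\nB, A", "bnet"),
               "line 2.*undeclared node C")
  expect_error(parse_network("targets, factors\nA, A\nA, !A", "bnet"),
               "line 3.*duplicate rule for node A")
  expect_error(parse_network("targets, factors\nA, A &", "bnet"),
               "line 2")
  expect_error(parse_network("A, B\nB, A", "bnet"), "header")
})

test_that("JSON dialect parses rules, truth tables and input policies", {
  txt <- '{"nodes":["X","Y"],"rules":{"X":"X & !Y","Y":"X | Y"}}'
  net <- parse_network(txt, "json")
  expect_identical(synchronous_step(net, c(1L, 0L)), c(1L, 1L))

  txt2 <- paste0('{"nodes":["A","B","C"],',
                 '"rules":{"A":{"regulators":["B"],"outputs":[1,0]}},',
                 '"inputs":{"B":"hold","C":"1"}}')
  net2 <- parse_network(txt2, "json")
  expect_identical(synchronous_step(net2, c(0L, 0L, 0L)), c(1L, 0L, 1L))
  expect_identical(synchronous_step(net2, c(0L, 1L, 1L)), c(0L, 1L, 1L))
})

test_that("serializers round-trip both dialects", {
  nets <- list(
    toggle_net(),
    random_nk_network(5, 2, bias = 0.5, seed = 11),
    macrophage_fixture()$network
  )
  for (net in nets) {
    for (d in c("bnet", "json")) {
      txt <- format_network(net, d)
      net2 <- parse_network(txt, d)
      expect_identical(net2$nodes, net$nodes)
      expect_identical(format_network(net2, d), txt)
    }
  }
})

test_that("round-trip preserves the successor function on all states", {
  for (seed in c(1, 2, 3)) {
    net <- random_nk_network(6, 3, bias = 0.5, seed = seed)
    for (d in c("bnet", "json")) {
      net2 <- parse_network(format_network(net, d), d)
      expect_identical(macpol:::successor_table(net2),
                       macpol:::successor_table(net))
    }
  }
})

test_that("file IO picks the dialect from the extension", {
  net <- toggle_net()
  for (ext in c("bnet", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network(net, f)
    expect_identical(read_network(f)$nodes, net$nodes)
  }
})

test_that("synchronous_step matches hand-evaluated truth tables", {
  tog <- toggle_net()
  expect_identical(synchronous_step(tog, c(0L, 0L)), c(1L, 1L))
  expect_identical(synchronous_step(tog, c(0L, 1L)), c(0L, 1L))  # fixed point
  ring <- ring3_net()
  expect_identical(synchronous_step(ring, c(0L, 0L, 1L)), c(0L, 1L, 1L))
  # determinism: repeated calls agree bit for bit
  for (i in 1:5) {
    s <- c(1L, 0L, 1L)
    expect_identical(synchronous_step(ring, s), synchronous_step(ring, s))
  }
  expect_error(synchronous_step(tog, c(1L, 0L, 1L)), "2 nodes")
  expect_error(synchronous_step(tog, c(2L, 0L)), "0/1")
})

test_that("state codec is a bijection with node 1 as least significant bit", {
  net <- analytic_fixture("identity_n", n = 3)$network
  expect_equal(state_to_code(c(1, 0, 0), net), 1)
  expect_equal(code_to_state(7, net), c(1L, 1L, 1L))
  for (code in 0:7) {
    expect_equal(state_to_code(code_to_state(code, net), net), code)
  }
  expect_error(code_to_state(8, net), "\\[0, 2\\^3\\)")
  expect_error(code_to_state(-1, net), "\\[0, 2\\^3\\)")
})

test_that("clamping fixes a node, leaves the original untouched, idempotent", {
  tog <- toggle_net()
  cl <- clamp_node(tog, "X", 1)
  for (s in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
    expect_identical(synchronous_step(cl, s)[1], 1L)
  }
  expect_identical(macpol:::rule_text(tog$rules$X), "!Y")  # original intact
  expect_identical(format_network(clamp_node(cl, "X", 1), "bnet"),
                   format_network(cl, "bnet"))
  expect_error(clamp_node(tog, "Z", 1), "unknown node")

  # clamp(identity-3, A, 0) from (1,1,1) reaches the fixed point (0,1,1)
  idn <- analytic_fixture("identity_n", n = 3)$network
  cl2 <- clamp_node(idn, "A1", 0)
  s1 <- synchronous_step(cl2, c(1L, 1L, 1L))
  expect_identical(s1, c(0L, 1L, 1L))
  expect_identical(synchronous_step(cl2, s1), s1)
})

test_that("clamped node is constant along every trajectory after step 1", {
  for (seed in c(4, 5)) {
    net <- random_nk_network(6, 2, bias = 0.5, seed = seed)
    cl <- clamp_node(net, "G3", 1)
    set.seed(seed)
    for (rep in 1:10) {
      s <- as.integer(stats::runif(6) < 0.5)
      for (step in 1:8) {
        s <- synchronous_step(cl, s)
        expect_identical(s[3], 1L)
      }
    }
  }
})

test_that("identity network: every state is a fixed point", {
  net <- analytic_fixture("identity_n", n = 4)$network
  for (code in 0:15) {
    s <- code_to_state(code, net)
    expect_identical(synchronous_step(net, s), s)
  }
})

test_that("network construction rejects bad inputs", {
  expect_error(boolean_network(c("A", "A"), list(A = "A")), "duplicate")
  expect_error(boolean_network("NF-KB", list(`NF-KB` = "NF-KB")), "invalid")
  expect_error(boolean_network("A", list(A = "A", B = "A")), "undeclared")
  expect_error(boolean_network(c("A", "B"), list(A = "C", B = "A")),
               "reference undeclared")
})
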