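# clamp perturbations and the cell fate map

test_that("resolve_perturbation follows clamps to the right destinations", {
  # identity 3-node net, source fixed point (0,0,0), clamp A1 -> 1
  idn <- analytic_fixture("identity_n", n = 3)$network
  src <- trajectory_to_attractor(idn, c(0, 0, 0))$attractor
  d <- resolve_perturbation(idn, src, "A1", 1)
  expect_length(d, 1L)
  expect_equal(d[[1]]$attractor$codes, 1)
  expect_equal(d[[1]]$attractor$period, 1L)

  # toggle net, source 2-cycle, clamp X -> 1: both states land on (1,0)
  tog <- toggle_net()
  cyc <- trajectory_to_attractor(tog, c(0, 0))$attractor
  d2 <- resolve_perturbation(tog, cyc, "X", 1)
  expect_length(d2, 1L)
  expect_equal(d2[[1]]$attractor$codes, 1)   # (1,0)
  expect_equal(d2[[1]]$n_entry_states, 2L)

  # clamping a node to its current constant value: destination = source state
  fp <- trajectory_to_attractor(tog, c(0, 1))$attractor   # fixed point (0,1)
  d3 <- resolve_perturbation(tog, fp, "X", 0)
  expect_equal(d3[[1]]$attractor$codes, fp$codes)
  expect_error(resolve_perturbation(tog, fp, "Z", 1), "unknown node")
})

test_that("fate map on the identity 2-node net flips one bit per edge", {
  idn <- analytic_fixture("identity_n", n = 2)$network
  scheme <- phenotype_scheme(c("M0", "M1"), c(M1 = "A1"), "M0",
                             c(M0 = "neutral", M1 = "tumor-eliminating"))
  fm <- build_fate_map(idn, enumerate_attractors(idn), scheme)
  expect_equal(nrow(fm$edges), 8L)            # 4 fixed points x 2 nodes
  v <- fm$vertices
  for (i in seq_len(nrow(fm$edges))) {
    e <- fm$edges[i, ]
    src_bits <- as.integer(strsplit(v$states[e$source], "")[[1]])
    dst_bits <- as.integer(strsplit(v$states[e$destination], "")[[1]])
    expect_equal(sum(src_bits != dst_bits), 1L)   # adjacent fixed point
  }
})

test_that("toggle 2-cycle dies under every clamp", {
  tog <- toggle_net()
  scheme <- phenotype_scheme(c("M0", "M1"), c(M1 = "X"), "M0",
                             c(M0 = "neutral", M1 = "tumor-eliminating"))
  aset <- enumerate_attractors(tog)
  fm <- build_fate_map(tog, aset, scheme)
  v <- fm$vertices
  cyc_id <- v$id[v$period == 2L & v$context == ""]
  out <- fm$edges[fm$edges$source == cyc_id, ]
  expect_gt(nrow(out), 0L)
  expect_true(all(v$period[out$destination] == 1L))
})

test_that("cycle-state clamps apply both signs when the node varies", {
  net <- macrophage_fixture()$network
  scheme <- default_phenotype_scheme()
  s0 <- integer(17)
  s0[match("IL10", net$nodes)] <- 1L
  cyc <- trajectory_to_attractor(net, s0)$attractor
  aset <- structure(list(network = net, attractors = list(cyc),
                         mode = "exhaustive", coverage = NA, seed = NULL),
                    class = "attractor_set")
  fm <- build_fate_map(net, aset, scheme, nodes = c("STAT3", "IL4"))
  e <- fm$edges
  # STAT3 varies across the cycle -> both clamps, flagged varies
  st3 <- e[e$node == "STAT3", ]
  expect_setequal(st3$sign, c("-", "+"))
  expect_true(all(st3$original_value == "varies"))
  # IL4 is constant 0 -> single "+" clamp
  il4 <- e[e$node == "IL4", ]
  expect_equal(il4$sign, "+")
  expect_equal(il4$original_value, "0")
})

test_that("transient mode runs the original network and merges vertices", {
  tog <- toggle_net()
  scheme <- phenotype_scheme(c("M0", "M1"), c(M1 = "X"), "M0",
                             c(M0 = "neutral", M1 = "tumor-eliminating"))
  aset <- enumerate_attractors(tog)
  fm <- build_fate_map(tog, aset, scheme, mode = "transient")
  # every destination is one of the three attractors of the original net
  expect_true(all(fm$vertices$context == ""))
  expect_lte(nrow(fm$vertices), 3L)
})

test_that("fate-map exports are byte-stable and round-trip", {
  net <- macrophage_fixture()$network
  scheme <- default_phenotype_scheme()
  s0 <- integer(17)
  s0[match(c("IFNG", "TNFA"), net$nodes)] <- 1L
  src <- trajectory_to_attractor(net, s0)$attractor
  aset <- structure(list(network = net, attractors = list(src),
                         mode = "exhaustive", coverage = NA, seed = NULL),
                    class = "attractor_set")
  fm <- build_fate_map(net, aset, scheme)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_fate_map(fm, f1)
  export_fate_map(build_fate_map(net, aset, scheme), f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read_fate_map_tsv(f1)
  expect_equal(nrow(tab), nrow(fm$edges))
  expect_identical(tab$node, fm$edges$node)
  expect_identical(tab$sign, fm$edges$sign)

  fd <- withr::local_tempfile(fileext = ".dot")
  export_fate_map(fm, fd)
  expect_match(readLines(fd)[1], "digraph")
  expect_error(export_fate_map(fm, withr::local_tempfile(fileext = ".xyz")),
               "format")
})

test_that("GraphML export is well-formed with declared keys", {
  skip_if_not_installed("xml2")
  tog <- toggle_net()
  scheme <- phenotype_scheme(c("M0", "M1"), c(M1 = "X"), "M0",
                             c(M0 = "neutral", M1 = "tumor-eliminating"))
  fm <- build_fate_map(tog, enumerate_attractors(tog), scheme)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_fate_map(fm, f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "graphml")
  ns <- xml2::xml_ns(doc)
  expect_true("http://graphml.graphdrawing.org/xmlns" %in% unlist(ns))
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:key", ns), "id")
  used <- unique(xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:data", ns),
                                "key"))
  expect_true(all(used %in% keys))
  n_nodes <- length(xml2::xml_find_all(doc, ".//d1:node", ns))
  expect_equal(n_nodes, nrow(fm$vertices))
})

test_that("flip involution on fixed points returns to the clamped-back net's attractors", {
  net <- random_nk_network(7, 2, bias = 0.5, seed = 24)
  aset <- enumerate_attractors(net)
  fps <- Filter(function(a) a$period == 1L, aset$attractors)
  expect_gte(length(fps), 1L)
  for (a in fps[seq_len(min(3, length(fps)))]) {
    nd <- net$nodes[2]
    orig <- a$states[1, 2]
    d <- resolve_perturbation(net, a, nd, 1 - orig)[[1]]$attractor
    back_net <- clamp_node(net, nd, orig)
    d2 <- resolve_perturbation(net, d, nd, orig)
    back_keys <- vapply(enumerate_attractors(back_net)$attractors,
                        function(x) paste(x$codes, collapse = ","), "")
    for (dd in d2) {
      expect_true(paste(dd$attractor$codes, collapse = ",") %in% back_keys)
    }
  }
})
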