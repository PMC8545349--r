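test_that("expressions compile to the right truth tables", {
  net <- parse_boolnet("targets, factors\nA, B & !C\nB, 1\nC, 0")
  f <- net$functions[["A"]]
  expect_equal(f$inputs, c("B", "C"))
  expect_equal(f$table, c(0L, 0L, 1L, 0L))  # rows BC = 00, 01, 10, 11
  expect_equal(net$functions[["B"]]$inputs, character(0))
  expect_equal(net$functions[["B"]]$table, 1L)
  expect_equal(net$functions[["C"]]$table, 0L)
})

test_that("operator precedence is ! > & > | and parentheses override", {
  net <- parse_boolnet("targets, factors\nA, B | C & !A\nB, (B | C) & A\nC, A")
  # B | (C & !A): rows ABC(=A,B,C order of appearance B,C,A) -> enumerate
  f <- net$functions[["A"]]
  expect_equal(f$inputs, c("B", "C", "A"))
  rows <- expand.grid(A = 0:1, C = 0:1, B = 0:1)[, 3:1]  # B,C,A with B as MSB
  expected <- as.integer(rows$B | (rows$C & !rows$A))
  expect_equal(f$table, expected)
  g <- net$functions[["B"]]
  rows2 <- expand.grid(A = 0:1, C = 0:1, B = 0:1)[, 3:1]
  expect_equal(g$table, as.integer((rows2$B | rows2$C) & rows2$A))
})

test_that("parser reports unknown genes, duplicates and malformed expressions", {
  expect_error(parse_boolnet("targets, factors\nA, B"), "unknown gene.*B")
  expect_error(parse_boolnet("targets, factors\nA, A\nA, 1"), "duplicate target")
  expect_error(parse_boolnet("targets, factors\nA, A &"), "line 2")
  expect_error(parse_boolnet("targets, factors\nA, (A"), "\\)")
  expect_error(parse_boolnet("A, B"), "targets, factors")
  expect_error(parse_boolnet("targets, factors\nA, A $ B"), "position")
})

test_that("comments and blank lines are ignored, names case-sensitive", {
  net <- parse_boolnet("# model\ntargets, factors\n\n# core\na, A\nA, a")
  expect_equal(net$genes, c("a", "A"))
  expect_equal(net$functions[["a"]]$inputs, "A")
})

test_that("serialization round-trips truth tables exactly", {
  t3 <- t3_network()
  again <- parse_boolnet(write_boolnet(t3))
  expect_equal(again$functions, t3$functions)

  # degenerate tables: constants and all-zero/all-one over listed inputs
  net <- boolean_network(list(
    A = bn_function(c("A", "B"), c(0L, 0L, 0L, 0L)),
    B = bn_function(c("A", "B"), c(1L, 1L, 1L, 1L)),
    C = bn_function(character(), 1L)
  ))
  again <- parse_boolnet(write_boolnet(net))
  expect_equal(again$functions, net$functions)
})

test_that("parse-write round trip is the identity on random networks", {
  for (seed in 1:20) {
    net <- generate_random_network(8, k = sample(1:3, 1), bias = 0.5, seed = seed)
    again <- parse_boolnet(write_boolnet(net))
    expect_equal(again$genes, net$genes)
    for (g in net$genes) {
      expect_equal(again$functions[[g]]$inputs, net$functions[[g]]$inputs)
      expect_equal(again$functions[[g]]$table, net$functions[[g]]$table)
    }
  }
})

test_that("essential inputs drop inert regulators", {
  # f(A,B) = A | (B & !B) is just A
  f <- parse_boolnet("targets, factors\nA, A | (B & !B)\nB, A")$functions[["A"]]
  expect_equal(essential_inputs(f), "A")
  xor <- bn_function(c("A", "B"), c(0L, 1L, 1L, 0L))
  expect_equal(essential_inputs(xor), c("A", "B"))
  expect_equal(essential_inputs(bn_function(character(), 0L)), character(0))
})

test_that("interaction graph uses essential edges; node set is complete", {
  t3 <- t3_network()
  g <- build_interaction_graph(t3)
  edges <- as_edge_list(t3)
  expect_setequal(paste(edges$source, edges$target),
                  c("C A", "A B", "C B", "B C"))
  expect_equal(igraph::V(g)$name, c("A", "B", "C"))

  # listed but inert regulator: edge absent in essential mode, present in syntactic
  net <- parse_boolnet("targets, factors\nA, B | (C & !C)\nB, A\nC, A")
  expect_false("C" %in% as_edge_list(net, "essential")$source)
  expect_true("C" %in% as_edge_list(net, "syntactic")$source)

  # constants leave their targets without incoming edges
  cnet <- parse_boolnet("targets, factors\nA, 1\nB, 0")
  expect_equal(igraph::ecount(build_interaction_graph(cnet)), 0)
})

test_that("edge count equals the sum of essential in-degrees", {
  for (seed in 1:10) {
    net <- generate_random_network(7, k = 2, seed = seed)
    g <- build_interaction_graph(net)
    total <- sum(vapply(net$functions,
                        function(f) length(essential_inputs(f)), integer(1)))
    expect_equal(igraph::ecount(g), total)
  }
})

test_that("random network generation is seeded and honours k and bias", {
  a <- generate_random_network(5, 2, bias = 0.5, seed = 42)
  b <- generate_random_network(5, 2, bias = 0.5, seed = 42)
  expect_equal(a, b)
  expect_false(identical(a, generate_random_network(5, 2, bias = 0.5, seed = 43)))

  allone <- generate_random_network(4, 2, bias = 1, seed = 1)
  for (f in allone$functions) expect_equal(f$table, rep(1L, 4))

  expect_error(generate_random_network(3, k = 4, seed = 1), "k")

  # mean fraction of 1 entries ~ Binomial(bias = 0.5) over many seeds
  fracs <- vapply(1:50, function(s) {
    net <- generate_random_network(10, 2, bias = 0.5, seed = s)
    mean(unlist(lapply(net$functions, `[[`, "table")))
  }, numeric(1))
  n_bits <- 50 * 10 * 4
  se <- sqrt(0.25 / n_bits)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("bundled model files load", {
  t3 <- read_boolnet(system.file("extdata", "toy3.bn", package = "bnscreen"))
  expect_equal(t3$genes, c("A", "B", "C"))
  nets <- read_boolnet_collection(system.file("extdata", package = "bnscreen"))
  expect_gte(length(nets), 2)
})
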