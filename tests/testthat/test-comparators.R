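test_that("canalysing inputs are detected from truth tables", {
  net <- parse_boolnet(paste(
    "targets, factors",
    "OR, A | B",
    "XOR, A & !B | !A & B",
    "A, A", "B, B", sep = "\n"))
  can <- canalysing_analysis(net)
  lvl <- stats::setNames(can$level, can$gene)
  # A and B each canalyse OR (value 1 forces 1) and their own identity,
  # but not XOR
  expect_equal(unname(lvl["A"]), 2L)
  expect_equal(unname(lvl["B"]), 2L)
  expect_true(all(can$canalyser[can$gene %in% c("A", "B")]))
})

test_that("a gene feeding m AND-gates canalyses all of them", {
  net <- parse_boolnet(paste(
    "targets, factors",
    "G, G", "H, H",
    "T1, G & H", "T2, G & T1", "T3, G & H & T1", sep = "\n"))
  can <- canalysing_analysis(net)
  expect_equal(can$level[can$gene == "G"], 3L + 1L)  # 3 AND gates + self-identity
})

test_that("canalysation level never exceeds out-degree", {
  for (seed in 1:8) {
    net <- generate_random_network(7, k = 2, seed = seed)
    can <- canalysing_analysis(net)
    outdeg <- igraph::degree(build_interaction_graph(net, "syntactic"),
                             mode = "out", loops = TRUE)
    expect_true(all(can$level <= outdeg[can$gene]))
  }
})

test_that("edge signs capture monotonicity", {
  net <- parse_boolnet(paste(
    "targets, factors",
    "P, A", "N, !A", "X, A & !B | !A & B",
    "A, A", "B, B", sep = "\n"))
  signs <- infer_edge_signs(net)
  get <- function(from, to) signs$sign[signs$from == from & signs$to == to]
  expect_equal(get("A", "P"), "positive")
  expect_equal(get("A", "N"), "negative")
  expect_equal(get("A", "X"), "ambivalent")
  expect_equal(get("B", "X"), "ambivalent")
})

test_that("motif counts match hand-built graphs", {
  net <- parse_boolnet(paste(
    "targets, factors",
    "A, A", "B, A", "C, A & B", sep = "\n"))
  motifs <- count_motifs(build_interaction_graph(net), infer_edge_signs(net))
  expect_equal(motifs$c1ffl, 1L)  # A -> B -> C with direct A -> C, all positive
  expect_equal(motifs$i1ffl, 0L)
  expect_equal(motifs$bifan, 0L)

  inc <- parse_boolnet(paste(
    "targets, factors",
    "A, A", "B, A", "C, A & !B", sep = "\n"))
  m2 <- count_motifs(build_interaction_graph(inc), infer_edge_signs(inc))
  expect_equal(m2$c1ffl, 0L)
  expect_equal(m2$i1ffl, 1L)

  bf <- parse_boolnet(paste(
    "targets, factors",
    "A, A", "B, B", "C, A | B", "D, A & B", sep = "\n"))
  m3 <- count_motifs(build_interaction_graph(bf), infer_edge_signs(bf))
  expect_equal(m3$bifan, 1L)
  part <- stats::setNames(m3$participation$bifan, m3$participation$gene)
  expect_equal(unname(part[c("A", "B", "C", "D")]), c(1L, 1L, 1L, 1L))
})

test_that("motif counts equal the exhaustive subset-scan oracle", {
  for (seed in 1:10) {
    net <- generate_random_network(7, k = 2, seed = seed * 7)
    g <- build_interaction_graph(net)
    signs <- infer_edge_signs(net)
    mine <- count_motifs(g, signs)
    oracle <- oracle_motifs(g, signs)
    expect_equal(mine$c1ffl, oracle$c1ffl)
    expect_equal(mine$i1ffl, oracle$i1ffl)
    expect_equal(mine$bifan, oracle$bifan)
  }
})

test_that("feedback vertex sets break all cycles, minimally on small graphs", {
  two <- igraph::graph_from_literal(A -+ B, B -+ A)
  fvs <- feedback_vertex_set(two)
  expect_equal(as.character(fvs), "A")  # lexicographic tie-break
  expect_true(attr(fvs, "minimum"))

  dag <- igraph::graph_from_literal(A -+ B, B -+ C, A -+ C)
  expect_length(feedback_vertex_set(dag), 0)

  two_cycles <- igraph::graph_from_literal(A -+ B, B -+ C, C -+ A,
                                           D -+ E, E -+ F, F -+ D)
  expect_length(feedback_vertex_set(two_cycles), 2)

  # self-loops are always included
  loops <- igraph::make_graph(c("A", "A", "B", "C", "C", "B"), directed = TRUE)
  fvs2 <- feedback_vertex_set(loops)
  expect_true("A" %in% fvs2)
})

test_that("FVS removal always leaves an acyclic graph; exact <= greedy", {
  for (seed in 1:8) {
    net <- generate_random_network(8, k = 2, seed = seed * 13)
    g <- build_interaction_graph(net)
    fvs <- feedback_vertex_set(g)
    rest <- igraph::delete_vertices(g, fvs)
    expect_true(igraph::vcount(rest) == 0 || igraph::is_dag(rest))
    greedy <- c(
      unique(igraph::ends(g, igraph::E(g))[igraph::which_loop(g), 1]),
      bnscreen:::greedy_fvs(bnscreen:::trim_acyclic_parts(
        igraph::delete_vertices(
          igraph::simplify(g, remove.loops = TRUE),
          unique(igraph::ends(g, igraph::E(g))[igraph::which_loop(g), 1])))))
    expect_lte(length(fvs), length(greedy))
  }
})

test_that("the comparator report combines all features per gene", {
  net <- read_boolnet(system.file("extdata", "synthetic_cascade.bn",
                                  package = "bnscreen"))
  rep <- comparator_report(net)
  expect_setequal(rep$gene, net$genes)
  expect_true(all(c("level", "canalyser", "c1ffl", "i1ffl", "bifan", "fvs")
                  %in% names(rep)))
  totals <- attr(rep, "motif_totals")
  expect_equal(unname(totals["c1ffl"]), sum(rep$c1ffl) / 3)
})
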