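test_that("top fraction sizes follow the ceiling rule with deterministic ties", {
  scores <- stats::setNames(10:1, letters[1:10])
  expect_length(top_fraction(scores, 73), 8)  # ceiling(7.3)
  expect_setequal(top_fraction(scores, 100), letters[1:10])
  expect_equal(sort(top_fraction(scores, 20)), c("a", "b"))

  tied <- stats::setNames(rep(1, 4), c("d", "b", "a", "c"))
  expect_equal(top_fraction(tied, 50), c("a", "b"))  # name order breaks ties
  expect_error(top_fraction(numeric(0), 50), "empty")
  expect_error(top_fraction(c(a = 1), 0), "1, 100")
})

test_that("selection sets obey set algebra", {
  scores <- tibble::tibble(gene = letters[1:6],
                           vb = c(6, 5, 4, 3, 2, 1),
                           dp = c(6, 5, 4, 3, 2, 1))
  sel <- static_selection(scores, 50)
  expect_setequal(sel$intersection, sel$union)
  expect_setequal(sel$vb_top, c("a", "b", "c"))

  disjoint <- tibble::tibble(gene = letters[1:6],
                             vb = c(6, 5, 1, 1, 1, 1),
                             dp = c(1, 1, 1, 1, 5, 6))
  sel2 <- static_selection(disjoint, 33)
  expect_length(sel2$intersection, 0)
  expect_setequal(sel2$union, c("a", "b", "e", "f"))

  # tiny networks: ceiling selects everything at the default threshold
  t3 <- static_scores(t3_network())
  sel3 <- static_selection(t3, 73)
  expect_setequal(sel3$vb_top, c("A", "B", "C"))
})

test_that("classification partitions genes and respects the mismatch rule", {
  nets <- generate_network_collection(4, size_range = c(8, 12), seed = 21)
  for (net in nets) {
    cls <- classify_nodes(static_scores(net))
    expect_equal(sum(cls$class == "PM") + sum(cls$class == "NM"),
                 sum(cls$selected))
    expect_equal(sum(cls$class == "NS"), sum(!cls$selected))
    expect_true(all(cls$static_pct[cls$class == "PM"] >
                      cls$conn_pct[cls$class == "PM"]))
    expect_true(all(cls$static_pct[cls$class == "NM"] <=
                      cls$conn_pct[cls$class == "NM"]))
    expect_true(all(cls$class[!cls$selected] == "NS"))
  }
})

test_that("a selected gene with equal static and connectivity ranks is NM", {
  # two identical genes: all percentiles tie, everything selected at T = 100
  net <- parse_boolnet("targets, factors\nA, B\nB, A")
  cls <- classify_nodes(static_scores(net), threshold = 100)
  expect_true(all(cls$selected))
  expect_true(all(cls$class == "NM"))
})

test_that("classification is invariant under gene reordering", {
  net <- generate_random_network(8, k = 2, seed = 31)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  permuted <- boolean_network(net$functions[net$genes[perm]])
  c1 <- classify_nodes(static_scores(net))
  c2 <- classify_nodes(static_scores(permuted))
  m <- match(c1$gene, c2$gene)
  expect_equal(as.character(c2$class[m]), as.character(c1$class))
  expect_equal(c2$hub[m], c1$hub)
})

test_that("input nodes are constants or self-identities only", {
  net <- parse_boolnet(paste(
    "targets, factors",
    "CONST, 1",
    "SELF, SELF",
    "NEG, !NEG",
    "REG, CONST & SELF", sep = "\n"))
  expect_setequal(detect_input_nodes(net), c("CONST", "SELF"))
})

test_that("the sweep hits perfect sensitivity and specificity at T = 100", {
  nets <- generate_network_collection(5, size_range = c(6, 9), seed = 41)
  scores <- score_collection(nets)
  curve <- sensitivity_specificity_sweep(scores)
  at100 <- curve[curve$threshold == 100, ]
  expect_equal(at100$sensitivity, 1)
  expect_equal(at100$specificity, 1)
  expect_true(all(curve$sensitivity >= 0 & curve$sensitivity <= 1))
  expect_true(all(curve$specificity >= 0 & curve$specificity <= 1))
})

test_that("the sweep equals an independent confusion-matrix recount", {
  nets <- generate_network_collection(10, size_range = c(6, 10), seed = 51)
  scores <- score_collection(nets)
  curve <- sensitivity_specificity_sweep(scores)
  for (T in c(1, 25, 50, 73, 100)) {
    recount <- vapply(split(scores, scores$network), oracle_confusion,
                      numeric(2), T = T)
    expect_equal(curve$sensitivity[curve$threshold == T],
                 mean(recount["sensitivity", ]))
    expect_equal(curve$specificity[curve$threshold == T],
                 mean(recount["specificity", ]))
  }
})

test_that("a selection identical to the labels scores perfectly", {
  # one network where vb, dp and impact rank genes identically
  df <- tibble::tibble(network = "n1", gene = letters[1:8],
                       vb = 8:1, dp = 8:1, impact = (8:1) / 8)
  curve <- sensitivity_specificity_sweep(df)
  expect_true(all(curve$sensitivity == 1))
  expect_true(all(curve$specificity == 1))
  expect_equal(attr(curve, "crossing_threshold"), 1)  # ties -> smallest T
})

test_that("networks with undefined dynamic scores are excluded with a warning", {
  df <- dplyr::bind_rows(
    tibble::tibble(network = "ok", gene = letters[1:4], vb = 4:1, dp = 4:1,
                   impact = (4:1) / 4),
    tibble::tibble(network = "bad", gene = letters[1:4], vb = 4:1, dp = 4:1,
                   impact = NA_real_))
  expect_warning(curve <- sensitivity_specificity_sweep(df), "bad")
  expect_equal(unique(curve$n_networks), 1L)
})

test_that("selected set sizes follow the ceiling rule at every threshold", {
  net <- generate_random_network(11, k = 2, seed = 61)
  scores <- static_scores(net)
  for (T in 1:100) {
    sel <- static_selection(scores, T)
    expect_length(sel$vb_top, ceiling(T * 11 / 100))
    expect_length(sel$dp_top, ceiling(T * 11 / 100))
    expect_true(all(sel$intersection %in% sel$union))
  }
})
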