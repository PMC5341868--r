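test_that("pathway synergy network matches brute-force pairwise intersection", {
  enr <- toy_enrichment(list(m1 = c("P1", "P2"), m2 = c("P2", "P3"),
                             m3 = "P4"))
  net <- pathway_synergy_network(enr)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "m1")
  expect_equal(net$edges$to, "m2")
  expect_equal(net$edges$weight, 1)
  expect_equal(net$edges$evidence, "P2")
  # isolates retained with hub score 0
  expect_equal(net$nodes$hub_score[net$nodes$mirna == "m3"], 0)

  # identical enriched sets -> complete graph with weight = set size
  enr2 <- toy_enrichment(list(a = c("P1", "P2", "P3"),
                              b = c("P1", "P2", "P3"),
                              c = c("P1", "P2", "P3")))
  net2 <- pathway_synergy_network(enr2)
  expect_equal(nrow(net2$edges), 3L)
  expect_equal(net2$edges$weight, rep(3, 3))

  # no overlaps -> edgeless
  net3 <- pathway_synergy_network(toy_enrichment(list(a = "P1", b = "P2")))
  expect_equal(nrow(net3$edges), 0L)
  expect_true(all(net3$nodes$hub_score == 0))
})

test_that("TF synergy network counts shared regulators", {
  tf_map <- list(SMAD3 = c("hsa-miR-155", "m2"),
                 SMAD4 = c("hsa-miR-155", "m2"),
                 CEBPB = "hsa-miR-143",
                 TFX = "m9")
  net <- tf_synergy_network(tf_map, c("hsa-miR-155", "hsa-miR-143", "m2"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 2) # SMAD3 and SMAD4 both shared
  expect_equal(net$edges$evidence, "SMAD3;SMAD4")
  # a TF regulating a single listed miRNA contributes nothing
  expect_false("hsa-miR-143" %in% c(net$edges$from, net$edges$to))
})

test_that("the three builders equal independent brute force on random fixtures", {
  set.seed(21)
  for (rep in 1:3) {
    mirnas <- paste0("m", sprintf("%02d", 1:30))
    sets <- setNames(lapply(mirnas, function(m) {
      sample(paste0("P", 1:12), sample(0:5, 1))
    }), mirnas)
    enr <- toy_enrichment(sets)
    net <- pathway_synergy_network(enr)
    oracle <- oracle_shared_network(lapply(sets, unique))
    expect_equal(net$edges$from, oracle$from)
    expect_equal(net$edges$to, oracle$to)
    expect_equal(net$edges$weight, oracle$weight)
    # handshake identity on every build
    expect_equal(sum(net$nodes$hub_score), 2 * sum(net$edges$weight))

    tf_map <- setNames(lapply(1:8, function(i) sample(mirnas, sample(1:6, 1))),
                       paste0("TF", 1:8))
    tnet <- tf_synergy_network(tf_map, mirnas)
    inv <- setNames(lapply(mirnas, function(m) {
      names(tf_map)[vapply(tf_map, function(x) m %in% x, logical(1))]
    }), mirnas)
    toracle <- oracle_shared_network(inv)
    expect_equal(tnet$edges[, c("from", "to", "weight")],
                 toracle, ignore_attr = TRUE)
    expect_equal(sum(tnet$nodes$hub_score), 2 * sum(tnet$edges$weight))

    vals <- matrix(rnorm(25 * 6), 25, 6,
                   dimnames = list(paste0("m", 1:25),
                                   paste0("normal_p", 1:6)))
    cnet <- correlation_network(toy_expression(vals), "normal",
                                min_abs_r = 0.5)
    coracle <- oracle_correlation_network(vals, 0.5)
    expect_equal(cnet$edges[, c("from", "to", "weight", "r")],
                 coracle, ignore_attr = TRUE)
    expect_equal(sum(cnet$nodes$hub_score), 2 * sum(cnet$edges$weight))
  }
})

test_that("correlation network handles exact, inverse and degenerate profiles", {
  x <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(a = x, b = x * 2 + 1, c = -x + 10, d = rep(1, 6),
                e = rnorm(6))
  colnames(vals) <- paste0("normal_p", 1:6)
  expect_warning(net <- correlation_network(toy_expression(vals), "normal",
                                            min_abs_r = 0.99),
                 "zero-variance")
  ab <- net$edges[net$edges$from == "a" & net$edges$to == "b", ]
  expect_equal(ab$r, 1)
  ac <- net$edges[net$edges$from == "a" & net$edges$to == "c", ]
  expect_equal(ac$r, -1)
  expect_equal(ac$weight, 1)
  expect_false("d" %in% net$nodes$mirna) # zero variance dropped
  # affine per-miRNA rescaling leaves Pearson edges unchanged
  vals2 <- vals[c("a", "b", "c", "e"), ]
  vals2["e", ] <- vals2["e", ] * 7 - 3
  net2 <- correlation_network(toy_expression(vals2), "normal",
                              min_abs_r = 0.99)
  expect_equal(net$edges[, c("from", "to", "weight")],
               net2$edges[, c("from", "to", "weight")])
  # fewer than three samples rejected
  expect_error(correlation_network(
    toy_expression(vals[, 1:2]), "normal"), "at least 3")
})

test_that("hub ranking orders by weighted degree with lexicographic ties", {
  # star centred on m0 with 4 unit edges
  enr <- toy_enrichment(list(m0 = paste0("P", 1:4), a = "P1", b = "P2",
                             c = "P3", d = "P4"))
  net <- pathway_synergy_network(enr)
  hr <- hub_ranking(net)
  expect_equal(hr$mirna[1], "m0")
  expect_equal(hr$hub_score[1], 4)
  expect_equal(hr$mirna[-1], c("a", "b", "c", "d")) # tied at 1, lexicographic
  # edgeless network: all zeros, lexicographic order
  e <- pathway_synergy_network(toy_enrichment(list(z = "P1", y = "P2")))
  hre <- hub_ranking(e)
  expect_equal(hre$mirna, c("y", "z"))
  expect_equal(hre$hub_score, c(0, 0))
})

test_that("network construction is deterministic and rejects invalid edges", {
  enr <- toy_enrichment(list(m1 = c("P1", "P2"), m2 = c("P2", "P1")))
  n1 <- pathway_synergy_network(enr)
  n2 <- pathway_synergy_network(enr)
  expect_identical(n1, n2)
  expect_error(
    crcmirnet:::new_synergy_network("a", data.frame(
      from = "a", to = "a", weight = 1, evidence = "",
      stringsAsFactors = FALSE)),
    "self-loops")
  expect_error(
    crcmirnet:::new_synergy_network(c("a", "b"), data.frame(
      from = "a", to = "b", weight = 0, evidence = "",
      stringsAsFactors = FALSE)),
    "positive")
})
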