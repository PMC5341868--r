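test_that("right-tail hypergeometric p matches exact enumeration on known cases", {
  expect_equal(hypergeom_right_pvalue(0, 5, 5, 10), 1)
  expect_equal(hypergeom_right_pvalue(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_right_pvalue(3, 6, 7, 20),
               oracle_hypergeom_right(3, 6, 7, 20), tolerance = 1e-12)
  # vectorised over arguments
  expect_equal(hypergeom_right_pvalue(c(0, 5), 5, 5, 10),
               c(1, 1 / choose(10, 5)), tolerance = 1e-12)
  expect_error(hypergeom_right_pvalue(6, 5, 5, 10), "inconsistent")
  expect_error(hypergeom_right_pvalue(1, 11, 5, 10), "inconsistent")
})

test_that("right-tail p agrees with the distribution-function route", {
  # independent route through the survival function of the hypergeometric
  set.seed(31)
  for (i in 1:200) {
    N <- sample(5:500, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_right_pvalue(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("Holm adjustment reproduces the step-down formula", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  # original order preserved, NAs passed through without counting
  p <- c(0.04, NA, 0.001, 0.9)
  out <- holm_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3, 4)],
               p.adjust(c(0.04, 0.001, 0.9), method = "holm"))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm is monotone and never exceeds single-step Bonferroni", {
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    h <- holm_adjust(p)
    expect_equal(h, p.adjust(p, method = "holm"))
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-15))
    ord <- order(p)
    expect_true(all(diff(h[ord]) >= -1e-15))
  }
})

test_that("kappa score matches the agreement-table definition", {
  u <- paste0("g", 1:10)
  expect_equal(kappa_score(u[1:4], u[1:4], u), 1)
  # balanced complements: perfect disagreement
  expect_equal(kappa_score(u[1:5], u[6:10], u), -1)
  # hand-computed 2x2 agreement table (3,1,1,5): p_o = 0.8,
  # p_e = 0.4*0.4 + 0.6*0.6 = 0.52 -> kappa = 0.28/0.48
  expect_equal(kappa_score(u[1:4], c(u[1:3], u[5]), u), 0.28 / 0.48)
  # symmetry and empty-set agreement
  expect_equal(kappa_score(u[1:4], c(u[1:3], u[5]), u),
               kappa_score(c(u[1:3], u[5]), u[1:4], u))
  expect_equal(kappa_score(character(0), character(0), u), 1)
  expect_error(kappa_score("a", "a", character(0)), "non-empty")
  expect_error(kappa_score("zz", "a", c("a", "b")), "subsets")
})

test_that("per-miRNA enrichment equals brute-force recomputation on a toy fixture", {
  u <- paste0("g", 1:30)
  pathway_db <- list(P1 = u[1:10], P2 = u[8:20], P3 = u[21:30])
  target_map <- list(
    m1 = u[1:9],              # strongly P1
    m2 = c(u[9:19], u[25]),   # strongly P2
    m3 = u[c(1, 15, 21:28)]   # strongly P3
  )
  enr <- enrich_mirna_targets(target_map, pathway_db, universe = u)
  expect_equal(nrow(enr), 9L)
  for (i in seq_len(nrow(enr))) {
    k <- length(intersect(target_map[[enr$mirna[i]]],
                          pathway_db[[enr$pathway[i]]]))
    expect_equal(enr$k[i], k)
    expect_equal(enr$p_raw[i],
                 oracle_hypergeom_right(k, length(pathway_db[[enr$pathway[i]]]),
                                        length(target_map[[enr$mirna[i]]]), 30),
                 tolerance = 1e-12)
  }
  # Holm applied within each miRNA's family of three tests
  for (m in names(target_map)) {
    rows <- enr[enr$mirna == m, ]
    expect_equal(rows$p_adj, holm_adjust(rows$p_raw))
  }
  # the dominant pathway has the family's smallest adjusted p
  expect_equal(enr$pathway[enr$mirna == "m1"][
    which.min(enr$p_adj[enr$mirna == "m1"])], "P1")
  expect_true(all(enr$p_adj >= enr$p_raw))
})

test_that("enrichment edge cases: disjoint targets, empty maps, universes", {
  u <- paste0("g", 1:20)
  pathway_db <- list(P1 = u[1:5])
  expect_warning(
    enr <- enrich_mirna_targets(list(m1 = "not-a-gene"), pathway_db,
                                universe = u),
    "skipped")
  expect_equal(nrow(enr), 0L)
  enr2 <- enrich_mirna_targets(list(m1 = u[10:15]), pathway_db,
                               universe = u)
  expect_false(any(enr2$enriched))
  expect_error(enrich_mirna_targets(list(m1 = u[1:3]), list()), "non-empty")
  # default universe is the union of pathway genes
  enr3 <- enrich_mirna_targets(list(m1 = u[1:5]), list(P1 = u[1:5],
                                                       P2 = u[6:10]))
  expect_equal(unique(enr3$N), 10L)
})

test_that("enriched-flag rate under a uniform null stays at or below nominal", {
  set.seed(77)
  u <- paste0("g", 1:400)
  pathway_db <- lapply(setNames(1:20, paste0("P", 1:20)),
                       function(i) sample(u, 30))
  flagged <- 0L; families <- 0L
  for (i in 1:150) {
    tm <- list(m = sample(u, 40))
    e <- enrich_mirna_targets(tm, pathway_db, universe = u)
    flagged <- flagged + any(e$enriched) # family-wise under Holm
    families <- families + 1L
  }
  expect_lte(flagged / families, 0.05 + 0.03)
})

test_that("kappa term grouping is single-linkage with lowest-p representatives", {
  u <- paste0("g", 1:40)
  # chain: A ~ B, B ~ C, A !~ C
  pathway_db <- list(A = u[1:10], B = u[3:12], C = u[5:14], D = u[30:40])
  enr <- data.frame(
    mirna = "m1", pathway = c("A", "B", "C", "D"),
    k = 5L, K = 10L, n = 10L, N = 40L,
    p_raw = c(0.01, 0.002, 0.02, 0.03),
    p_adj = c(0.02, 0.008, 0.03, 0.04),
    enriched = TRUE, stringsAsFactors = FALSE)
  groups <- group_terms(enr, pathway_db, universe = u,
                        kappa_threshold = 0.5)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  chain <- groups[[which(sizes == 3L)]]
  expect_setequal(chain$members, c("A", "B", "C"))
  expect_equal(chain$representative, "B") # lowest p_adj in the component
  expect_true(kappa_score(pathway_db$A, pathway_db$C, u) < 0.5)
  singleton <- groups[[which(sizes == 1L)]]
  expect_equal(singleton$members, "D")

  # identical pathways always group; all-dissimilar stays singleton
  pd2 <- list(X = u[1:8], Y = u[1:8], Z = u[20:28])
  enr2 <- enr[1:3, ]; enr2$pathway <- c("X", "Y", "Z")
  g2 <- group_terms(enr2, pd2, universe = u, kappa_threshold = 0.3)
  expect_equal(sort(vapply(g2, function(g) length(g$members), integer(1))),
               c(1L, 2L))
  expect_error(group_terms(enr[0, ], pathway_db, universe = u), "no enriched")
})
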