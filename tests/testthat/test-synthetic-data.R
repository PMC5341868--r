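test_that("generator dimensions, determinism, and metadata structure", {
  cfg <- simulation_config(seed = 42)
  expr <- simulate_expression(cfg)
  expect_equal(dim(expr$values), c(830L, 18L))
  expect_equal(sort(unique(expr$metadata$tissue_class)),
               sort(tissue_classes()))
  expect_equal(unname(table(expr$metadata$tissue_class)["normal"]), 6L)

  expr2 <- simulate_expression(cfg)
  expect_identical(expr$values, expr2$values)
  expect_identical(expr$metadata, expr2$metadata)

  # different seed, different draws
  expr3 <- simulate_expression(simulation_config(seed = 43))
  expect_false(identical(expr$values, expr3$values))
})

test_that("noise-free generation reproduces planted fold changes exactly", {
  cfg <- simulation_config(n_mirnas = 60, n_up = 5, n_down = 3,
                           noise_sd = 0, effect_log2fc = 1.5, seed = 9)
  expr <- simulate_expression(cfg)
  pl <- attr(expr, "planted")
  md <- expr$metadata
  n_cols <- md$sample_id[md$tissue_class == "normal"]
  c_cols <- md$sample_id[md$tissue_class == "carcinoma"]
  d <- expr$values[, c_cols] - expr$values[, n_cols]
  expect_equal(unname(rowMeans(d)[pl$up]), rep(1.5, 5))
  expect_equal(unname(rowMeans(d)[pl$down]), rep(-1.5, 3))
  null_mirnas <- setdiff(rownames(d), c(pl$up, pl$down))
  expect_equal(max(abs(d[null_mirnas, ])), 0)
  # adenoma carries half the carcinoma effect by default
  a_cols <- md$sample_id[md$tissue_class == "adenoma"]
  da <- expr$values[, a_cols] - expr$values[, n_cols]
  expect_equal(unname(rowMeans(da)[pl$up]), rep(0.75, 5))
})

test_that("hub/group correlation is -corr_strength in normal and +corr_strength in tumour", {
  # realised-loading construction: the within-class sample correlation is
  # exact, so this holds for every seed, not just most
  for (s in c(1, 7, 101)) {
    cfg <- simulation_config(seed = s, corr_strength = 0.6)
    expr <- simulate_expression(cfg)
    for (cl in tissue_classes()) {
      v <- subset_class(expr, cl)$values
      rs <- vapply(cfg$corr_group, function(m) {
        cor(v[cfg$hub_mirna, ], v[m, ])
      }, numeric(1))
      expected <- if (cl == "normal") -0.6 else 0.6
      expect_equal(unname(rs), rep(expected, 4), tolerance = 1e-10)
    }
  }
})

test_that("downstream paired test has near-perfect power at default settings", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    expr <- simulate_expression(simulation_config(seed = s))
    pl <- attr(expr, "planted")
    dt <- differential_mirnas(expr, "normal", "carcinoma",
                              fc_threshold = 1, alpha = 0.05)
    hits <- hits + sum(dt$mirna[dt$call == "up"] %in% pl$up) +
      sum(dt$mirna[dt$call == "down"] %in% pl$down)
    total <- total + length(pl$up) + length(pl$down)
  }
  expect_gt(hits / total, 0.99)
})

test_that("generator rejects invalid configurations", {
  expect_error(simulation_config(n_mirnas = 0), "positive")
  expect_error(simulation_config(n_up = 500, n_down = 500, n_mirnas = 830),
               "exceed")
  expect_error(simulation_config(corr_strength = 1), "corr_strength")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  # corr_group labels must fit among the miRNAs
  expect_error(simulate_expression(
    simulation_config(n_mirnas = 3, n_up = 1, n_down = 0)), "named")
})

test_that("annotation bundle honours its structural guarantees", {
  cfg <- simulation_config(seed = 5)
  ann <- simulate_annotations(cfg, n_genes = 800, n_pathways = 20)
  # reproducible
  ann2 <- simulate_annotations(cfg, n_genes = 800, n_pathways = 20)
  expect_identical(ann$target_map, ann2$target_map)
  expect_identical(ann$pathway_db, ann2$pathway_db)
  # every pathway gene inside the declared universe; sets non-empty
  expect_true(all(unlist(ann$pathway_db) %in% ann$universe))
  expect_true(all(lengths(ann$pathway_db) > 0))
  expect_true(all(lengths(ann$target_map) > 0))
  # literature-anchored TF edges present
  expect_true(cfg$hub_mirna %in% ann$tf_map$SMAD3)
  expect_true(cfg$hub_mirna %in% ann$tf_map$SMAD4)
  expect_true("hsa-miR-143" %in% ann$tf_map$CEBPB)
  # infeasible constraint reported, not silently dropped
  expect_error(
    simulate_annotations(cfg, n_genes = 10, n_pathways = 5,
                         pathway_size = c(15L, 60L)),
    "infeasible")
})

test_that("hub and every planted partner share an enriched pathway", {
  cfg <- simulation_config(seed = 3)
  ann <- simulate_annotations(cfg)
  expr <- simulate_expression(cfg)
  pl <- attr(expr, "planted")
  enr <- enrich_mirna_targets(ann$target_map, ann$pathway_db)
  sets <- split(enr$pathway[enr$enriched], enr$mirna[enr$enriched])
  hub_set <- sets[[cfg$hub_mirna]]
  partners <- setdiff(c(pl$up, pl$down), cfg$hub_mirna)
  shared <- vapply(partners, function(m) {
    length(intersect(sets[[m]], hub_set)) >= 1L
  }, logical(1))
  expect_true(all(shared))
})

test_that("single shared pathway yields a complete synergy network", {
  cfg <- simulation_config(n_mirnas = 10, n_up = 4, n_down = 4, seed = 2)
  ann <- simulate_annotations(cfg, n_genes = 100, n_pathways = 1,
                              pathway_size = c(30L, 40L))
  enr <- enrich_mirna_targets(ann$target_map, ann$pathway_db,
                              universe = ann$universe)
  net <- pathway_synergy_network(enr)
  m <- nrow(net$nodes)
  expect_equal(nrow(net$edges), m * (m - 1) / 2)
})

test_that("positivity simulator conserves counts and matches the target odds ratio", {
  tab <- simulate_positivity(78, 0.5, 2.96, seed = 1)
  expect_s3_class(tab, "contingency_2x2")
  expect_equal(tab$a + tab$b + tab$c + tab$d, 78L)
  expect_error(simulate_positivity(0, 0.5, 1, seed = 1), "positive")

  # Monte-Carlo oracle: mean log sample-OR over many replicates approaches
  # the requested log OR (Haldane-corrected sample ORs to absorb zero cells)
  lors <- vapply(1:4000, function(s) {
    t <- simulate_positivity(78, 0.5, 2.96, seed = s)
    log(odds_ratio(t))
  }, numeric(1))
  # small positive bias of the log sample OR at n = 78 is expected; the
  # Monte-Carlo mean must sit near log(2.96) on the log scale
  expect_equal(mean(lors), log(2.96), tolerance = 0.1)

  # null case: OR = 1 at large n gives sample OR near 1
  big <- simulate_positivity(200000, 0.4, 1, seed = 7)
  expect_equal(as.numeric(odds_ratio(big)), 1, tolerance = 0.1)
})
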