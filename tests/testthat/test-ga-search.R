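# Small, fast search problems: strong planted effects in few features so the
# GA converges within a handful of generations.
small_search_study <- function(n_features = 60, planted = 1:4, delta = 4,
                               seed = 50, n = 10) {
  toy_study(n_features = n_features, n_treated = n, n_control = n,
            planted = planted, delta = delta, seed = seed)
}

fast_config <- function(algorithm = "knn", ...) {
  search_config(algorithm, population_size = 20L, max_generations = 40L,
                n_models_to_collect = 5L, seed = 7L, ...)
}

test_that("a perfectly separated feature scores accuracy 1 under any split", {
  vals <- matrix(rep(c(1, 0), c(6, 6)), 1, dimnames = list("f1", sprintf("s%d", 1:12)))
  samples <- data.frame(sample_id = colnames(vals), chemical = "c", tissue = "t",
                        class = rep(c("treated", "control"), each = 6),
                        stringsAsFactors = FALSE)
  st <- expression_study(vals, samples)
  sl <- condition_slice("c", "t", 1:6, 7:12)
  for (alg in c("knn", "svm"))
    expect_equal(evaluate_fitness("f1", st, sl, fast_config(alg)), 1)
})

test_that("pure-noise fitness stays inside the chance band", {
  g <- toy_study(n_features = 20, n_treated = 10, n_control = 10, seed = 51)
  sl <- toy_slice(g$study)
  cfg <- fast_config("knn", n_splits = 50L)
  f <- evaluate_fitness(rownames(g$study$values)[1:5], g$study, sl, cfg)
  expect_gte(f, 0.3); expect_lte(f, 0.7)
})

test_that("k beyond the training class size is an error", {
  g <- small_search_study(n = 4)
  sl <- toy_slice(g$study)
  cfg <- fast_config("knn", knn_k = 10L)
  expect_error(evaluate_fitness(rownames(g$study$values)[1:3], g$study, sl, cfg),
               "knn_k")
})

test_that("cost grid search breaks ties toward the smallest cost", {
  g <- small_search_study(planted = 1:10, delta = 6)   # easily separable
  sl <- toy_slice(g$study)
  cfg <- fast_config("svm")
  expect_equal(tune_svm_cost(g$study, sl, c(0.1, 1, 10), cfg), 0.1)
  expect_equal(tune_svm_cost(g$study, sl, 42, cfg), 42)
  expect_error(tune_svm_cost(g$study, sl, numeric(), cfg), "empty")
})

test_that("the chosen cost is at least as accurate as every other grid point", {
  g <- small_search_study(planted = 1:5, delta = 4, seed = 52)
  sl <- toy_slice(g$study)
  cfg <- fast_config("svm")
  grid <- c(0.01, 0.1, 1, 10)
  chosen <- tune_svm_cost(g$study, sl, grid, cfg)
  splits <- gaclassify:::make_splits(as.character(sl$treated), as.character(sl$control),
                                     cfg$n_splits, cfg$train_fraction,
                                     derive_seed(cfg$seed, "cost_grid", sl$id))
  acc <- vapply(grid, function(cost) {
    c2 <- cfg; c2$svm_cost <- cost
    evaluate_fitness(rownames(g$study$values), g$study, sl, c2, splits = splits)
  }, 0)
  expect_equal(acc[match(chosen, grid)], max(acc))
})

test_that("search recovers planted features and respects the feature space", {
  g <- small_search_study(seed = 53)
  sl <- toy_slice(g$study)
  planted <- g$truth$planted[[1]]
  models <- ga_search(g$study, sl, NULL, fast_config())
  expect_gt(length(models), 0)
  expect_true(all(vapply(models, function(m) m$fitness >= 0.90, TRUE)))
  union <- consolidate_models(models)
  expect_gte(sum(planted %in% union), 2)
  # network-restricted search can only use the declared space
  space <- c(planted, rownames(g$study$values)[30:55])
  models_net <- ga_search(g$study, sl, space, fast_config())
  for (m in models_net) expect_true(all(m$features %in% space))
})

test_that("identical config and data reproduce the identical model list", {
  g <- small_search_study(seed = 54)
  sl <- toy_slice(g$study)
  m1 <- ga_search(g$study, sl, NULL, fast_config())
  m2 <- ga_search(g$study, sl, NULL, fast_config())
  expect_identical(m1, m2)
})

test_that("without signal no model reaches a high fitness goal", {
  g <- toy_study(n_features = 60, n_treated = 10, n_control = 10, seed = 55)
  sl <- toy_slice(g$study)
  models <- ga_search(g$study, sl, NULL, fast_config(fitness_goal = 0.95))
  expect_length(models, 0)
  expect_equal(attr(models, "generations_used"), 40L)
})

test_that("recovery power does not fall as the planted effect grows", {
  recovery <- vapply(c(0, 2, 4), function(delta) {
    g <- toy_study(n_features = 80, n_treated = 10, n_control = 10,
                   planted = 1:4, delta = delta, seed = 56)
    sl <- toy_slice(g$study)
    models <- ga_search(g$study, sl, NULL, fast_config(fitness_goal = 0.95))
    if (!length(models)) return(0)
    mean(g$truth$planted[[1]] %in% consolidate_models(models))
  }, 0)
  expect_true(all(diff(recovery) >= 0))
  expect_equal(recovery[1], 0)
  expect_gt(recovery[3], 0.5)
})

test_that("a too-small feature space is an error in single search, skipped in batch", {
  g <- small_search_study()
  sl <- toy_slice(g$study)
  expect_error(ga_search(g$study, sl, rownames(g$study$values)[1:3], fast_config()),
               "smaller than chromosome")
  nets <- gene_set_collection(list(
    tiny = rownames(g$study$values)[1:3],
    ok = c(g$truth$planted[[1]], rownames(g$study$values)[20:40])))
  res <- batch_network_search(g$study, list(sl), nets, fast_config())
  skipped <- attr(res, "skipped")
  expect_equal(skipped$network, "tiny")
  expect_named(res[[sl$id]], "ok")
})

test_that("batch search covers the condition-network cartesian product", {
  g <- small_search_study(seed = 57)
  sl <- toy_slice(g$study)
  ids <- rownames(g$study$values)
  nets <- gene_set_collection(list(n1 = ids[1:20], n2 = ids[21:40], n3 = ids[41:60]))
  res <- batch_network_search(g$study, list(sl), nets, fast_config())
  expect_length(res, 1)
  expect_length(res[[sl$id]], 3)
  # n1 contains the planted features -> it should be the productive network
  expect_gt(length(res[[sl$id]]$n1), 0)
})

test_that("networks without planted signal yield no models at the goal", {
  params <- simulation_params(
    n_features = 150,
    conditions = list(sim_condition("chemA", "ovary", 10, 10,
                                    planted = 1:5, delta = 3)),
    n_networks = 5, network_size_range = c(20, 30),
    planted_in_network_fraction = 0, seed = 58)
  g <- generate_study(params)
  nets <- generate_networks(params, g$truth)$networks
  sl <- toy_slice(g$study)
  res <- batch_network_search(g$study, list(sl), nets, fast_config())
  expect_equal(sum(lengths(res[[sl$id]])), 0)
})
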