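ranked_fixture <- function(metric, features = sprintf("g%02d", seq_along(metric))) {
  ord <- order(-metric, features)
  structure(list(feature = features[ord], metric = metric[ord]),
            class = "ranked_list")
}

test_that("signal-to-noise ranking matches hand computation with SD floors", {
  vals <- rbind(gA = c(3, 5, 1, 1),        # mu 4 vs 1, sd sqrt(2) vs floored 0.2
                gB = c(2, 2, 2, 2))        # equal means -> 0
  colnames(vals) <- sprintf("s%d", 1:4)
  samples <- data.frame(sample_id = colnames(vals), chemical = "c", tissue = "t",
                        class = rep(c("treated", "control"), each = 2),
                        stringsAsFactors = FALSE)
  st <- expression_study(vals, samples)
  sl <- condition_slice("c", "t", 1:2, 3:4)
  r <- rank_genes(st, sl)
  expect_equal(r$feature[1], "gA")
  expect_equal(r$metric[1], 3 / (sqrt(2) + 0.2))
  expect_equal(r$metric[2], 0)
})

test_that("swapping class labels negates the metric and reverses the ranking", {
  g <- toy_study(n_features = 50, seed = 8)
  sl <- toy_slice(g$study)
  swapped <- condition_slice(sl$chemical, sl$tissue, sl$control, sl$treated)
  r1 <- rank_genes(g$study, sl); r2 <- rank_genes(g$study, swapped)
  m1 <- setNames(r1$metric, r1$feature); m2 <- setNames(r2$metric, r2$feature)
  expect_equal(m2[names(m1)], -m1)
  expect_equal(r2$feature, rev(r1$feature))
})

test_that("enrichment score hits its extremes for leading and trailing sets", {
  r <- ranked_fixture(10:1)
  expect_equal(enrichment_score(r, r$feature[1:2], p = 0)$es, 1)
  expect_equal(enrichment_score(r, r$feature[9:10], p = 0)$es, -1)
})

test_that("the N=5 running sum is reproduced step by step", {
  r <- ranked_fixture(5:1)
  es <- enrichment_score(r, r$feature[c(1, 4)], p = 0)
  expect_equal(es$running, c(1 / 2, 1 / 6, -1 / 6, 1 / 3, 0))
  expect_equal(es$es, 0.5)
})

test_that("weighted ES matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    metric <- rnorm(n)
    r <- ranked_fixture(metric)
    set_size <- sample(2:10, 1)
    gene_set <- sample(r$feature, set_size)
    for (p in c(0, 1, 1.5)) {
      es <- enrichment_score(r, gene_set, p = p)$es
      ref <- oracle_es(r$feature, r$metric, gene_set, p)
      # when both extremes tie in magnitude the sign is ambiguous; the
      # magnitude is the well-defined part
      if (abs(es + ref) < 1e-9 && abs(es) > 1e-9) {
        expect_equal(abs(es), abs(ref), tolerance = 1e-12)
      } else {
        expect_equal(es, ref, tolerance = 1e-12)
      }
      expect_lte(abs(es), 1)
    }
  }
})

test_that("at p = 0 the score is invariant under monotone metric transforms", {
  set.seed(12)
  metric <- rnorm(30)
  r1 <- ranked_fixture(metric)
  r2 <- ranked_fixture(exp(metric))       # strictly monotone transform
  gene_set <- sample(r1$feature, 6)
  expect_equal(enrichment_score(r1, gene_set, p = 0)$es,
               enrichment_score(r2, gene_set, p = 0)$es)
})

test_that("empty intersections and degenerate sets are rejected", {
  r <- ranked_fixture(5:1)
  expect_error(enrichment_score(r, c("zzz")), "empty intersection")
  expect_error(enrichment_score(r, r$feature), "entire")
})

test_that("a set stronger than every permutation gets the add-one minimum p", {
  g <- toy_study(n_features = 80, n_treated = 10, n_control = 10,
                 planted = 1:8, delta = 3, seed = 13)
  sl <- toy_slice(g$study)
  sets <- gene_set_collection(list(planted = g$truth$planted[[1]]))
  res <- permutation_significance(g$study, sl, sets, n_perm = 50, seed = 5)
  # sign-conditional add-one convention: minimum attainable p for this run
  expect_equal(res$p_value, 1 / (1 + res$n_same_sign))
  expect_true(res$enriched)
})

test_that("few distinct label assignments are enumerated exactly", {
  g <- toy_study(n_features = 30, n_treated = 3, n_control = 3, seed = 14)
  sl <- toy_slice(g$study)
  sets <- gene_set_collection(list(s = rownames(g$study$values)[1:5]))
  # choose(6, 3) = 20 distinct assignments < n_perm -> exact enumeration,
  # which always includes the observed labelling, so the extreme count is
  # at least 1 on top of the add-one guard
  res <- permutation_significance(g$study, sl, sets, n_perm = 1000, seed = 1)
  expect_equal(res$p_value * (1 + res$n_same_sign),
               round(res$p_value * (1 + res$n_same_sign)))
  expect_gte(res$p_value, 2 / (1 + res$n_same_sign))
  res2 <- permutation_significance(g$study, sl, sets, n_perm = 1000, seed = 99)
  expect_equal(res$p_value, res2$p_value)  # enumeration ignores the seed
})

test_that("nominal p is calibrated under the null", {
  # quick check of the type-I rate; the full calibration runs in acceptance
  set.seed(15)
  hits <- 0; n_sim <- 100
  for (i in seq_len(n_sim)) {
    g <- toy_study(n_features = 60, n_treated = 5, n_control = 5, seed = 1000 + i)
    sl <- toy_slice(g$study)
    sets <- gene_set_collection(list(s = sample(rownames(g$study$values), 8)))
    p <- permutation_significance(g$study, sl, sets, n_perm = 99,
                                  seed = i)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_sim, 0.01)
  expect_lte(hits / n_sim, 0.10)
})

test_that("a planted classifier is enriched on an independent replicate", {
  train <- toy_study(n_features = 150, n_treated = 10, n_control = 10,
                     planted = 1:8, delta = 3, seed = 16)
  valid <- toy_study(n_features = 150, n_treated = 10, n_control = 10,
                     planted = 1:8, delta = 3, seed = 17)   # new draw, same truth
  sl <- toy_slice(valid$study)
  sets <- gene_set_collection(list(classifier = train$truth$planted[[1]]))
  res <- permutation_significance(valid$study, sl, sets, n_perm = 200, seed = 2)
  expect_true(res$enriched)
  expect_lt(res$fdr_q, 0.25)
})

test_that("validation pairs gene sets and GEPs by tissue only", {
  g_ov <- toy_study(n_features = 60, planted = 1:5, delta = 3, seed = 18)
  g_br <- toy_study(n_features = 60, planted = 1:5, delta = 3, seed = 19,
                    tissue = "brain")
  sets <- gene_set_collection(
    list(c1 = rownames(g_ov$study$values)[1:5],
         c2 = rownames(g_ov$study$values)[6:10],
         c3 = rownames(g_ov$study$values)[11:15]),
    description = c("ovary", "ovary", "brain"))
  geps <- list(
    list(study = g_ov$study, slice = toy_slice(g_ov$study), name = "gep_ov1"),
    list(study = g_ov$study, slice = toy_slice(g_ov$study), name = "gep_ov2"),
    list(study = g_br$study, slice = toy_slice(g_br$study), name = "gep_br"))
  rep <- validate_collection(sets, geps, n_perm = 50, seed = 3)
  expect_equal(sum(rep$gep %in% c("gep_ov1", "gep_ov2")), 4)  # 2 ovary sets x 2
  expect_false(any(rep$set == "c3" & rep$tissue == "ovary"))
  expect_false(any(rep$set %in% c("c1", "c2") & rep$gep == "gep_br"))
  expect_true(all(c("f_ratio", "fdr_q", "enriched") %in% names(rep)))
})

test_that("an identity cross-mapping leaves validation unchanged", {
  g <- toy_study(n_features = 40, planted = 1:5, delta = 3, seed = 20)
  sl <- toy_slice(g$study)
  feats <- rownames(g$study$values)[1:8]
  sets <- gene_set_collection(list(c1 = feats), description = "ovary")
  identity_map <- structure(
    data.frame(probe_a = feats, probe_b = feats,
               evidence = "perfect_sequence", stringency = "relaxed",
               stringsAsFactors = FALSE),
    class = c("probe_mapping", "data.frame"))
  geps <- list(list(study = g$study, slice = sl, name = "gep1"))
  r1 <- validate_collection(sets, geps, n_perm = 50, seed = 4)
  r2 <- validate_collection(sets, geps, crossmap = identity_map,
                            n_perm = 50, seed = 4)
  expect_equal(r1, r2)
})

test_that("cross-tissue-only pairings fail loudly", {
  g <- toy_study(n_features = 40, seed = 21)
  sets <- gene_set_collection(list(c1 = rownames(g$study$values)[1:5]),
                              description = "brain")
  geps <- list(list(study = g$study, slice = toy_slice(g$study)))
  expect_error(validate_collection(sets, geps, n_perm = 10), "same-tissue")
})
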