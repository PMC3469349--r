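model_of <- function(...) list(features = c(...), fitness = 0.95,
                               algorithm = "knn", generation = 1L, seed = 1L)

test_that("model consolidation is the union of chromosomes", {
  expect_setequal(consolidate_models(list(model_of("g1", "g2", "g3", "g4", "g5"))),
                  c("g1", "g2", "g3", "g4", "g5"))
  u <- consolidate_models(list(model_of("g1", "g2", "g3"), model_of("g3", "g4", "g5")))
  expect_setequal(u, c("g1", "g2", "g3", "g4", "g5"))
  expect_length(u, 5)
  # duplicated identical models collapse to one copy
  expect_equal(consolidate_models(list(model_of("g1", "g2"), model_of("g1", "g2"))),
               c("g1", "g2"))
  expect_error(consolidate_models(list()), "no models")
})

test_that("a constant class offset forces bifurcation; permuted noise does not", {
  g <- toy_study(n_features = 30, n_treated = 6, n_control = 6, seed = 30)
  st <- g$study
  sl <- toy_slice(st)
  st$values[, sl$treated] <- st$values[, sl$treated] + 10
  # a uniform offset separates the classes in euclidean space but is
  # invisible to the correlation distance (cor(x + c, y) = cor(x, y))
  expect_true(qualify_by_bifurcation(rownames(st$values), st, sl,
                                     distance = "euclidean"))
  # a shift confined to half the features changes expression profile shape,
  # which the default correlation distance does see
  g3 <- toy_study(n_features = 30, n_treated = 6, n_control = 6,
                  planted = 1:15, delta = 8, seed = 30)
  expect_true(qualify_by_bifurcation(rownames(g3$study$values), g3$study,
                                     toy_slice(g3$study)))
  # pure noise with the same labels: no class structure to recover
  g2 <- toy_study(n_features = 30, n_treated = 6, n_control = 6, seed = 31)
  expect_false(qualify_by_bifurcation(rownames(g2$study$values), g2$study,
                                      toy_slice(g2$study)))
})

test_that("average-linkage merge order matches a hand-traced dendrogram", {
  # s1=(0,0) s2=(0,1) s3=(5,5) s4=(5,7): euclidean merges (s1,s2) then
  # (s3,s4); the 2-cut is {s1,s2} vs {s3,s4}
  vals <- matrix(c(0, 0, 0, 1, 5, 5, 5, 7), nrow = 2,
                 dimnames = list(c("f1", "f2"), c("s1", "s2", "s3", "s4")))
  samples <- data.frame(sample_id = colnames(vals), chemical = "c", tissue = "t",
                        class = c("treated", "treated", "control", "control"),
                        stringsAsFactors = FALSE)
  st <- expression_study(vals, samples)
  expect_true(qualify_by_bifurcation(c("f1", "f2"), st,
                                     condition_slice("c", "t", 1:2, 3:4),
                                     distance = "euclidean"))
  # with labels crossing the natural split the same data cannot qualify
  expect_false(qualify_by_bifurcation(c("f1", "f2"), st,
                                      condition_slice("c", "t", c(1, 3), c(2, 4)),
                                      distance = "euclidean"))
})

test_that("degenerate feature sets are unqualified with a reason, not an error", {
  g <- toy_study(n_features = 10, seed = 32)
  st <- g$study; sl <- toy_slice(st)
  st$values["p00001", ] <- 5                       # every sample vector constant
  st$values["p00002", ] <- 5
  res <- qualify_by_bifurcation(c("p00001", "p00002"), st, sl,
                                distance = "correlation")
  expect_false(isTRUE(res))
  expect_match(attr(res, "reason"), "zero-variance")
  res1 <- qualify_by_bifurcation("p00002", st, sl, distance = "correlation")
  expect_false(isTRUE(res1))
  expect_match(attr(res1, "reason"), "fewer than 2")
})

test_that("deduplication removes shared features from every condition", {
  cands <- list(
    A = list(condition = "A", features = c("g1", "g2", "g3")),
    B = list(condition = "B", features = c("g3", "g4")))
  out <- deduplicate_across_conditions(cands)
  expect_setequal(out$A$features, c("g1", "g2"))
  expect_setequal(out$B$features, "g4")
  # a feature in three conditions vanishes from all three
  cands3 <- list(
    A = list(condition = "A", features = c("g1", "gx")),
    B = list(condition = "B", features = c("g2", "gx")),
    C = list(condition = "C", features = c("g3", "gx")))
  out3 <- deduplicate_across_conditions(cands3)
  expect_false(any(vapply(out3, function(c) "gx" %in% c$features, TRUE)))
  # disjoint input is a fixed point
  disj <- list(A = list(condition = "A", features = c("g1", "g2")),
               B = list(condition = "B", features = c("g3")))
  expect_equal(lapply(deduplicate_across_conditions(disj), `[[`, "features"),
               lapply(disj, `[[`, "features"))
})

test_that("an emptied candidate is retained and flagged", {
  cands <- list(
    A = list(condition = "A", features = "gx"),
    B = list(condition = "B", features = c("gx", "g2")))
  out <- deduplicate_across_conditions(cands)
  expect_true(out$A$emptied)
  expect_length(out$A$features, 0)
  expect_false(out$B$emptied)
})

test_that("deduplicated candidates are always pairwise disjoint", {
  set.seed(33)
  for (rep in 1:20) {
    cands <- lapply(1:4, function(i)
      list(condition = paste0("c", i),
           features = sample(sprintf("g%02d", 1:30), sample(5:15, 1))))
    names(cands) <- vapply(cands, `[[`, "", "condition")
    out <- deduplicate_across_conditions(cands)
    feats <- lapply(out, `[[`, "features")
    for (i in seq_along(feats)) for (j in seq_along(feats))
      if (i < j) expect_length(intersect(feats[[i]], feats[[j]]), 0)
  }
})

test_that("ranking keeps the highest network counts up to the cap", {
  feats <- sprintf("g%03d", 1:150)
  cand <- list(condition = "A", features = feats)
  counts <- setNames(150:1, feats)      # distinct counts, g001 highest
  out <- rank_and_truncate(cand, counts, cap = 100)
  expect_length(out$features, 100)
  expect_setequal(out$features, feats[1:100])
  expect_true(out$truncated)
  # under the cap everything is retained
  small <- rank_and_truncate(list(condition = "A", features = feats[1:40]),
                             counts, cap = 100)
  expect_length(small$features, 40)
  expect_false(small$truncated)
})

test_that("rank ties break by selection frequency then feature id", {
  cand <- list(condition = "A", features = c("gC", "gB", "gA"))
  counts <- c(gA = 3, gB = 3, gC = 1)
  out <- rank_and_truncate(cand, counts, cap = 2)
  expect_equal(out$features, c("gA", "gB"))
  # frequency outranks the id tie-break
  freq <- c(gA = 1, gB = 5, gC = 1)
  out2 <- rank_and_truncate(cand, counts, selection_freq = freq, cap = 2)
  expect_equal(out2$features, c("gB", "gA"))
  expect_error(rank_and_truncate(list(condition = "A", features = "zz"), counts),
               "missing")
})

test_that("network selection counts track networks and models per feature", {
  batch_entry <- list(
    net1 = list(model_of("g1", "g2"), model_of("g1", "g3")),
    net2 = list(model_of("g1", "g4")),
    net3 = list())
  counts <- network_selection_counts(batch_entry)
  expect_equal(counts$network_counts[["g1"]], 2L)   # net1 and net2
  expect_equal(counts$network_counts[["g2"]], 1L)
  expect_equal(counts$selection_freq[["g1"]], 3L)   # three models
  restricted <- network_selection_counts(batch_entry, qualified_networks = "net2")
  expect_false("g2" %in% names(restricted$network_counts))
})

test_that("gene set export uses symbols where mapped and round-trips GMT", {
  cands <- list(
    A = list(condition = "chemA.ovary", tissue = "ovary",
             features = c("p1", "p2", "p3")),
    B = list(condition = "chemB.ovary", tissue = "ovary",
             features = c("p4", "p5")),
    C = list(condition = "chemC.ovary", tissue = "ovary", features = character()))
  gs <- export_gene_sets(cands, symbol_map = c(p1 = "sox9a", p4 = "cyp19a1"))
  expect_length(gs$sets, 2)                       # empty candidate skipped
  expect_setequal(gs$sets$chemA.ovary, c("sox9a", "p2", "p3"))  # fallback ids
  expect_setequal(gs$sets$chemB.ovary, c("cyp19a1", "p5"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_equal(back$sets, gs$sets)
  expect_equal(unname(back$description), unname(gs$description))
})
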