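#' Configuration for a genetic-algorithm classifier search
#'
#' The GA evolves fixed-length chromosomes of distinct feature indices under
#' tournament selection (size 2), uniform crossover, point mutation
#' (resampling one index from the search space) and elitism. Fitness is the
#' mean test-set accuracy of an SVM or KNN classifier over repeated
#' stratified random train/test splits. Whenever the best chromosome reaches
#' `fitness_goal` its model is collected and the population restarts, until
#' `n_models_to_collect` models are collected or the generation budget
#' `max_generations` is exhausted.
#'
#' @param algorithm `"svm"` (linear kernel, soft margin) or `"knn"`.
#' @param chromosome_size Features per chromosome (default 5).
#' @param population_size Chromosomes per generation (default 50).
#' @param max_generations Total generation budget of one search, consumed
#'   across restart cycles (default 200).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param crossover_rate Probability an offspring is produced by uniform
#'   crossover rather than cloning (default 0.9).
#' @param elitism_count Chromosomes carried over unchanged (default 1).
#' @param fitness_goal Accuracy a chromosome must reach for its model to be
#'   collected (default 0.90).
#' @param n_models_to_collect Stop after this many models (default 50).
#' @param n_splits Random stratified train/test splits per fitness
#'   evaluation (default 10).
#' @param train_fraction Fraction of each class used for training (default 2/3).
#' @param knn_k Neighbours for the KNN vote (default 3).
#' @param svm_cost Soft-margin cost, or `"auto"` to grid-search via
#'   [tune_svm_cost()] (default 1).
#' @param svm_cost_grid Grid used when `svm_cost = "auto"`.
#' @param tournament_size Tournament size for parent selection (default 2).
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return An object of class `search_config`.
#' @export
search_config <- function(algorithm = c("knn", "svm"),
                          chromosome_size = 5L, population_size = 50L,
                          max_generations = 200L, mutation_rate = 0.1,
                          crossover_rate = 0.9, elitism_count = 1L,
                          fitness_goal = 0.90, n_models_to_collect = 50L,
                          n_splits = 10L, train_fraction = 2 / 3,
                          knn_k = 3L, svm_cost = 1,
                          svm_cost_grid = c(0.01, 0.1, 1, 10, 100),
                          tournament_size = 2L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  counts <- c(chromosome_size, population_size, max_generations, elitism_count,
              n_models_to_collect, n_splits, knn_k, tournament_size)
  if (any(counts < 1)) stopf("all search counts must be positive")
  if (fitness_goal <= 0 || fitness_goal > 1) stopf("fitness_goal must lie in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1) stopf("train_fraction must lie in (0, 1)")
  structure(list(algorithm = algorithm,
                 chromosome_size = as.integer(chromosome_size),
                 population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elitism_count = as.integer(elitism_count),
                 fitness_goal = fitness_goal,
                 n_models_to_collect = as.integer(n_models_to_collect),
                 n_splits = as.integer(n_splits), train_fraction = train_fraction,
                 knn_k = as.integer(knn_k), svm_cost = svm_cost,
                 svm_cost_grid = svm_cost_grid,
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "search_config")
}

# z-score columns of train; apply the same transform to test. Constant
# columns get unit scale so they contribute nothing to distances.
standardize_pair <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train_x, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test_x, 2, mu), 2, sdv, "/"))
}

# Deterministic KNN: majority vote of the k nearest training samples by
# Euclidean distance on standardized features; distance ties resolved by
# training-sample order, class ties by the single nearest neighbour.
knn_classify <- function(train_x, train_y, test_x, k) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else as.character(train_y[nn[1]])
  })
}

split_accuracy <- function(X, y, split, config) {
  tr <- match(split$train, rownames(X)); te <- match(split$test, rownames(X))
  std <- standardize_pair(X[tr, , drop = FALSE], X[te, , drop = FALSE])
  y_tr <- y[tr]; y_te <- y[te]
  if (config$algorithm == "knn") {
    if (config$knn_k > min(table(y_tr)))
      stopf("knn_k = %d exceeds the smallest training class (%d)",
            config$knn_k, min(table(y_tr)))
    pred <- knn_classify(std$train, y_tr, std$test, config$knn_k)
  } else {
    fit <- e1071::svm(x = std$train, y = factor(y_tr), kernel = "linear",
                      cost = config$svm_cost, scale = FALSE)
    pred <- as.character(predict(fit, std$test))
  }
  mean(pred == as.character(y_te))
}

#' Mean cross-split accuracy of one feature subset
#'
#' Fitness of a chromosome: the mean test-set accuracy of the configured
#' classifier over `n_splits` stratified random train/test splits, using
#' only the chromosome's features. KNN uses the majority vote of the
#' `knn_k` nearest training samples by Euclidean distance on features
#' z-scored with training-sample statistics.
#'
#' @param chromosome Character vector of probe ids (or integer row indices).
#' @param study An [expression_study()].
#' @param slice A [condition_slice()].
#' @param config A [search_config()].
#' @param splits Optional precomputed split list; when `NULL`, splits are
#'   drawn deterministically from the config seed and the slice id.
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_fitness <- function(chromosome, study, slice, config, splits = NULL) {
  stopifnot(inherits(study, "expression_study"), inherits(slice, "condition_slice"))
  rows <- if (is.character(chromosome)) match(chromosome, rownames(study$values))
          else as.integer(chromosome)
  if (anyNA(rows) || anyDuplicated(rows) || any(rows < 1 | rows > nrow(study$values)))
    stopf("chromosome must be distinct features present in the study")
  cols <- c(slice$treated, slice$control)
  X <- t(study$values[rows, cols, drop = FALSE])
  rownames(X) <- as.character(cols)
  y <- ifelse(cols %in% slice$treated, "treated", "control")
  if (is.null(splits))
    splits <- make_splits(as.character(slice$treated), as.character(slice$control),
                          config$n_splits, config$train_fraction,
                          derive_seed(config$seed, "splits", slice$id))
  mean(vapply(splits, function(s) split_accuracy(X, y, s, config), 0))
}

#' Grid-search the SVM soft-margin cost for one condition
#'
#' Evaluates each cost on the full feature set of the slice by mean
#' cross-split accuracy of a linear-kernel SVM (shared splits across grid
#' points) and returns the maximiser; ties break toward the smallest cost.
#'
#' @param study An [expression_study()].
#' @param slice A [condition_slice()].
#' @param cost_grid Positive costs to try.
#' @param config A [search_config()] (split settings and seed are used).
#' @return The chosen cost (a single number).
#' @export
tune_svm_cost <- function(study, slice, cost_grid, config = search_config("svm")) {
  if (!length(cost_grid)) stopf("empty cost grid")
  if (any(cost_grid <= 0)) stopf("costs must be positive")
  splits <- make_splits(as.character(slice$treated), as.character(slice$control),
                        config$n_splits, config$train_fraction,
                        derive_seed(config$seed, "cost_grid", slice$id))
  all_feats <- rownames(study$values)
  acc <- vapply(cost_grid, function(cost) {
    cfg <- config; cfg$algorithm <- "svm"; cfg$svm_cost <- cost
    evaluate_fitness(all_feats, study, slice, cfg, splits = splits)
  }, 0)
  ord <- order(cost_grid)
  cost_grid[ord][which.max(acc[ord])]
}

random_chromosome <- function(space, size) sort(sample(space, size))

repair_chromosome <- function(chrom, space, size) {
  chrom <- unique(chrom)
  while (length(chrom) < size) {
    pool <- setdiff(space, chrom)
    chrom <- c(chrom, sample(pool, min(size - length(chrom), length(pool))))
  }
  sort(chrom[seq_len(size)])
}

#' Genetic-algorithm feature-subset search on one condition
#'
#' Evolves chromosomes sampled from `feature_space` to maximise classifier
#' accuracy on the slice. Each chromosome is scored once, on fresh random
#' stratified splits drawn at its first evaluation, and the value is cached:
#' the estimate is unbiased (the GA cannot hill-climb a lucky split set, so
#' pure-noise data cannot reach the goal) and the recorded best fitness is
#' non-decreasing under elitism. After each chromosome reaching the fitness
#' Any chromosome reaching the fitness goal is re-evaluated on an
#' independent set of fresh splits; only if the confirmation also reaches
#' the goal is the model collected (achieved fitness = mean of the two
#' evaluations), and the population restarts from scratch either way, so a
#' cycle cannot keep climbing into dataset-specific overfitting after a
#' goal-hit. The search ends when `n_models_to_collect` models are
#' collected or the generation budget is spent. Deterministic given the
#' config seed.
#'
#' @param study An [expression_study()].
#' @param slice A [condition_slice()].
#' @param feature_space Character vector of probe ids to search within
#'   (`NULL` = all features in the study).
#' @param config A [search_config()]. `svm_cost = "auto"` triggers a cost
#'   grid search first.
#' @return A list of models, each with `features` (probe ids), `fitness`,
#'   `algorithm`, `generation` and `seed`; empty if no chromosome reached
#'   the goal. Attributes `generations_used` and `n_rejected` record the
#'   budget consumed and the goal-hits that failed confirmation.
#' @export
ga_search <- function(study, slice, feature_space = NULL, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  space <- feature_space %||% rownames(study$values)
  space <- intersect(space, rownames(study$values))
  if (length(space) < config$chromosome_size)
    stopf("feature space (%d) smaller than chromosome size (%d)",
          length(space), config$chromosome_size)
  if (identical(config$svm_cost, "auto") && config$algorithm == "svm")
    config$svm_cost <- tune_svm_cost(study, slice, config$svm_cost_grid, config)

  set.seed(derive_seed(config$seed, "ga", slice$id))
  # Fresh random splits are drawn at a chromosome's first evaluation and the
  # result cached: the accuracy estimate is unbiased (a lucky split set
  # cannot be hill-climbed by the GA, so pure-noise data cannot reach the
  # goal), while the cache keeps the recorded best fitness monotone under
  # elitism and the whole search deterministic given the seed.
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(chrom) {
    key <- paste(chrom, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    splits <- make_splits(as.character(slice$treated), as.character(slice$control),
                          config$n_splits, config$train_fraction, seed = NULL)
    f <- evaluate_fitness(chrom, study, slice, config, splits = splits)
    cache[[key]] <- f
    f
  }
  new_population <- function()
    lapply(seq_len(config$population_size),
           function(i) random_chromosome(space, config$chromosome_size))
  pop <- new_population()
  models <- list()
  gen <- 0L
  n_rejected <- 0L
  while (gen < config$max_generations &&
         length(models) < config$n_models_to_collect) {
    gen <- gen + 1L
    fit <- vapply(pop, fitness_of, 0)
    best <- which.max(fit)
    if (fit[best] >= config$fitness_goal) {
      # Guard against the winner's curse: a goal-hit must be confirmed on an
      # independent set of fresh splits before its model is collected. Either
      # way the population restarts, so one cycle cannot keep climbing into
      # dataset-specific overfitting after reaching the goal.
      conf_splits <- make_splits(as.character(slice$treated),
                                 as.character(slice$control),
                                 config$n_splits, config$train_fraction,
                                 seed = NULL)
      conf <- evaluate_fitness(pop[[best]], study, slice, config,
                               splits = conf_splits)
      achieved <- mean(c(fit[best], conf))
      if (conf >= config$fitness_goal) {
        models[[length(models) + 1L]] <- list(
          features = pop[[best]], fitness = achieved,
          algorithm = config$algorithm, generation = gen, seed = config$seed)
      } else {
        n_rejected <- n_rejected + 1L
        key <- paste(pop[[best]], collapse = ",")
        cache[[key]] <- achieved
      }
      pop <- new_population()
      next
    }
    elite <- pop[order(-fit)[seq_len(config$elitism_count)]]
    offspring <- lapply(seq_len(config$population_size - config$elitism_count),
                        function(i) {
      pick <- function() {
        cand <- sample(length(pop), config$tournament_size)
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      child <- if (runif(1) < config$crossover_rate) {
        take <- runif(config$chromosome_size) < 0.5
        ifelse(take, p1, p2)
      } else p1
      mut <- runif(config$chromosome_size) < config$mutation_rate
      if (any(mut)) child[mut] <- sample(space, sum(mut), replace = TRUE)
      repair_chromosome(child, space, config$chromosome_size)
    })
    pop <- c(elite, offspring)
  }
  structure(models, generations_used = gen, n_rejected = n_rejected)
}

#' Run the GA over every (condition, network) pair
#'
#' One independent [ga_search()] per condition and network (including any
#' special compiled sets present in the collection, e.g. a master-regulator
#' hub list or a curated pathway list), each with its own derived seed.
#' Networks smaller than the chromosome size are skipped with a logged
#' reason; per-pair errors are recorded, never fatal.
#'
#' @param study An [expression_study()].
#' @param slices List of [condition_slice()] objects.
#' @param networks A [gene_set_collection()].
#' @param config A [search_config()].
#' @return Nested list `result[[condition]][[network]]` of model lists;
#'   attribute `skipped` is a data frame (condition, network, reason).
#' @export
batch_network_search <- function(study, slices, networks, config = search_config()) {
  stopifnot(inherits(networks, "gene_set_collection"))
  if (!length(networks$sets)) stopf("empty network collection")
  results <- list(); skipped <- list()
  for (sl in slices) {
    per_net <- list()
    for (net in names(networks$sets)) {
      space <- intersect(networks$sets[[net]], rownames(study$values))
      if (length(space) < config$chromosome_size) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = sl$id, network = net,
          reason = sprintf("network size %d < chromosome size %d",
                           length(space), config$chromosome_size))
        next
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, "network_search", sl$id, net)
      res <- tryCatch(ga_search(study, sl, space, cfg), error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          condition = sl$id, network = net, reason = conditionMessage(res))
      } else per_net[[net]] <- res
    }
    results[[sl$id]] <- per_net
  }
  attr(results, "skipped") <- if (length(skipped))
    do.call(rbind, c(skipped, list(make.row.names = FALSE)))
  else data.frame(condition = character(), network = character(), reason = character())
  results
}
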