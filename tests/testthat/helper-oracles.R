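# Independent brute-force oracles, written as plain loops over the defining
# formulas so they share no code path with the package implementations.

# Fisher's discriminant ratio, one feature at a time.
oracle_f_ratio <- function(values, treated, control) {
  out <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    x1 <- values[i, treated]; x2 <- values[i, control]
    m1 <- sum(x1) / length(x1); m2 <- sum(x2) / length(x2)
    v1 <- sum((x1 - m1)^2) / (length(x1) - 1)
    v2 <- sum((x2 - m2)^2) / (length(x2) - 1)
    out[i] <- (m1 - m2)^2 / (v1 + v2)
  }
  out
}

# Weighted running-sum enrichment score, step by step.
oracle_es <- function(features, metric, gene_set, p) {
  n <- length(features)
  in_set <- features %in% gene_set
  nr <- 0
  for (i in seq_len(n)) if (in_set[i]) nr <- nr + abs(metric[i])^p
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      run <- run + (if (nr > 0) abs(metric[i])^p / nr else 1 / sum(in_set))
    } else {
      run <- run - 1 / (n - sum(in_set))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Small two-class study with optional planted mean shift, for fixtures.
toy_study <- function(n_features = 40, n_treated = 6, n_control = 6,
                      planted = integer(), delta = 0, seed = 1,
                      chemical = "chemX", tissue = "ovary") {
  params <- simulation_params(
    n_features = n_features,
    conditions = list(sim_condition(chemical, tissue, n_treated, n_control,
                                    planted = planted, delta = delta)),
    seed = seed)
  generate_study(params)
}

toy_slice <- function(study) assemble_conditions(study, min_arrays = 2)[[1]]
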