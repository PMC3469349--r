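#' Per-feature Fisher's discriminant ratio for one condition
#'
#' For each feature i, f_i = (mu1 - mu2)^2 / (s1^2 + s2^2), with unbiased
#' (n-1) class variances. The ratio is affine-invariant and summarises how
#' well a single feature separates the treated and control classes; its
#' condition-level maximum is a standard complexity measure for two-class
#' expression data (smaller maximum = less separable = more complex).
#'
#' Degenerate features with both classes constant get f_i = 0 when the class
#' means agree; when the means differ the ratio is infinite and the feature
#' is flagged (`degenerate`) and excluded from the condition maximum rather
#' than allowed to dominate it.
#'
#' @param study An [expression_study()].
#' @param slice A [condition_slice()]; each class needs >= 2 samples.
#' @return An object of class `f_ratio_profile`: data frame fields `f`
#'   (per-feature ratio), `mu1`, `mu2`, `var1`, `var2`, `degenerate`, plus
#'   the condition id.
#' @export
fisher_ratio_per_feature <- function(study, slice) {
  stopifnot(inherits(study, "expression_study"), inherits(slice, "condition_slice"))
  if (length(slice$treated) < 2 || length(slice$control) < 2)
    stopf("condition %s: each class needs >= 2 samples for a variance", slice$id)
  x1 <- study$values[, slice$treated, drop = FALSE]
  x2 <- study$values[, slice$control, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  var1 <- rowSums((x1 - mu1)^2) / (ncol(x1) - 1)
  var2 <- rowSums((x2 - mu2)^2) / (ncol(x2) - 1)
  denom <- var1 + var2
  num <- (mu1 - mu2)^2
  f <- unname(ifelse(denom > 0, num / denom, ifelse(num == 0, 0, Inf)))
  degenerate <- !is.finite(f)
  structure(list(feature = rownames(study$values), f = f,
                 mu1 = unname(mu1), mu2 = unname(mu2),
                 var1 = unname(var1), var2 = unname(var2),
                 degenerate = degenerate, condition = slice$id),
            class = "f_ratio_profile")
}

#' Condition-level complexity summary of an F-ratio profile
#'
#' Returns the maximum per-feature Fisher ratio (excluding degenerate
#' infinite features) together with the arg-max feature. A mean-based
#' summary is exposed as an alternative but the maximum is the default.
#'
#' @param profile An `f_ratio_profile` from [fisher_ratio_per_feature()].
#' @param summary `"max"` (default) or `"mean"`.
#' @return A list with `value`, `feature` (arg-max id; `NA` for `"mean"`),
#'   `condition` and `n_degenerate`.
#' @export
condition_complexity <- function(profile, summary = c("max", "mean")) {
  stopifnot(inherits(profile, "f_ratio_profile"))
  summary <- match.arg(summary)
  ok <- !profile$degenerate
  if (!any(ok)) stopf("no non-degenerate features in profile")
  f <- profile$f[ok]
  if (summary == "max") {
    j <- which.max(f)
    list(value = f[j], feature = profile$feature[ok][j],
         condition = profile$condition, n_degenerate = sum(!ok))
  } else {
    list(value = mean(f), feature = NA_character_,
         condition = profile$condition, n_degenerate = sum(!ok))
  }
}

#' Per-condition complexity table
#'
#' Convenience wrapper producing one row per condition with the condition
#' F-ratio and arg-max feature, the form in which data complexity is
#' reported alongside enrichment results.
#'
#' @param study An [expression_study()].
#' @param slices List of [condition_slice()] objects.
#' @return Data frame with columns `condition`, `f_ratio`, `argmax_feature`.
#' @export
complexity_table <- function(study, slices) {
  rows <- lapply(slices, function(sl) {
    cc <- condition_complexity(fisher_ratio_per_feature(study, sl))
    data.frame(condition = cc$condition, f_ratio = cc$value,
               argmax_feature = cc$feature, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
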