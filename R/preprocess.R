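#' Split two-colour arrays into single-channel samples
#'
#' Two-colour arrays whose channels carry distinct biological samples are
#' decomposed into one single-channel sample per channel, so a binary
#' treated-vs-control search can treat every hybridised sample independently.
#' Arrays listed in `exclude` (e.g. dye swaps) contribute no samples.
#'
#' @param raw_arrays A list with components `probe_ids` (character), `cy5`
#'   and `cy3` (numeric matrices, features x arrays, log2 intensities) and
#'   `arrays` (data frame with one row per array: `array_id` plus
#'   channel-specific annotation columns `chemical_cy5`, `tissue_cy5`,
#'   `class_cy5`, `duration_cy5` and the `_cy3` counterparts).
#' @param exclude Character vector of array ids to drop.
#' @return An [expression_study()] with sample ids `<array_id>.Cy5` /
#'   `<array_id>.Cy3`.
#' @export
split_channels <- function(raw_arrays, exclude = character()) {
  arr <- raw_arrays$arrays
  for (ch in c("cy5", "cy3")) {
    need <- paste(c("chemical", "tissue", "class"), ch, sep = "_")
    bad <- !stats::complete.cases(arr[, need])
    if (any(bad))
      stopf("array %s: channel %s lacks sample annotation",
            paste(arr$array_id[bad], collapse = ", "), toupper(ch))
  }
  keep <- !(arr$array_id %in% exclude)
  if (!any(keep)) stopf("all arrays excluded")
  arr <- arr[keep, , drop = FALSE]

  one_channel <- function(ch) {
    suffix <- c(cy5 = "Cy5", cy3 = "Cy3")[[ch]]
    data.frame(
      sample_id = paste(arr$array_id, suffix, sep = "."),
      chemical = arr[[paste0("chemical_", ch)]],
      tissue = arr[[paste0("tissue_", ch)]],
      class = arr[[paste0("class_", ch)]],
      duration = if (!is.null(arr[[paste0("duration_", ch)]]))
        arr[[paste0("duration_", ch)]] else NA_integer_,
      array_id = arr$array_id, channel = suffix,
      stringsAsFactors = FALSE)
  }
  annos <- rbind(one_channel("cy5"), one_channel("cy3"))
  values <- cbind(raw_arrays$cy5[, keep, drop = FALSE],
                  raw_arrays$cy3[, keep, drop = FALSE])
  rownames(values) <- raw_arrays$probe_ids
  colnames(values) <- annos$sample_id
  # interleave so each array's two samples sit together, Cy5 before Cy3
  ord <- unlist(lapply(arr$array_id, function(a)
    which(annos$array_id == a)[order(annos$channel[annos$array_id == a], decreasing = TRUE)]))
  expression_study(values[, ord, drop = FALSE], annos[ord, , drop = FALSE])
}

#' Remove probes with low intensity across samples
#'
#' Retains exactly the probes whose log2 intensity is at least `floor` in at
#' least `min_fraction` of samples. Idempotent; the sample set is unchanged.
#'
#' @param study An [expression_study()].
#' @param floor Log2 intensity floor (default `log2(64)` = 6).
#' @param min_fraction Minimum fraction of samples at or above the floor.
#' @return The filtered study.
#' @export
filter_low_intensity <- function(study, floor = log2(64), min_fraction = 0.75) {
  stopifnot(inherits(study, "expression_study"))
  if (min_fraction < 0 || min_fraction > 1) stopf("min_fraction must lie in [0, 1]")
  frac <- rowMeans(study$values >= floor)
  keep <- frac >= min_fraction
  if (!any(keep))
    stopf("intensity filter (floor=%.3g, min_fraction=%.2f) removed every probe",
          floor, min_fraction)
  expression_study(study$values[keep, , drop = FALSE], study$samples)
}

#' Quantile-normalize a study across samples
#'
#' Forces every sample's value distribution onto the common distribution of
#' cross-sample row means of sorted columns, preserving within-sample ranks;
#' tied values share the mean of the tied ranks' target values.
#'
#' @param study An [expression_study()] with at least 2 samples.
#' @return The normalized study.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 2) stopf("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(study$values, ties = TRUE)
  dimnames(norm) <- dimnames(study$values)
  expression_study(norm, study$samples)
}

#' Assemble chemical-tissue condition slices with the sample-size gate
#'
#' Builds one [condition_slice()] per (chemical, tissue) pair having both
#' classes present. Conditions backed by fewer than `min_arrays` microarrays
#' are excluded, mirroring the minimum needed for repeated random train/test
#' splitting; exclusions are reported via the `excluded` attribute.
#'
#' @param study An [expression_study()].
#' @param min_arrays Minimum number of arrays backing a condition (default 9).
#' @param tissue_mode `"per_tissue"` (default) keeps conditions as
#'   (chemical, tissue) contrasts; `"combined"` collapses tissue labels into
#'   one pooled pseudo-tissue per chemical, the negative-control design in
#'   which tissue variance dominates.
#' @return A list of [condition_slice()] objects; attribute `excluded` is a
#'   data frame naming gated-out conditions and their array counts.
#' @export
assemble_conditions <- function(study, min_arrays = 9,
                                tissue_mode = c("per_tissue", "combined")) {
  stopifnot(inherits(study, "expression_study"))
  tissue_mode <- match.arg(tissue_mode)
  ann <- study$samples
  tissue <- if (tissue_mode == "combined") rep("combined", nrow(ann)) else ann$tissue
  key <- paste(ann$chemical, tissue, sep = ".")
  slices <- list(); excluded <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    treated <- idx[ann$class[idx] == "treated"]
    control <- idx[ann$class[idx] == "control"]
    if (!length(treated) || !length(control)) next
    n_arr <- if (all(is.na(ann$array_id[idx]))) ceiling(length(idx) / 2)
             else length(unique(ann$array_id[idx]))
    if (n_arr < min_arrays) {
      excluded[[k]] <- data.frame(condition = k, n_arrays = n_arr,
                                  reason = sprintf("fewer than %d arrays", min_arrays))
      next
    }
    slices[[k]] <- condition_slice(ann$chemical[idx[1]], tissue[idx[1]],
                                   treated, control, n_arrays = n_arr)
  }
  if (!length(slices))
    stopf("no condition passes the %d-array gate", min_arrays)
  attr(slices, "excluded") <- if (length(excluded))
    do.call(rbind, c(excluded, list(make.row.names = FALSE)))
  else data.frame(condition = character(), n_arrays = integer(), reason = character())
  slices
}
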