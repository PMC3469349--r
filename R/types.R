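#' Expression study container
#'
#' Bundles a probes-by-samples matrix of log2 intensities with per-sample
#' annotations. This is the substrate of every downstream stage: complexity
#' characterisation, classifier search, qualification and enrichment all take
#' an `expression_study` plus a [condition_slice()].
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Rownames are probe ids, colnames sample ids.
#' @param samples Data frame with one row per sample and columns `sample_id`,
#'   `chemical`, `tissue`, `class` (`"treated"` or `"control"`), and
#'   optionally `duration`, `array_id`, `channel`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry probe ids (rownames) and sample ids (colnames)")
  required <- c("sample_id", "chemical", "tissue", "class")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stopf("sample annotations lack column(s): %s", paste(missing, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stopf("annotation rows (%d) != sample columns (%d)", nrow(samples), ncol(values))
  if (!identical(samples$sample_id, colnames(values)))
    stopf("sample_id column must match the matrix column names, in order")
  if (anyNA(samples$class) || !all(samples$class %in% c("treated", "control")))
    stopf("every sample needs class 'treated' or 'control'")
  structure(list(values = values, samples = samples), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$chemical, x$samples$tissue)
  cat(sprintf("  %d chemical(s), %d tissue(s), %d treated / %d control\n",
              nrow(tab), ncol(tab),
              sum(x$samples$class == "treated"),
              sum(x$samples$class == "control")))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' One chemical-tissue condition within a study
#'
#' Treated and control sample index sets for a single chemical-tissue
#' contrast, the unit at which classifiers are searched and validated.
#'
#' @param chemical,tissue Condition labels.
#' @param treated,control Integer column indices into the study matrix.
#' @param n_arrays Number of microarrays backing the condition (used by the
#'   sample-size gate).
#' @return An object of class `condition_slice`.
#' @export
condition_slice <- function(chemical, tissue, treated, control, n_arrays = NA_integer_) {
  if (length(intersect(treated, control)))
    stopf("treated and control sample sets overlap")
  if (!length(treated) || !length(control))
    stopf("condition %s needs both classes non-empty", condition_id(chemical, tissue))
  structure(list(chemical = chemical, tissue = tissue,
                 treated = as.integer(treated), control = as.integer(control),
                 n_arrays = as.integer(n_arrays),
                 id = condition_id(chemical, tissue)),
            class = "condition_slice")
}

#' @export
print.condition_slice <- function(x, ...) {
  cat(sprintf("<condition_slice> %s: %d treated vs %d control (%s arrays)\n",
              x$id, length(x$treated), length(x$control),
              ifelse(is.na(x$n_arrays), "?", x$n_arrays)))
  invisible(x)
}

#' Named gene set collection (GMT semantics)
#'
#' A named list of character vectors of member features, plus a description
#' per set. Used both for transcription-factor networks (restricted search
#' spaces) and for exported classifiers handed to enrichment analysis.
#'
#' @param sets Named list of character vectors.
#' @param description Character vector of per-set descriptions (recycled).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<gene_set_collection> %d set(s), sizes %s..%s\n",
              length(x$sets),
              if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Probe catalog for one array design
#'
#' @param probes Data frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `strand`, `sequence`. Coordinates are 0-based half-open (BED convention).
#' @return An object of class `probe_catalog`.
#' @export
probe_catalog <- function(probes) {
  required <- c("probe_id", "chrom", "start", "end", "strand", "sequence")
  missing <- setdiff(required, names(probes))
  if (length(missing))
    stopf("probe catalog lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stopf("duplicate probe ids in catalog")
  if (!all(grepl("^[ACGT]+$", probes$sequence)))
    stopf("probe sequences must be over {A,C,G,T}")
  structure(list(probes = probes), class = "probe_catalog")
}

#' @export
print.probe_catalog <- function(x, ...) {
  cat(sprintf("<probe_catalog> %d probes, %d chromosome(s)\n",
              nrow(x$probes), length(unique(x$probes$chrom))))
  invisible(x)
}
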