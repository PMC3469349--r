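#' Write / read a gene set collection in GMT format
#'
#' GMT (gene matrix transposed): one tab-delimited line per set — name,
#' description, then member identifiers.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a
#'   [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  gene_set_collection(sets, desc)
}

#' Write / read an expression study as tab-delimited text
#'
#' The matrix file has probe ids in the first column and sample ids in the
#' header; annotations go to a companion table.
#'
#' @param study An [expression_study()].
#' @param matrix_path,annotation_path Output files.
#' @return `write_study` returns the paths invisibly; `read_study` returns
#'   an [expression_study()].
#' @export
write_study <- function(study, matrix_path, annotation_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(probe_id = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$samples, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = matrix_path, annotation = annotation_path))
}

#' @rdname write_study
#' @export
read_study <- function(matrix_path, annotation_path) {
  df <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  samples <- read.delim(annotation_path, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  expression_study(values, samples)
}

#' Write / read a probe catalog as BED-like tab-delimited text
#'
#' Columns: probe_id, chrom, start, end, strand, sequence. Coordinates are
#' 0-based half-open (BED convention).
#'
#' @param catalog A [probe_catalog()].
#' @param path File path.
#' @return `write_probe_catalog` returns `path` invisibly;
#'   `read_probe_catalog` returns a [probe_catalog()].
#' @export
write_probe_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "probe_catalog"))
  write.table(catalog$probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_catalog
#' @export
read_probe_catalog <- function(path) {
  probe_catalog(read.delim(path, stringsAsFactors = FALSE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
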