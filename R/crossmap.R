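#' Alignment parameters for probe cross-mapping
#'
#' Local (Smith-Waterman) alignment with +1/-1 nucleotide scoring stands in
#' for a BLASTN search when mapping probes between two designs. The E-value
#' cutoffs of the two stringency levels are converted to minimum alignment
#' scores by the ungapped Karlin-Altschul relation `S = ln(K * m * n / E) /
#' lambda`; for the +1/-1 scheme with uniform base frequencies `lambda =
#' ln 3` exactly and `K ~ 0.333`.
#'
#' @param evalue_relaxed,evalue_elevated E-value cutoffs (defaults 1e-10,
#'   1e-25).
#' @param coord_tol_relaxed,coord_tol_elevated Maximum start-position
#'   difference in bp on the same chromosome (defaults 50, 20).
#' @param gap_opening,gap_extension Gap penalties for the aligner.
#' @param lambda,K Karlin-Altschul parameters.
#' @return A list of parameters for [match_probes()].
#' @export
align_params <- function(evalue_relaxed = 1e-10, evalue_elevated = 1e-25,
                         coord_tol_relaxed = 50, coord_tol_elevated = 20,
                         gap_opening = 2, gap_extension = 1,
                         lambda = log(3), K = 0.333) {
  list(evalue_relaxed = evalue_relaxed, evalue_elevated = evalue_elevated,
       coord_tol_relaxed = coord_tol_relaxed, coord_tol_elevated = coord_tol_elevated,
       gap_opening = gap_opening, gap_extension = gap_extension,
       lambda = lambda, K = K)
}

score_threshold <- function(evalue, m, n, params) {
  log(params$K * m * n / evalue) / params$lambda
}

#' Match probes between two array designs
#'
#' A probe pair is matched if ANY evidence class fires at the requested
#' stringency: identical sequences (`perfect_sequence`); local-alignment
#' score at or above the threshold implied by the stringency's E-value
#' cutoff (`alignment`); or same chromosome with start positions within the
#' stringency's tolerance (`coordinate`: |dstart| <= 50 bp relaxed, <= 20 bp
#' elevated). Many-to-many matches are allowed and every supporting
#' evidence class is recorded. The elevated mapping is a subset of the
#' relaxed mapping on any input.
#'
#' @param catalog_a,catalog_b [probe_catalog()] objects.
#' @param stringency `"relaxed"` or `"elevated"`.
#' @param params An [align_params()] list.
#' @param alignment_table Optional precomputed external alignment table
#'   (data frame `probe_a`, `probe_b`, `score`) used instead of the built-in
#'   aligner, the hook for real-data BLAST output.
#' @return A data frame of class `probe_mapping`: `probe_a`, `probe_b`,
#'   `evidence` (comma-joined classes), `stringency`.
#' @export
match_probes <- function(catalog_a, catalog_b,
                         stringency = c("relaxed", "elevated"),
                         params = align_params(), alignment_table = NULL) {
  stopifnot(inherits(catalog_a, "probe_catalog"), inherits(catalog_b, "probe_catalog"))
  stringency <- match.arg(stringency)
  a <- catalog_a$probes; b <- catalog_b$probes
  if (!nrow(a) || !nrow(b)) stopf("probe catalogs must be non-empty")

  coord_tol <- if (stringency == "relaxed") params$coord_tol_relaxed
               else params$coord_tol_elevated
  evalue <- if (stringency == "relaxed") params$evalue_relaxed
            else params$evalue_elevated

  # perfect sequence identity
  perfect <- merge(data.frame(probe_a = a$probe_id, sequence = a$sequence),
                   data.frame(probe_b = b$probe_id, sequence = b$sequence),
                   by = "sequence")[, c("probe_a", "probe_b")]

  # coordinate proximity on the same chromosome
  coord <- merge(data.frame(probe_a = a$probe_id, chrom = a$chrom, start_a = a$start),
                 data.frame(probe_b = b$probe_id, chrom = b$chrom, start_b = b$start),
                 by = "chrom")
  coord <- coord[abs(coord$start_a - coord$start_b) <= coord_tol,
                 c("probe_a", "probe_b")]

  # local alignment similarity
  if (is.null(alignment_table)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    pat <- Biostrings::DNAStringSet(setNames(a$sequence, a$probe_id))
    scores <- vapply(seq_len(nrow(b)), function(j) {
      Biostrings::pairwiseAlignment(
        pat, Biostrings::DNAString(b$sequence[j]), type = "local",
        substitutionMatrix = mat, gapOpening = params$gap_opening,
        gapExtension = params$gap_extension, scoreOnly = TRUE)
    }, numeric(nrow(a)))
    alignment_table <- data.frame(
      probe_a = rep(a$probe_id, times = nrow(b)),
      probe_b = rep(b$probe_id, each = nrow(a)),
      score = as.vector(scores), stringsAsFactors = FALSE)
  }
  thr <- score_threshold(evalue, mean(nchar(a$sequence)), mean(nchar(b$sequence)),
                         params)
  aligned <- alignment_table[alignment_table$score >= thr, c("probe_a", "probe_b")]

  tag <- function(df, ev) if (nrow(df)) cbind(df, evidence = ev) else
    data.frame(probe_a = character(), probe_b = character(), evidence = character())
  all_ev <- rbind(tag(perfect, "perfect_sequence"), tag(aligned, "alignment"),
                  tag(coord, "coordinate"))
  if (!nrow(all_ev)) {
    out <- data.frame(probe_a = character(), probe_b = character(),
                      evidence = character(), stringency = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("probe_mapping", "data.frame")
    return(out)
  }
  key <- paste(all_ev$probe_a, all_ev$probe_b, sep = "\r")
  ev <- tapply(as.character(all_ev$evidence), key, function(e)
    paste(sort(unique(e)), collapse = ","))
  pairs <- do.call(rbind, strsplit(names(ev), "\r", fixed = TRUE))
  out <- data.frame(probe_a = pairs[, 1], probe_b = pairs[, 2],
                    evidence = as.character(ev), stringency = stringency,
                    stringsAsFactors = FALSE)
  out <- out[order(out$probe_a, out$probe_b), ]
  rownames(out) <- NULL
  class(out) <- c("probe_mapping", "data.frame")
  out
}

#' Translate gene sets across array designs via a probe mapping
#'
#' Each member is replaced by its mapped partner(s); with the default
#' policy all mapped partners are kept, duplicates collapsed. Unmapped
#' members are dropped and counted in the per-set loss report (attribute
#' `loss`). A set losing all members is retained empty and flagged in the
#' loss report so validation can skip it with a logged reason.
#'
#' @param sets A [gene_set_collection()] keyed by design-A probe ids.
#' @param mapping A `probe_mapping` from [match_probes()].
#' @param policy `"all"` (every partner) or `"first"` (first partner by id).
#' @param direction `"a_to_b"` (default) or `"b_to_a"`.
#' @return A [gene_set_collection()] with attribute `loss` (data frame:
#'   set, n_members, n_mapped, n_dropped, emptied).
#' @export
translate_gene_sets <- function(sets, mapping, policy = c("all", "first"),
                                direction = c("a_to_b", "b_to_a")) {
  stopifnot(inherits(sets, "gene_set_collection"))
  policy <- match.arg(policy); direction <- match.arg(direction)
  from <- if (direction == "a_to_b") mapping$probe_a else mapping$probe_b
  to <- if (direction == "a_to_b") mapping$probe_b else mapping$probe_a
  loss <- list()
  new_sets <- lapply(names(sets$sets), function(nm) {
    members <- sets$sets[[nm]]
    mapped <- lapply(members, function(m) sort(unique(to[from == m])))
    hit <- lengths(mapped) > 0
    translated <- unlist(lapply(mapped[hit], function(v)
      if (policy == "first") v[1] else v), use.names = FALSE)
    translated <- unique(translated)
    loss[[nm]] <<- data.frame(set = nm, n_members = length(members),
                              n_mapped = sum(hit), n_dropped = sum(!hit),
                              emptied = length(translated) == 0,
                              stringsAsFactors = FALSE)
    translated
  })
  names(new_sets) <- names(sets$sets)
  out <- gene_set_collection(new_sets, sets$description)
  attr(out, "loss") <- do.call(rbind, c(loss, list(make.row.names = FALSE)))
  out
}
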