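#' Theoretical genome coverage of a molecule set
#'
#' Fold coverage implied by the raw molecule count and mean molecule length:
#' `n_maps * mean_len / genome_size`. For reports it is conventionally
#' rounded to one decimal. The default genome size of 3.0 Gb is the value
#' that reproduces published human optical-map coverages from the printed
#' map counts and mean molecule sizes.
#'
#' @param n_maps Number of molecules (> 0).
#' @param mean_len Mean molecule length (bp, > 0).
#' @param genome_size Genome size (bp, > 0), default 3.0e9.
#' @return Fold coverage (numeric, unrounded).
#' @examples
#' round(theoretical_coverage(309879, 285000), 1)  # 29.4
#' @export
theoretical_coverage <- function(n_maps, mean_len, genome_size = 3.0e9) {
  stopifnot(n_maps > 0, mean_len > 0)
  if (genome_size <= 0) stop("genome_size must be > 0")
  n_maps * mean_len / genome_size
}

#' Aligned yield in genome coverage
#'
#' Summed full length of uniquely aligned molecules divided by the genome
#' size. Whole-molecule (not aligned-span) accounting is used, which is why
#' the yield/theoretical ratio can exceed the count-based alignment rate:
#' longer molecules align more often.
#'
#' @param aln An `om_alignments`.
#' @param genome_size Genome size (bp), default 3.0e9.
#' @return Fold coverage of aligned data.
#' @export
yield_coverage <- function(aln, genome_size = 3.0e9) {
  stopifnot(inherits(aln, "om_alignments"))
  if (genome_size <= 0) stop("genome_size must be > 0")
  sum(as.numeric(aln$table$mol_length[aln$table$unique])) / genome_size
}

#' Pooled digestion-rate estimator
#'
#' Fraction of reference cut sites inside aligned spans that are matched by
#' a molecule cut, pooled over all unique alignments. Pooling (rather than
#' averaging per-molecule ratios) keeps short molecules from dominating.
#'
#' An aligned span is delimited by its first and last matched cut, so those
#' two sites are matched by construction and carry no information about the
#' digestion probability; counting them biases the estimate upward by about
#' `2 (1 - p) / n_sites` per molecule. With `exclude_delimiters = TRUE`
#' (the default) the two delimiting pairs are dropped from both numerator
#' and denominator, giving `sum(matched - 2) / sum(matched + missed - 2)`;
#' with `FALSE` the raw pooled ratio `sum(matched) / sum(matched + missed)`
#' is returned.
#'
#' @param aln An `om_alignments` with at least one unique alignment.
#' @param exclude_delimiters Drop the two span-delimiting matched cuts per
#'   alignment (bias correction), default `TRUE`.
#' @return Estimated per-site digestion probability.
#' @export
estimate_digestion_rate <- function(aln, exclude_delimiters = TRUE) {
  stopifnot(inherits(aln, "om_alignments"))
  tab <- aln$table[aln$table$unique, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no unique alignments to estimate from")
  off <- if (exclude_delimiters) 2L else 0L
  num <- sum(pmax(tab$matched_cuts - off, 0L))
  denom <- sum(pmax(tab$matched_cuts + tab$missed_ref_cuts - off, 0L))
  if (denom == 0) stop("no reference cuts in aligned spans")
  num / denom
}

#' Pooled extra-cut-rate estimator
#'
#' Molecule cuts not matched to any reference cut, per 100 kb of aligned
#' molecule length: `sum(false_mol_cuts) / sum(mol_length) * 1e5`, pooled
#' over unique alignments.
#'
#' @param aln An `om_alignments` with at least one unique alignment.
#' @return Extra cuts per 100 kb.
#' @export
estimate_extra_cut_rate <- function(aln) {
  stopifnot(inherits(aln, "om_alignments"))
  tab <- aln$table[aln$table$unique, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no unique alignments to estimate from")
  total_len <- sum(as.numeric(tab$mol_length))
  if (total_len == 0) stop("aligned molecule length is zero")
  sum(tab$false_mol_cuts) / total_len * 1e5
}

#' Small-missing-fragment ratio
#'
#' Among reference fragments of at most `threshold` bp lying strictly inside
#' aligned spans, the fraction that are absent from the molecule — i.e. whose
#' two flanking reference cuts are not both matched — pooled over unique
#' alignments. Small fragments go missing either through desorption or
#' because one of their flanking sites went undigested.
#'
#' @param aln An `om_alignments`.
#' @param rm_ The `om_refmap` the alignments refer to.
#' @param threshold Small-fragment threshold (bp, > 0), default 2000.
#' @return Fraction missing, or `NA` if no small fragment lies in any span.
#' @export
small_missing_ratio <- function(aln, rm_, threshold = 2000L) {
  stopifnot(inherits(aln, "om_alignments"), inherits(rm_, "om_refmap"),
            threshold > 0)
  tab <- aln$table
  n_small <- 0L
  n_missing <- 0L
  for (k in seq_len(nrow(tab))) {
    if (!tab$unique[k]) next
    ct <- rm_$contigs[[tab$contig_id[k]]]
    frag_len <- diff(c(0L, ct$cuts, ct$length))     # fragment q is frag_len[q+1]
    matched <- aln$matched_ref_cuts[[k]]
    # fully spanned interior fragments: both flanking cuts inside the span
    first_cut <- tab$ref_frag_start[k] + 1L          # = r_1
    last_cut <- tab$ref_frag_end[k] - 1L             # = r_K
    if (last_cut <= first_cut) next
    for (q in first_cut:(last_cut - 1L)) {           # 0-based fragment index
      if (frag_len[q + 1L] > threshold) next
      n_small <- n_small + 1L
      if (!(q %in% matched && (q + 1L) %in% matched))
        n_missing <- n_missing + 1L
    }
  }
  if (n_small == 0L) return(NA_real_)
  n_missing / n_small
}

#' QC summary table
#'
#' One row per molecule group plus a Total row, in the layout of a per-run
#' (MapCard-style) optical mapping QC report: molecule counts with
#' theoretical coverage, average molecule size, fragment count and fragment
#' size, alignment rate, aligned yield, and the alignment-based estimators
#' of digestion rate, extra-cut rate and small-missing-fragment ratio.
#' Groups are taken from the molecule id prefix before `":"`. Averages are
#' over molecules, except the average fragment size which is total length
#' over total fragment count.
#'
#' @param rmaps List of Rmaps.
#' @param aln An `om_alignments` over the same molecules.
#' @param rm_ Optional `om_refmap` (needed for the small-missing ratio).
#' @param filter Optional `om_filter` applied to the molecules (alignment
#'   rows of discarded molecules are dropped too).
#' @param genome_size Genome size (bp), default 3.0e9.
#' @return A data.frame, one row per group plus `"Total"`; estimator columns
#'   are `NA` where no unique alignment exists in the group.
#' @export
qc_summarize <- function(rmaps, aln, rm_ = NULL, filter = NULL,
                         genome_size = 3.0e9) {
  stopifnot(inherits(aln, "om_alignments"))
  if (!is.null(filter)) {
    rmaps <- apply_filter(rmaps, filter)$rmaps
    ids <- vapply(rmaps, `[[`, character(1), "id")
    keep <- aln$table$molecule_id %in% ids
    aln <- structure(list(table = aln$table[keep, , drop = FALSE],
                          matched_ref_cuts = aln$matched_ref_cuts[keep],
                          alignment_rate = NA_real_), class = "om_alignments")
  }
  ids <- vapply(rmaps, `[[`, character(1), "id")
  stopifnot(identical(ids, aln$table$molecule_id))
  groups <- sub(":.*$", "", ids)
  lens <- vapply(rmaps, `[[`, numeric(1), "length")
  nfr <- vapply(rmaps, function(r) length(r$fragments), integer(1))

  one_row <- function(sel, label) {
    sub_aln <- structure(list(table = aln$table[sel, , drop = FALSE],
                              matched_ref_cuts = aln$matched_ref_cuts[sel],
                              alignment_rate = NA_real_),
                         class = "om_alignments")
    n <- sum(sel)
    uniq <- sub_aln$table$unique
    has_aln <- any(uniq)
    data.frame(
      group = label,
      n_maps = n,
      theoretical_coverage = theoretical_coverage(n, mean(lens[sel]),
                                                  genome_size),
      avg_quality = NA_real_,
      avg_molecule_kb = mean(lens[sel]) / 1000,
      avg_n_fragments = mean(nfr[sel]),
      avg_fragment_kb = sum(lens[sel]) / sum(nfr[sel]) / 1000,
      alignment_rate = sum(uniq) / n,
      yield_coverage = yield_coverage(sub_aln, genome_size),
      digestion_rate = if (has_aln) estimate_digestion_rate(sub_aln) else NA_real_,
      extra_cut_rate_per_100kb = if (has_aln) estimate_extra_cut_rate(sub_aln)
                                 else NA_real_,
      small_missing_ratio = if (has_aln && !is.null(rm_))
        small_missing_ratio(sub_aln, rm_) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (length(rmaps) == 0L) stop("no molecules to summarize")
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g)
    one_row(groups == g, g)))
  if (nrow(out) > 1L) out <- rbind(out, one_row(rep(TRUE, length(ids)), "Total"))
  rownames(out) <- NULL
  out
}

#' Write a QC summary as TSV or JSON
#'
#' TSV output follows the conventional report formatting: coverages to one
#' decimal, rates to three decimals, sizes to one decimal kb.
#'
#' @param qc data.frame from [qc_summarize()].
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @param extra_header Optional `#`-prefixed header lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_qc <- function(qc, path, format = c("tsv", "json"),
                     extra_header = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(qc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    return(invisible(path))
  }
  fmt <- qc
  r1 <- function(x) ifelse(is.na(x), ".", sprintf("%.1f", x))
  r3 <- function(x) ifelse(is.na(x), ".", sprintf("%.3f", x))
  fmt$theoretical_coverage <- r1(qc$theoretical_coverage)
  fmt$avg_quality <- r3(qc$avg_quality)
  fmt$avg_molecule_kb <- r1(qc$avg_molecule_kb)
  fmt$avg_n_fragments <- r1(qc$avg_n_fragments)
  fmt$avg_fragment_kb <- r1(qc$avg_fragment_kb)
  fmt$alignment_rate <- r3(qc$alignment_rate)
  fmt$yield_coverage <- r1(qc$yield_coverage)
  fmt$digestion_rate <- r3(qc$digestion_rate)
  fmt$extra_cut_rate_per_100kb <- r3(qc$extra_cut_rate_per_100kb)
  fmt$small_missing_ratio <- r3(qc$small_missing_ratio)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(extra_header)) writeLines(extra_header, con)
  writeLines(paste(names(fmt), collapse = "\t"), con)
  for (k in seq_len(nrow(fmt)))
    writeLines(paste(unlist(fmt[k, ]), collapse = "\t"), con)
  invisible(path)
}
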