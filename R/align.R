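#' Glocal alignment parameters
#'
#' The aligner places the entire molecule on a local stretch of the
#' reference map (glocal alignment), allowing missed reference cuts (partial
#' digestion), false molecule cuts and Gaussian sizing error. Each aligned
#' block of merged fragments is scored
#' `-(mol - ref)^2 / (2 (sizing_cv * ref)^2) - miss_penalty * (n_merged_ref - 1)
#'  - false_penalty * (n_merged_mol - 1)`,
#' so a perfect size match with no merges scores 0 and higher is better.
#' Terminal molecule fragments are partial and scored one-sided (free when
#' they fit inside the flanking reference fragment).
#'
#' @param sizing_cv Relative sd used in the size-match term (> 0).
#' @param miss_penalty Cost per unmatched reference cut inside the span.
#' @param false_penalty Cost per unmatched molecule cut.
#' @param delta Maximum fragments merged per block on either side (>= 1);
#'   bounds the DP lookback.
#' @param min_matched_cuts Minimum matched cut pairs for an accepted
#'   placement.
#' @param margin Required score gap between the best placement and the best
#'   placement overlapping it by less than 50%; placements failing it are
#'   reported as ambiguous.
#' @return An `om_align_params` list.
#' @export
align_params <- function(sizing_cv = 0.10, miss_penalty = 1.1,
                         false_penalty = 2.5, delta = 6L,
                         min_matched_cuts = 6L, margin = 5.0) {
  stopifnot(sizing_cv > 0, miss_penalty >= 0, false_penalty >= 0,
            delta >= 1L, min_matched_cuts >= 1L, margin >= 0)
  structure(list(sizing_cv = sizing_cv, miss_penalty = miss_penalty,
                 false_penalty = false_penalty, delta = as.integer(delta),
                 min_matched_cuts = as.integer(min_matched_cuts),
                 margin = margin),
            class = "om_align_params")
}

#' Score one aligned block
#'
#' The score contribution of a block matching `n_merged_mol` molecule
#' fragments of total size `mol_block_size` against `n_merged_ref` reference
#' fragments of total size `ref_block_size`. Exposed mainly for
#' documentation and testing; the aligner computes the same quantity
#' internally.
#'
#' @param mol_block_size,ref_block_size Block sizes (bp, > 0).
#' @param n_merged_mol,n_merged_ref Fragments merged on each side (>= 1).
#' @param params An `om_align_params`.
#' @return Numeric score (<= 0; 0 for an exact single-fragment match).
#' @examples
#' score_block(11000, 10000, 1, 1, align_params(sizing_cv = 0.10))  # -0.5
#' @export
score_block <- function(mol_block_size, ref_block_size, n_merged_mol,
                        n_merged_ref, params = align_params()) {
  stopifnot(mol_block_size > 0, ref_block_size > 0,
            n_merged_mol >= 1L, n_merged_ref >= 1L)
  -((mol_block_size - ref_block_size)^2 /
      (2 * (params$sizing_cv * ref_block_size)^2)) -
    params$miss_penalty * (n_merged_ref - 1) -
    params$false_penalty * (n_merged_mol - 1)
}

# overlap fraction of two inclusive fragment-index spans, relative to the
# shorter span
.span_overlap <- function(s1, e1, s2, e2) {
  inter <- min(e1, e2) - max(s1, s2) + 1
  if (inter <= 0) return(0)
  inter / min(e1 - s1 + 1, e2 - s2 + 1)
}

#' Align one molecule to a reference map
#'
#' Dynamic programming over (molecule cut, reference cut) states with
#' lookback bounded by `delta` on both sides, evaluated on every contig in
#' both orientations (the reverse orientation aligns the reversed fragment
#' list). The best placement is accepted when it has at least
#' `min_matched_cuts` matched cut pairs and beats every placement
#' overlapping its span by less than 50% by at least `margin` (the
#' uniqueness test); otherwise no alignment is returned, with a reason code
#' `no_candidate`, `too_few_matches` or `ambiguous`.
#'
#' @param rmap_ One Rmap (`list(id, fragments, ...)`) with >= 2 fragments.
#' @param rm_ An `om_refmap`.
#' @param params An `om_align_params`.
#' @return A list: `aligned` (logical), `reason` (`"ok"` or a reason code),
#'   and when an alignment is produced: `contig`, `orientation`,
#'   `ref_frag_start` / `ref_frag_end` (0-based half-open fragment range),
#'   `matched_cuts`, `missed_ref_cuts`, `false_mol_cuts`, `score`, `unique`,
#'   `pairs` (two-column matrix of matched molecule cut / reference cut
#'   indices, molecule cuts in the aligned orientation's frame).
#' @export
align_molecule <- function(rmap_, rm_, params = align_params()) {
  stopifnot(inherits(rm_, "om_refmap"), inherits(params, "om_align_params"))
  frags <- as.numeric(rmap_$fragments)
  if (length(frags) < 2L)
    return(list(aligned = FALSE, reason = "too_few_fragments"))
  m <- length(frags)

  cand_all <- NULL
  contig_ids <- names(rm_$contigs)
  for (ci in seq_along(contig_ids)) {
    ct <- rm_$contigs[[ci]]
    if (length(ct$cuts) < 1L) next
    ref_frags <- as.numeric(diff(c(0L, ct$cuts, ct$length)))
    for (orient in c("+", "-")) {
      mf <- if (orient == "+") frags else rev(frags)
      res <- .dp_align(mf, ref_frags, params$sizing_cv, params$miss_penalty,
                       params$false_penalty, params$delta)
      cand <- res$cand
      if (nrow(cand) == 0L) next
      cand_all <- rbind(cand_all, cbind(cand, contig = ci,
                                        orient = if (orient == "+") 1 else -1))
    }
  }
  if (is.null(cand_all) || nrow(cand_all) == 0L)
    return(list(aligned = FALSE, reason = "no_candidate"))

  # deterministic best: score desc, then contig order, start cut, '+' first
  ord <- order(-cand_all[, "score"], cand_all[, "contig"],
               cand_all[, "start_cut"], -cand_all[, "orient"])
  cand_all <- cand_all[ord, , drop = FALSE]
  best <- cand_all[1L, ]
  b_span <- c(best[["start_cut"]] - 1, best[["end_cut"]])  # fragment indices

  if (best[["matched"]] < params$min_matched_cuts)
    return(list(aligned = FALSE, reason = "too_few_matches"))

  second <- NA_real_
  if (nrow(cand_all) > 1L) {
    for (r in 2:nrow(cand_all)) {
      if (cand_all[r, "contig"] != best[["contig"]] ||
          .span_overlap(b_span[1L], b_span[2L],
                        cand_all[r, "start_cut"] - 1,
                        cand_all[r, "end_cut"]) < 0.5) {
        second <- cand_all[r, "score"]
        break
      }
    }
  }
  uniq <- is.na(second) || best[["score"]] - second >= params$margin
  if (!uniq)
    return(list(aligned = FALSE, reason = "ambiguous",
                score = best[["score"]], second_score = second))

  orient <- if (best[["orient"]] > 0) "+" else "-"
  ct <- rm_$contigs[[best[["contig"]]]]
  ref_frags <- as.numeric(diff(c(0L, ct$cuts, ct$length)))
  mf <- if (orient == "+") frags else rev(frags)
  res <- .dp_align(mf, ref_frags, params$sizing_cv, params$miss_penalty,
                   params$false_penalty, params$delta,
                   path_end_i = as.integer(best[["end_mol_cut"]]),
                   path_end_j = as.integer(best[["end_cut"]]))
  pairs <- cbind(mol_cut = res$mol_cuts, ref_cut = res$ref_cuts)
  K <- nrow(pairs)
  missed <- (best[["end_cut"]] - best[["start_cut"]] + 1) - K
  list(
    aligned = TRUE, reason = "ok",
    contig = contig_ids[best[["contig"]]], orientation = orient,
    ref_frag_start = as.integer(best[["start_cut"]] - 1),
    ref_frag_end = as.integer(best[["end_cut"]] + 1),
    matched_cuts = as.integer(K),
    missed_ref_cuts = as.integer(missed),
    false_mol_cuts = as.integer(m - 1 - K),
    score = best[["score"]], unique = TRUE, pairs = pairs
  )
}

#' Align a set of Rmaps and tabulate the results
#'
#' Applies [align_molecule()] to every molecule. The alignment rate is the
#' fraction of input molecules with an accepted (unique) placement; with
#' zero molecules it is reported as 0 with a warning.
#'
#' @param rmaps List of Rmaps.
#' @param rm_ An `om_refmap`.
#' @param params An `om_align_params`.
#' @return An `om_alignments` list: `table` (one data.frame row per
#'   molecule: id, contig, orientation, span, counts, score, unique,
#'   reason, molecule length), `matched_ref_cuts` (per-molecule integer
#'   vector of matched reference cut indices, `NULL` when unaligned) and
#'   `alignment_rate`.
#' @export
align_all <- function(rmaps, rm_, params = align_params()) {
  n <- length(rmaps)
  if (n == 0L) {
    warning("no molecules to align; alignment rate reported as 0")
    return(structure(list(table = .empty_aln_table(),
                          matched_ref_cuts = list(),
                          alignment_rate = 0), class = "om_alignments"))
  }
  rows <- vector("list", n)
  cuts <- vector("list", n)
  for (k in seq_len(n)) {
    r <- rmaps[[k]]
    a <- align_molecule(r, rm_, params)
    if (isTRUE(a$aligned)) {
      rows[[k]] <- data.frame(
        molecule_id = r$id, contig_id = a$contig, orientation = a$orientation,
        ref_frag_start = a$ref_frag_start, ref_frag_end = a$ref_frag_end,
        matched_cuts = a$matched_cuts, missed_ref_cuts = a$missed_ref_cuts,
        false_mol_cuts = a$false_mol_cuts, score = a$score, unique = TRUE,
        reason = "ok", mol_length = r$length, stringsAsFactors = FALSE)
      cuts[[k]] <- as.integer(a$pairs[, "ref_cut"])
    } else {
      rows[[k]] <- data.frame(
        molecule_id = r$id, contig_id = NA_character_,
        orientation = NA_character_, ref_frag_start = NA_integer_,
        ref_frag_end = NA_integer_, matched_cuts = NA_integer_,
        missed_ref_cuts = NA_integer_, false_mol_cuts = NA_integer_,
        score = NA_real_, unique = FALSE, reason = a$reason,
        mol_length = r$length, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, matched_ref_cuts = cuts,
                 alignment_rate = sum(tab$unique) / n),
            class = "om_alignments")
}

.empty_aln_table <- function() {
  data.frame(molecule_id = character(), contig_id = character(),
             orientation = character(), ref_frag_start = integer(),
             ref_frag_end = integer(), matched_cuts = integer(),
             missed_ref_cuts = integer(), false_mol_cuts = integer(),
             score = numeric(), unique = logical(), reason = character(),
             mol_length = integer(), stringsAsFactors = FALSE)
}

#' @export
print.om_alignments <- function(x, ...) {
  cat("<om_alignments>", nrow(x$table), "molecules |",
      sum(x$table$unique), "uniquely aligned |",
      sprintf("rate %.3f", x$alignment_rate), "\n")
  invisible(x)
}

#' Write / read alignments as TSV
#'
#' Columns: `molecule_id`, `contig_id`, `orientation`, `ref_frag_start`,
#' `ref_frag_end`, `matched_cuts`, `missed_ref_cuts`, `false_mol_cuts`,
#' `score`, `unique`, `reason`, `mol_length`, plus `ref_cuts` — the matched
#' reference cut indices, comma separated — so that QC estimators (notably
#' the small-missing-fragment ratio) can be recomputed from the file.
#'
#' @param aln An `om_alignments`.
#' @param path File path.
#' @param extra_header Optional `#`-prefixed header lines.
#' @return `write_alignments` returns `path` invisibly; `read_alignments`
#'   returns an `om_alignments`.
#' @export
write_alignments <- function(aln, path, extra_header = NULL) {
  stopifnot(inherits(aln, "om_alignments"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#alignments v1", con)
  if (!is.null(extra_header)) writeLines(extra_header, con)
  writeLines(paste(c("molecule_id", "contig_id", "orientation",
                     "ref_frag_start", "ref_frag_end", "matched_cuts",
                     "missed_ref_cuts", "false_mol_cuts", "score", "unique",
                     "reason", "mol_length", "ref_cuts"), collapse = "\t"), con)
  tab <- aln$table
  for (k in seq_len(nrow(tab))) {
    cuts <- aln$matched_ref_cuts[[k]]
    writeLines(paste(
      tab$molecule_id[k],
      ifelse(is.na(tab$contig_id[k]), ".", tab$contig_id[k]),
      ifelse(is.na(tab$orientation[k]), ".", tab$orientation[k]),
      .na_int(tab$ref_frag_start[k]), .na_int(tab$ref_frag_end[k]),
      .na_int(tab$matched_cuts[k]), .na_int(tab$missed_ref_cuts[k]),
      .na_int(tab$false_mol_cuts[k]),
      ifelse(is.na(tab$score[k]), ".",
             format(tab$score[k], digits = 17, scientific = FALSE)),
      ifelse(tab$unique[k], "1", "0"), tab$reason[k], tab$mol_length[k],
      if (is.null(cuts) || length(cuts) == 0L) "." else
        paste(cuts, collapse = ","),
      sep = "\t"), con)
  }
  invisible(path)
}

.na_int <- function(x) ifelse(is.na(x), ".", as.character(x))

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#alignments v1", lines[[1L]]))
    stop("line 1: missing '#alignments v1' header in ", path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) stop("alignment file has no rows: ", path)
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1]]
  rows <- vector("list", length(body) - 1L)
  cuts <- vector("list", length(body) - 1L)
  for (k in seq_along(rows)) {
    parts <- strsplit(body[[k + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != length(header))
      stop("line ", k + 1L, ": expected ", length(header), " fields, got ",
           length(parts))
    gi <- function(x) if (x == ".") NA_integer_ else as.integer(x)
    rows[[k]] <- data.frame(
      molecule_id = parts[1L],
      contig_id = if (parts[2L] == ".") NA_character_ else parts[2L],
      orientation = if (parts[3L] == ".") NA_character_ else parts[3L],
      ref_frag_start = gi(parts[4L]), ref_frag_end = gi(parts[5L]),
      matched_cuts = gi(parts[6L]), missed_ref_cuts = gi(parts[7L]),
      false_mol_cuts = gi(parts[8L]),
      score = if (parts[9L] == ".") NA_real_ else as.numeric(parts[9L]),
      unique = parts[10L] == "1", reason = parts[11L],
      mol_length = as.integer(parts[12L]), stringsAsFactors = FALSE)
    cuts[[k]] <- if (parts[13L] == ".") NULL else
      as.integer(strsplit(parts[13L], ",", fixed = TRUE)[[1]])
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, matched_ref_cuts = cuts,
                 alignment_rate = if (nrow(tab)) sum(tab$unique) / nrow(tab) else 0),
            class = "om_alignments")
}
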