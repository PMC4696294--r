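#' Fragment-size statistics for enzyme selection
#'
#' Summarizes the fragment-size distribution of an in-silico digest the way
#' an enzyme-selection screen needs it: the percentage of fragments falling
#' in "usable" size windows (small fragments size poorly on an optical
#' mapper; very large ones yield maps with too few fragments), the average
#' and maximum fragment size, and the number of very large fragments.
#' Fragments are pooled across contigs and terminal fragments are included;
#' window bounds are inclusive at both ends.
#'
#' @param rm_ An `om_refmap`.
#' @param windows List of `c(lo, hi)` windows in kb. Default the three
#'   standard screens: 5–20, 6–15 and 6–12 kb.
#' @param big_threshold Threshold in kb for the large-fragment count
#'   (strictly greater than), default 100.
#' @return A one-row data.frame: `enzyme`, one `usable_pct_<lo>_<hi>` column
#'   per window, `avg_fragment_kb`, `max_fragment_kb`, `n_fragments_gt_big`.
#' @examples
#' rm_ <- refmap(builtin_enzymes("KpnI"),
#'               list(c1 = list(length = 46000L, cuts = c(4000L, 14000L, 39000L))))
#' fragment_stats(rm_)
#' @export
fragment_stats <- function(rm_, windows = list(c(5, 20), c(6, 15), c(6, 12)),
                           big_threshold = 100) {
  frags <- refmap_fragments(rm_)
  if (length(frags) == 0L) stop("reference map has no fragments")
  kb <- frags / 1000
  row <- data.frame(enzyme = rm_$enzyme$name, stringsAsFactors = FALSE)
  for (w in windows) {
    stopifnot(length(w) == 2L, w[1L] <= w[2L])
    col <- sprintf("usable_pct_%g_%g", w[1L], w[2L])
    row[[col]] <- 100 * mean(kb >= w[1L] & kb <= w[2L])
  }
  row$avg_fragment_kb <- mean(kb)
  row$max_fragment_kb <- max(kb)
  row$n_fragments_gt_big <- sum(kb > big_threshold)
  row
}

#' Rank enzymes by usable-fragment percentage
#'
#' Stable descending sort on the usable percentage of one window; ties are
#' broken alphabetically by enzyme name. The top row is flagged as the
#' recommendation.
#'
#' @param rows data.frame of [fragment_stats()] rows (one per enzyme).
#' @param window `c(lo, hi)` in kb naming the ranking column, default
#'   `c(5, 20)`.
#' @return `rows` reordered best-first with a logical `recommended` column.
#' @export
rank_enzymes <- function(rows, window = c(5, 20)) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  col <- sprintf("usable_pct_%g_%g", window[1L], window[2L])
  if (!col %in% names(rows)) stop("no column '", col, "' in rows")
  ord <- order(-rows[[col]], rows$enzyme)
  out <- rows[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$recommended <- seq_len(nrow(out)) == 1L
  out
}

#' Digest a genome with a panel of enzymes and rank them
#'
#' Convenience wrapper: digests the same contigs with each enzyme, computes
#' [fragment_stats()] per enzyme, and ranks by the first window.
#'
#' @param contigs Output of [load_contigs()].
#' @param enzymes List of `om_enzyme` (default all built-ins).
#' @inheritParams fragment_stats
#' @return Ranked data.frame (see [rank_enzymes()]).
#' @export
enzyme_report <- function(contigs, enzymes = builtin_enzymes(),
                          windows = list(c(5, 20), c(6, 15), c(6, 12)),
                          big_threshold = 100) {
  rows <- do.call(rbind, lapply(enzymes, function(e)
    fragment_stats(digest_contigs(contigs, e), windows, big_threshold)))
  rank_enzymes(rows, windows[[1L]])
}
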