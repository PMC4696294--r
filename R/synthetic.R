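#' Generate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with a given GC content; a stand-in
#' reference for demonstrations and tests when no real genome is at hand.
#' Lowering GC thins out GC-rich recognition sites such as GGTACC, which is
#' how the bundled demo reaches realistic ~10 kb fragment sizes.
#'
#' @param length Sequence length (bp).
#' @param gc GC fraction in `[0, 1]` (default 0.36, which puts the GGTACC
#'   site density near one per 10 kb).
#' @param n_seqs Number of sequences (the length is split evenly).
#' @param seed Optional integer seed.
#' @return Named character vector of sequences, usable as `fasta_source` in
#'   [load_contigs()].
#' @export
random_genome <- function(length, gc = 0.36, n_seqs = 1L, seed = NULL) {
  stopifnot(length >= n_seqs, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  per <- diff(round(seq(0, length, length.out = n_seqs + 1L)))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(per, function(n)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(seqs) <- paste0("synth", seq_along(seqs))
  seqs
}

#' Generate a synthetic reference restriction map directly
#'
#' Draws per-contig fragment lengths i.i.d. exponential with a given mean
#' (floored at `min_frag`) and converts them to cut positions. This skips the
#' sequence level entirely and is the cheap way to build desk-scale references
#' with a realistic fragment-size distribution (a KpnI digest of the human
#' genome has a mean fragment near 10 kb).
#'
#' @param genome_size Total reference size (bp).
#' @param mean_frag Mean fragment length (bp), default 10000.
#' @param n_contigs Number of contigs (size split evenly), default 1.
#' @param min_frag Minimum fragment length (bp), default 200.
#' @param enzyme Enzyme to stamp on the map (metadata), default KpnI.
#' @param seed Optional integer seed.
#' @return An `om_refmap`.
#' @export
synthetic_refmap <- function(genome_size, mean_frag = 10000, n_contigs = 1L,
                             min_frag = 200, enzyme = builtin_enzymes("KpnI"),
                             seed = NULL) {
  stopifnot(genome_size >= n_contigs * mean_frag, mean_frag > min_frag)
  if (!is.null(seed)) set.seed(seed)
  per <- diff(round(seq(0, genome_size, length.out = n_contigs + 1L)))
  contigs <- list()
  for (k in seq_len(n_contigs)) {
    len <- as.integer(per[k])
    n_draw <- ceiling(len / mean_frag * 1.5) + 10L
    frags <- pmax(round(stats::rexp(n_draw, rate = 1 / mean_frag)), min_frag)
    pos <- cumsum(frags)
    cuts <- as.integer(pos[pos < len - min_frag])
    contigs[[paste0("synth", k)]] <- list(length = len, cuts = cuts)
  }
  refmap(enzyme, contigs)
}
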