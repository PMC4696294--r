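# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths (Biostrings matching, the C++ DP).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# sliding-window matcher: pattern IUPAC codes match their expansions; an N in
# the sequence matches nothing; returns 0-based cut positions
naive_scan <- function(sequence, enz) {
  s <- strsplit(toupper(sequence), "")[[1]]
  pats <- list(strsplit(enz$recognition, "")[[1]])
  offs <- enz$cut_offset
  rc_map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
  rc <- rev(unname(rc_map[pats[[1]]]))
  if (!identical(paste(rc, collapse = ""), enz$recognition)) {
    pats <- c(pats, list(rc))
    offs <- c(offs, length(rc) - enz$cut_offset)
  }
  cuts <- integer()
  L <- length(pats[[1]])
  for (pi in seq_along(pats)) {
    pat <- pats[[pi]]
    for (st in seq_len(length(s) - L + 1)) {
      win <- s[st:(st + L - 1)]
      ok <- all(vapply(seq_len(L), function(q)
        win[q] != "N" && win[q] %in% IUPAC_SETS[[pat[q]]], logical(1)))
      if (ok) cuts <- c(cuts, st - 1L + offs[pi])
    }
  }
  sort(unique(cuts))
}

# exhaustive enumeration of all monotone block matchings of a molecule
# against a reference fragment vector, under the same scoring model as the
# DP: returns the best total score (-Inf if no full-molecule matching exists)
brute_best_score <- function(mol, ref_frags, params) {
  m <- length(mol)
  R <- length(ref_frags) - 1L
  if (m < 2L || R < 1L) return(-Inf)
  X <- cumsum(c(0, mol))
  F <- cumsum(c(0, ref_frags))
  cv <- params$sizing_cv
  delta <- params$delta
  term_start <- function(i, j) {
    over <- max(0, X[i + 1] - ref_frags[j])
    -over^2 / (2 * (cv * ref_frags[j])^2) - params$false_penalty * (i - 1)
  }
  term_end <- function(i, j) {
    over <- max(0, (X[m + 1] - X[i + 1]) - ref_frags[j + 1])
    -over^2 / (2 * (cv * ref_frags[j + 1])^2) -
      params$false_penalty * (m - 1 - i)
  }
  block <- function(i0, j0, i1, j1) {
    dx <- X[i1 + 1] - X[i0 + 1]
    dr <- F[j1 + 1] - F[j0 + 1]
    -(dx - dr)^2 / (2 * (cv * dr)^2) -
      params$miss_penalty * (j1 - j0 - 1) -
      params$false_penalty * (i1 - i0 - 1)
  }
  best <- -Inf
  extend <- function(i, j, sc) {
    if (m - i <= delta)
      best <<- max(best, sc + term_end(i, j))
    for (di in 1:delta) for (dj in 1:delta) {
      i1 <- i + di; j1 <- j + dj
      if (i1 <= m - 1 && j1 <= R)
        extend(i1, j1, sc + block(i, j, i1, j1))
    }
  }
  for (i1 in 1:min(delta, m - 1)) for (j1 in 1:R)
    extend(i1, j1, term_start(i1, j1))
  best
}

# best DP score over all terminal candidates for one orientation
dp_best_score <- function(mol, ref_frags, params) {
  res <- omapr:::.dp_align(as.numeric(mol), as.numeric(ref_frags),
                           params$sizing_cv, params$miss_penalty,
                           params$false_penalty, params$delta)
  if (nrow(res$cand) == 0L) return(-Inf)
  max(res$cand[, "score"])
}

# minimal Rmap constructor for fixtures
make_rmap <- function(fragments, id = "m:1") {
  list(id = id, fragments = as.integer(fragments),
       length = sum(as.integer(fragments)), quality = NA_real_, truth = NULL)
}

# hand-built om_alignments object for estimator arithmetic fixtures
make_alignments <- function(rows, matched_ref_cuts = NULL) {
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 matched_ref_cuts = if (is.null(matched_ref_cuts))
                   vector("list", nrow(tab)) else matched_ref_cuts,
                 alignment_rate = sum(tab$unique) / nrow(tab)),
            class = "om_alignments")
}

aln_row <- function(id = "m:1", contig = "c1", matched = 0L, missed = 0L,
                    false = 0L, mol_length = 0L, unique = TRUE,
                    span = c(0L, 1L), score = 0) {
  data.frame(molecule_id = id, contig_id = contig, orientation = "+",
             ref_frag_start = span[1L], ref_frag_end = span[2L],
             matched_cuts = as.integer(matched),
             missed_ref_cuts = as.integer(missed),
             false_mol_cuts = as.integer(false), score = score,
             unique = unique, reason = if (unique) "ok" else "ambiguous",
             mol_length = as.integer(mol_length), stringsAsFactors = FALSE)
}
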