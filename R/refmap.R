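#' Load contigs from a FASTA file, splitting at assembly gaps
#'
#' Reads a (possibly gzipped) multi-sequence FASTA and splits every sequence
#' at each maximal run of at least `min_gap` consecutive `N` bases. The `N`
#' runs themselves are discarded. Soft-masked (lower-case) bases are treated
#' as their upper-case equivalents. Splitting at gaps matters for whole-genome
#' digestion: assembly gaps would otherwise surface as huge artefactual
#' restriction fragments.
#'
#' @param fasta_source Path to a FASTA file, or a named character vector of
#'   sequences (convenient for tests and simulation).
#' @param min_gap Minimum N-run length (bp) that splits a sequence. Default 1:
#'   every N breaks the sequence.
#' @return A list with one element per contig: `id`, `source` (sequence name,
#'   0-based half-open `start`/`end` in the input sequence), `length` (bp) and
#'   `seq` (upper-case character sequence).
#' @export
load_contigs <- function(fasta_source, min_gap = 1L) {
  min_gap <- as.integer(min_gap)
  if (is.na(min_gap) || min_gap < 1L) stop("min_gap must be >= 1")
  looks_like_path <- is.character(fasta_source) &&
    length(fasta_source) == 1L && !grepl("[\n>]", fasta_source) &&
    grepl("[./\\\\]", fasta_source)
  if (looks_like_path && !file.exists(fasta_source))
    stop("cannot read FASTA file: ", fasta_source)
  if (looks_like_path) {
    # readDNAStringSet drops invalid letters with a warning; promote both
    # warnings and errors to a parse error naming the offending position
    set <- withCallingHandlers(
      tryCatch(
        Biostrings::readDNAStringSet(fasta_source),
        error = function(e) .fasta_read_error(fasta_source, e)
      ),
      warning = function(w) {
        if (grepl("invalid", conditionMessage(w)))
          .fasta_read_error(fasta_source, w)
        invokeRestart("muffleWarning")
      }
    )
    seqs <- toupper(as.character(set))
    # drop FASTA description text after the first space in the name
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else if (is.character(fasta_source)) {
    seqs <- toupper(fasta_source)
    if (length(seqs) && is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("fasta_source must be a file path or a character vector of sequences")
  }
  if (length(seqs) == 0L || all(!nzchar(seqs))) stop("empty FASTA input")
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", seqs[[nm]])
    if (bad > 0L)
      stop("sequence '", nm, "' has a non-IUPAC character at position ", bad)
  }

  contigs <- list()
  for (nm in names(seqs)) {
    s <- toupper(seqs[[nm]])
    gaps <- gregexpr(sprintf("N{%d,}", min_gap), s, perl = TRUE)[[1]]
    if (gaps[1L] == -1L) {
      pieces <- data.frame(start = 0L, end = nchar(s))
    } else {
      gs <- as.integer(gaps) - 1L                       # 0-based gap starts
      ge <- gs + attr(gaps, "match.length")             # 0-based gap ends
      starts <- c(0L, ge)
      ends <- c(gs, nchar(s))
      pieces <- data.frame(start = starts, end = ends)
      pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
    }
    if (nrow(pieces) == 0L) next
    for (k in seq_len(nrow(pieces))) {
      id <- if (nrow(pieces) == 1L && pieces$start[k] == 0L) nm else
        sprintf("%s:%d-%d", nm, pieces$start[k], pieces$end[k])
      contigs[[length(contigs) + 1L]] <- list(
        id = id,
        source = list(seqname = nm, start = pieces$start[k], end = pieces$end[k]),
        length = pieces$end[k] - pieces$start[k],
        seq = substr(s, pieces$start[k] + 1L, pieces$end[k])
      )
    }
  }
  contigs
}

.fasta_read_error <- function(path, e) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  # locate the first offending character for a useful message
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(...) character())
  pos <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) { pos <- 0L; next }
    bad <- regexpr("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", ln)
    if (bad > 0L)
      stop("non-IUPAC character '", substr(ln, bad, bad), "' in ", path,
           " at line ", i, ", column ", bad)
    pos <- pos + nchar(ln)
  }
  stop("cannot parse FASTA file ", path, ": ", conditionMessage(e))
}

#' Scan a sequence for restriction cut positions
#'
#' Returns every cut position produced by the enzyme's recognition pattern on
#' the scanned strand: for a site starting at 0-based position `s`, the cut is
#' at `s + cut_offset`. IUPAC ambiguity codes in the pattern match their
#' expansions in the sequence, but an `N` in the *sequence* matches nothing.
#' Overlapping sites each contribute a cut; duplicate positions are collapsed.
#' Non-palindromic recognition sequences are additionally scanned on the
#' reverse strand and the two cut sets merged; all built-in enzymes are
#' palindromic, so a single-strand scan suffices for them.
#'
#' @param sequence Character sequence (IUPAC alphabet) or `DNAString`.
#' @param enzyme An `om_enzyme`.
#' @return Strictly increasing integer vector of 0-based cut positions (bp).
#' @examples
#' scan_sites("GGTACCGGTACC", builtin_enzymes("KpnI"))  # 5, 11
#' @export
scan_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "om_enzyme"))
  subject <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  pat <- Biostrings::DNAString(enzyme$recognition)
  L <- length(pat)
  cuts <- .strand_cuts(pat, subject, enzyme$cut_offset)
  if (!is_palindromic(enzyme)) {
    # reverse-strand site at forward 0-based start s cuts the forward strand
    # at s + (L - cut_offset)
    rc <- Biostrings::reverseComplement(pat)
    cuts <- c(cuts, .strand_cuts(rc, subject, L - enzyme$cut_offset))
  }
  sort(unique(cuts))
}

.strand_cuts <- function(pat, subject, offset) {
  m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  if (length(m) == 0L) return(integer())
  st <- BiocGenerics::start(m)
  # drop matches whose window touches an N in the subject: sequence N never
  # counts as a base, even against an N in the pattern
  has_n <- Biostrings::vcountPattern(
    "N", Biostrings::DNAStringSet(Biostrings::Views(subject, m))) > 0L
  st <- st[!has_n]
  as.integer(st - 1L + offset)
}

#' Digest contigs into a reference restriction map
#'
#' Runs [scan_sites()] on each contig and records per-contig cut positions and
#' fragment lengths. Cut positions are relative to the contig start, 0-based,
#' and exclusive of 0 and the contig length; fragment `i` covers
#' `[cut[i-1], cut[i])`, so the lengths always sum to the contig length.
#'
#' @param contigs Output of [load_contigs()] (each element must carry `seq`).
#' @param enzyme An `om_enzyme`.
#' @return An `om_refmap`: list with `enzyme` and `contigs`, the latter a
#'   named list of `list(length, cuts)`.
#' @export
digest_contigs <- function(contigs, enzyme) {
  stopifnot(inherits(enzyme, "om_enzyme"))
  if (length(contigs) == 0L) stop("no contigs to digest")
  out <- list()
  for (ct in contigs) {
    cuts <- scan_sites(ct$seq, enzyme)
    cuts <- cuts[cuts > 0L & cuts < ct$length]
    out[[ct$id]] <- list(length = as.integer(ct$length), cuts = as.integer(cuts))
  }
  refmap(enzyme, out)
}

#' Construct a reference map from explicit cut positions
#'
#' @param enzyme An `om_enzyme`.
#' @param contigs Named list of `list(length, cuts)` with 0-based cut
#'   positions strictly inside `(0, length)`.
#' @return An `om_refmap`.
#' @export
refmap <- function(enzyme, contigs) {
  stopifnot(inherits(enzyme, "om_enzyme"), length(contigs) >= 1L,
            !is.null(names(contigs)), all(nzchar(names(contigs))))
  for (nm in names(contigs)) {
    ct <- contigs[[nm]]
    len <- as.integer(ct$length)
    cuts <- as.integer(ct$cuts)
    if (is.na(len) || len <= 0L) stop("contig '", nm, "': length must be > 0")
    if (length(cuts) && (is.unsorted(cuts, strictly = TRUE) ||
                         cuts[1L] <= 0L || cuts[length(cuts)] >= len))
      stop("contig '", nm, "': cuts must be strictly increasing within (0, length)")
    contigs[[nm]] <- list(length = len, cuts = cuts)
  }
  structure(list(enzyme = enzyme, contigs = contigs), class = "om_refmap")
}

#' Fragment lengths of a reference map
#'
#' @param rm_ An `om_refmap`.
#' @param contig Optional contig id; default pools all contigs.
#' @return Integer vector of fragment lengths (bp). Per contig there are
#'   `length(cuts) + 1` fragments summing exactly to the contig length.
#' @export
refmap_fragments <- function(rm_, contig = NULL) {
  stopifnot(inherits(rm_, "om_refmap"))
  ids <- if (is.null(contig)) names(rm_$contigs) else contig
  unlist(lapply(ids, function(nm) {
    ct <- rm_$contigs[[nm]]
    if (is.null(ct)) stop("unknown contig '", nm, "'")
    diff(c(0L, ct$cuts, ct$length))
  }), use.names = FALSE)
}

#' @export
print.om_refmap <- function(x, ...) {
  n_cuts <- sum(vapply(x$contigs, function(ct) length(ct$cuts), integer(1)))
  total <- sum(vapply(x$contigs, function(ct) ct$length, integer(1)))
  cat("<om_refmap>", x$enzyme$name, "|", length(x$contigs), "contigs |",
      n_cuts, "cuts |", format(total, big.mark = ","), "bp\n")
  invisible(x)
}

#' Write / read a reference map as TSV
#'
#' The file starts with a header line
#' `#enzyme=<name> recognition=<seq> offset=<int>` followed by one row per
#' fragment: `contig_id`, `fragment_index` (0-based), `start_bp`, `end_bp`
#' (0-based half-open), `length_bp`. `read_refmap(write_refmap(x))`
#' reproduces `x` exactly.
#'
#' @param rm_ An `om_refmap`.
#' @param path Output / input file path.
#' @return `write_refmap` returns `path` invisibly; `read_refmap` returns an
#'   `om_refmap`.
#' @export
write_refmap <- function(rm_, path) {
  stopifnot(inherits(rm_, "om_refmap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#enzyme=%s recognition=%s offset=%d",
                     rm_$enzyme$name, rm_$enzyme$recognition,
                     rm_$enzyme$cut_offset), con)
  for (nm in names(rm_$contigs)) {
    ct <- rm_$contigs[[nm]]
    bounds <- c(0L, ct$cuts, ct$length)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d", nm, seq_along(starts) - 1L,
                       starts, ends, ends - starts), con)
  }
  invisible(path)
}

#' @rdname write_refmap
#' @export
read_refmap <- function(path) {
  if (!file.exists(path)) stop("reference map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty reference map file: ", path)
  hdr_at <- grep("^#enzyme=", lines)
  if (length(hdr_at) == 0L)
    stop("missing '#enzyme=' header in reference map file ", path)
  hdr <- lines[[hdr_at[1L]]]
  hm <- regmatches(hdr, regexec(
    "^#enzyme=(\\S+) recognition=(\\S+) offset=(\\d+)\\s*$", hdr))[[1]]
  if (length(hm) != 4L)
    stop("line ", hdr_at[1L], ": malformed reference map header: '", hdr, "'")
  enz <- enzyme(hm[2L], hm[3L], as.integer(hm[4L]))
  contigs <- list()
  expect_start <- list()
  any_row <- FALSE
  for (i in seq_along(lines)[-seq_len(hdr_at[1L])]) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 5L)
      stop("line ", i, ": expected 5 tab-separated fields, got ", length(parts))
    vals <- suppressWarnings(as.integer(parts[2:5]))
    if (anyNA(vals)) stop("line ", i, ": non-integer coordinate field")
    nm <- parts[1L]; start <- vals[2L]; end <- vals[3L]; lenf <- vals[4L]
    if (end <= start || lenf != end - start)
      stop("line ", i, ": inconsistent fragment coordinates (", start, ", ",
           end, ", length ", lenf, ")")
    prev <- expect_start[[nm]]
    if (is.null(prev)) {
      if (start != 0L) stop("line ", i, ": first fragment of '", nm,
                            "' must start at 0")
      contigs[[nm]] <- list(length = 0L, cuts = integer())
    } else if (start != prev) {
      stop("line ", i, ": fragments of '", nm,
           "' are not contiguous/monotone (expected start ", prev, ")")
    }
    if (start > 0L) contigs[[nm]]$cuts <- c(contigs[[nm]]$cuts, start)
    contigs[[nm]]$length <- end
    expect_start[[nm]] <- end
    any_row <- TRUE
  }
  if (!any_row) stop("reference map file has no fragment rows: ", path)
  refmap(enz, contigs)
}
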