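#' Restriction enzyme definition
#'
#' Construct a restriction enzyme object from its recognition sequence and the
#' cut offset on the scanned strand. The recognition sequence may contain IUPAC
#' ambiguity codes; the cut offset counts bases from the 5' start of the
#' recognition site to the phosphodiester bond that is cleaved, so KpnI
#' (GGTAC^C) has recognition `"GGTACC"` and `cut_offset = 5`.
#'
#' @param name Short enzyme label, e.g. `"KpnI"`.
#' @param recognition IUPAC nucleotide string, at least 4 bases.
#' @param cut_offset Integer offset in `[0, nchar(recognition)]`.
#' @return An object of class `om_enzyme` with fields `name`, `recognition`
#'   and `cut_offset`.
#' @examples
#' enzyme("KpnI", "GGTACC", 5)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  if (nchar(recognition) < 4L)
    stop("recognition sequence must be at least 4 bases, got '", recognition, "'")
  bad <- gsub("[ACGTRYSWKMBDHVN]", "", recognition)
  if (nzchar(bad))
    stop("recognition sequence contains non-IUPAC characters: '", bad, "'")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie in [0, ", nchar(recognition), "]")
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "om_enzyme"
  )
}

#' @export
print.om_enzyme <- function(x, ...) {
  site <- paste0(
    substr(x$recognition, 1L, x$cut_offset), "^",
    substr(x$recognition, x$cut_offset + 1L, nchar(x$recognition))
  )
  cat("<om_enzyme>", x$name, site, "\n")
  invisible(x)
}

#' Is a recognition sequence palindromic?
#'
#' A site is palindromic when it equals its own reverse complement (IUPAC
#' codes included). Palindromic sites need only be scanned on one strand.
#'
#' @param x An `om_enzyme`.
#' @return Logical scalar.
#' @export
is_palindromic <- function(x) {
  stopifnot(inherits(x, "om_enzyme"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x$recognition)))
  identical(rc, x$recognition)
}

#' Built-in restriction enzyme table
#'
#' Thirteen commonly used 6-cutters with their canonical recognition sites and
#' cut offsets (REBASE conventions). All have palindromic sites.
#'
#' @param name Optional enzyme name; if given, the single matching
#'   `om_enzyme` is returned (error if unknown).
#' @return A named list of `om_enzyme` objects, or one `om_enzyme` if `name`
#'   is supplied.
#' @examples
#' builtin_enzymes("KpnI")
#' names(builtin_enzymes())
#' @export
builtin_enzymes <- function(name = NULL) {
  tab <- list(
    AflII  = c("CTTAAG", 1L),
    BamHI  = c("GGATCC", 1L),
    BglII  = c("AGATCT", 1L),
    EcoRI  = c("GAATTC", 1L),
    KpnI   = c("GGTACC", 5L),
    MluI   = c("ACGCGT", 1L),
    NcoI   = c("CCATGG", 1L),
    NdeI   = c("CATATG", 2L),
    NheI   = c("GCTAGC", 1L),
    PvuII  = c("CAGCTG", 3L),
    SpeI   = c("ACTAGT", 1L),
    XbaI   = c("TCTAGA", 1L),
    XhoI   = c("CTCGAG", 1L)
  )
  enzymes <- lapply(names(tab), function(nm)
    enzyme(nm, tab[[nm]][1L], as.integer(tab[[nm]][2L])))
  names(enzymes) <- names(tab)
  if (is.null(name)) return(enzymes)
  if (!name %in% names(enzymes))
    stop("unknown built-in enzyme '", name, "'; known: ",
         paste(names(enzymes), collapse = ", "))
  enzymes[[name]]
}

#' Read enzyme definitions from a config file
#'
#' Each non-comment line holds `name recognition cut_offset`, whitespace
#' separated. Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the definitions file.
#' @return Named list of `om_enzyme` objects.
#' @export
read_enzymes <- function(path) {
  if (!file.exists(path)) stop("enzyme definition file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 3L)
      stop("line ", i, ": expected 'name recognition cut_offset', got '", ln, "'")
    off <- suppressWarnings(as.integer(parts[3L]))
    if (is.na(off)) stop("line ", i, ": cut_offset is not an integer: '", parts[3L], "'")
    e <- tryCatch(enzyme(parts[1L], parts[2L], off),
                  error = function(err) stop("line ", i, ": ", conditionMessage(err)))
    out[[e$name]] <- e
  }
  if (length(out) == 0L) stop("no enzyme definitions found in ", path)
  out
}
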