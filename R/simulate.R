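#' Single-molecule error model
#'
#' Parameters of the observation process that turns a stretch of the
#' reference restriction map into one molecule's observed fragment list:
#'
#' * partial digestion — each true site in the molecule is cut independently
#'   with probability `p_digest`;
#' * false (extra) cuts — random breakage and imaging artefacts add
#'   `Poisson(lambda_false * length / 100 kb)` spurious cuts at uniform
#'   positions, kept at least 100 bp away from existing cuts (closer pairs
#'   are unresolvable optically);
#' * small-fragment loss — each resulting fragment of at most
#'   `small_threshold` bp desorbs (its mass disappears from the molecule)
#'   with probability `p_small_loss`;
#' * sizing noise — each surviving fragment size is scaled by
#'   `Normal(1, sizing_cv)`, floored at 100 bp.
#'
#' Defaults are the rates measured on the GM12878 KpnI dataset: digestion
#' 0.66, 0.751 extra cuts per 100 kb; molecule lengths are truncated
#' exponential with minimum 150 kb, mean 285 kb, capped at 2 Mb (the optical
#' mapper only retains molecules of 150 kb to 2 Mb). The sizing CV and the
#' small-fragment loss probability are not measured quantities; 0.10 and 0.5
#' are configurable defaults.
#'
#' @param p_digest Per-site cut probability in `[0, 1]`.
#' @param lambda_false Expected false cuts per 100 kb of molecule.
#' @param sizing_cv Relative standard deviation of observed fragment size.
#' @param p_small_loss Loss probability for fragments `<= small_threshold`.
#' @param small_threshold Small-fragment threshold (bp).
#' @param min_len,mean_len,max_len Molecule length distribution (bp):
#'   truncated exponential above `min_len` with mean `mean_len`, clamped at
#'   `max_len`.
#' @return An `om_error_model` list.
#' @export
error_model <- function(p_digest = 0.66, lambda_false = 0.751,
                        sizing_cv = 0.10, p_small_loss = 0.5,
                        small_threshold = 2000L,
                        min_len = 150000L, mean_len = 285000L,
                        max_len = 2000000L) {
  stopifnot(p_digest >= 0, p_digest <= 1, lambda_false >= 0, sizing_cv >= 0,
            p_small_loss >= 0, p_small_loss <= 1, small_threshold > 0,
            min_len < mean_len, mean_len <= max_len)
  structure(list(p_digest = p_digest, lambda_false = lambda_false,
                 sizing_cv = sizing_cv, p_small_loss = p_small_loss,
                 small_threshold = as.integer(small_threshold),
                 min_len = as.integer(min_len), mean_len = as.integer(mean_len),
                 max_len = as.integer(max_len)),
            class = "om_error_model")
}

#' Simulate single-molecule Rmaps from a reference map
#'
#' Draws `n` molecules: a contig is picked with probability proportional to
#' its length, the start uniformly, the length from the truncated
#' exponential of the error model (clipped at the contig end), and the
#' orientation uniformly. The error channels are then applied in a fixed
#' order — digestion, false cuts, small-fragment loss, sizing noise — so that
#' the recorded truth is well defined. A window containing no retained cut
#' still yields a (single-fragment) molecule.
#'
#' @param rm_ An `om_refmap`.
#' @param model An `om_error_model`.
#' @param n Number of molecules.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param id_prefix Molecule id prefix; ids are `<prefix>:<k>` so the prefix
#'   doubles as a group (MapCard-style) key in QC reports.
#' @return List of Rmaps; each is `list(id, fragments, length, quality,
#'   truth)` where `truth` records contig, 0-based start/end, orientation,
#'   total and retained true cut indices (1-based into the contig's cut
#'   vector), false-cut positions (bp relative to molecule start, forward
#'   frame) and the number of lost small fragments.
#' @export
sample_molecules <- function(rm_, model = error_model(), n, seed = 1L,
                             id_prefix = "mol") {
  stopifnot(inherits(rm_, "om_refmap"), inherits(model, "om_error_model"),
            n >= 1L)
  clens <- vapply(rm_$contigs, function(ct) as.numeric(ct$length), numeric(1))
  if (sum(clens) < model$mean_len)
    stop("reference total length is below the molecule mean length")
  set.seed(as.integer(seed))
  ids <- names(rm_$contigs)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    nm <- if (length(ids) == 1L) ids else sample(ids, 1L, prob = clens)
    ct <- rm_$contigs[[nm]]
    start <- floor(stats::runif(1) * ct$length)
    len <- model$min_len +
      stats::rexp(1, rate = 1 / (model$mean_len - model$min_len))
    len <- min(len, model$max_len)
    end <- min(start + round(len), ct$length)
    len <- end - start
    orient <- if (stats::runif(1) < 0.5) "+" else "-"

    in_window <- which(ct$cuts > start & ct$cuts < end)
    kept <- in_window[stats::runif(length(in_window)) < model$p_digest]
    rel <- ct$cuts[kept] - start

    n_false <- stats::rpois(1, model$lambda_false * len / 1e5)
    false_pos <- numeric(0)
    if (n_false > 0L && len > 2L) {
      existing <- rel
      for (f in seq_len(n_false)) {
        for (try in 1:50) {
          p <- 1 + floor(stats::runif(1) * (len - 1))
          if (!length(existing) || min(abs(existing - p)) >= 100) {
            false_pos <- c(false_pos, p)
            existing <- c(existing, p)
            break
          }
        }
      }
    }

    bounds <- c(0, sort(c(rel, false_pos)), len)
    frags <- diff(bounds)

    lost <- frags <= model$small_threshold &
      stats::runif(length(frags)) < model$p_small_loss
    if (all(lost)) lost[which.max(frags)] <- FALSE
    n_lost <- sum(lost)
    frags <- frags[!lost]

    if (model$sizing_cv > 0) {
      frags <- frags * stats::rnorm(length(frags), 1, model$sizing_cv)
      frags <- pmax(frags, 100)   # observed sizes cannot collapse below 100 bp
    }
    frags <- as.integer(round(frags))
    if (orient == "-") frags <- rev(frags)

    out[[k]] <- list(
      id = sprintf("%s:%d", id_prefix, k),
      fragments = frags,
      length = sum(frags),
      quality = NA_real_,
      truth = list(contig = nm, start = as.integer(start),
                   end = as.integer(end), orientation = orient,
                   n_sites = length(in_window),
                   true_cut_idx = as.integer(kept),
                   false_pos = as.integer(sort(false_pos)),
                   n_lost_small = as.integer(n_lost))
    )
  }
  out
}

#' Molecule retention filter
#'
#' The optical-map inclusion rule of the study: filter (r) keeps molecules
#' with at least 10 fragments and at least 150 kb total length; the stricter
#' filter (s) uses 12 fragments and 250 kb. Both thresholds are inclusive.
#'
#' @param min_fragments Minimum fragment count (>= 1).
#' @param min_length Minimum total molecule length (bp).
#' @return An `om_filter` list.
#' @export
filter_spec <- function(min_fragments = 10L, min_length = 150000L) {
  stopifnot(min_fragments >= 1L, min_length >= 0)
  structure(list(min_fragments = as.integer(min_fragments),
                 min_length = as.integer(min_length)),
            class = "om_filter")
}

#' Apply a retention filter to a set of Rmaps
#'
#' @param rmaps List of Rmaps (see [sample_molecules()]).
#' @param filter An `om_filter`.
#' @return `list(rmaps, n_input, n_retained, n_discarded)`.
#' @export
apply_filter <- function(rmaps, filter = filter_spec()) {
  stopifnot(inherits(filter, "om_filter"))
  keep <- vapply(rmaps, function(r)
    length(r$fragments) >= filter$min_fragments &&
      r$length >= filter$min_length, logical(1))
  list(rmaps = rmaps[keep], n_input = length(rmaps),
       n_retained = sum(keep), n_discarded = sum(!keep))
}

#' Write / read Rmaps as TSV
#'
#' Header `#rmaps v1 enzyme=<name>`; one row per molecule:
#' `molecule_id`, `n_fragments`, `total_len_bp`, comma-separated fragment
#' sizes (bp), and an optional fifth column holding the simulation truth
#' block as JSON. The round trip is exact, truth included.
#'
#' @param rmaps List of Rmaps.
#' @param path File path.
#' @param enzyme_name Enzyme label for the header.
#' @param extra_header Optional additional `#`-prefixed header lines.
#' @return `write_rmaps` returns `path` invisibly; `read_rmaps` returns the
#'   list of Rmaps (with `truth = NULL` when the column is absent).
#' @export
write_rmaps <- function(rmaps, path, enzyme_name = "NA", extra_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#rmaps v1 enzyme=%s", enzyme_name), con)
  if (!is.null(extra_header)) writeLines(extra_header, con)
  for (r in rmaps) {
    base <- sprintf("%s\t%d\t%d\t%s", r$id, length(r$fragments),
                    sum(r$fragments),
                    paste(format(r$fragments, scientific = FALSE, trim = TRUE),
                          collapse = ","))
    if (!is.null(r$truth))
      base <- paste0(base, "\t",
                     jsonlite::toJSON(r$truth, auto_unbox = TRUE, digits = NA))
    writeLines(base, con)
  }
  invisible(path)
}

#' @rdname write_rmaps
#' @export
read_rmaps <- function(path) {
  if (!file.exists(path)) stop("Rmap file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#rmaps v1", lines[[1L]]))
    stop("line 1: missing '#rmaps v1' header in ", path)
  out <- list()
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 4L || length(parts) > 5L)
      stop("line ", i, ": expected 4 or 5 tab-separated fields, got ",
           length(parts))
    frags <- suppressWarnings(as.integer(strsplit(parts[4L], ",", fixed = TRUE)[[1]]))
    if (length(frags) == 0L || anyNA(frags))
      stop("line ", i, ": malformed fragment size list")
    if (any(frags <= 0L))
      stop("line ", i, ": fragment sizes must be > 0")
    n <- suppressWarnings(as.integer(parts[2L]))
    tot <- suppressWarnings(as.integer(parts[3L]))
    if (is.na(n) || n != length(frags))
      stop("line ", i, ": n_fragments (", parts[2L],
           ") does not match the size list (", length(frags), ")")
    if (is.na(tot) || tot != sum(frags))
      stop("line ", i, ": total_len_bp (", parts[3L],
           ") does not match the size list sum (", sum(frags), ")")
    truth <- NULL
    if (length(parts) == 5L) {
      truth <- tryCatch(jsonlite::fromJSON(parts[5L]),
                        error = function(e) stop("line ", i,
                                                 ": malformed truth JSON"))
      for (f in c("start", "end", "n_sites", "true_cut_idx", "false_pos",
                  "n_lost_small"))
        if (!is.null(truth[[f]])) truth[[f]] <- as.integer(truth[[f]])
    }
    out[[length(out) + 1L]] <- list(id = parts[1L], fragments = frags,
                                    length = sum(frags), quality = NA_real_,
                                    truth = truth)
  }
  out
}
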