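# Design of minimal coverage sequences: the shortest DNA string containing
# each required NYYN context exactly once, with no pyrimidine run longer
# than a set maximum, found by randomized merging of tetramers that share
# identical ends.

#' Constraints for coverage-sequence design
#'
#' @param max_pyrimidine_run Longest pyrimidine run allowed in the designed
#'   sequence. Must be at least 2 (a dipyrimidine). Default 4, which keeps
#'   cleavage bands resolvable by preventing long ladders of adjacent sites.
#' @param required_contexts Character vector of NYYN tetramers the sequence
#'   must contain. Defaults to all 64.
#' @param exact_coverage If `TRUE` (default), each required context must
#'   appear exactly once and no unrequested NYYN context may appear.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(max_pyrimidine_run = 4L,
                               required_contexts = nyyn_contexts()$context,
                               exact_coverage = TRUE) {
  max_pyrimidine_run <- as.integer(max_pyrimidine_run)
  if (is.na(max_pyrimidine_run) || max_pyrimidine_run < 2L)
    stop("`max_pyrimidine_run` must be an integer >= 2")
  required_contexts <- toupper(required_contexts)
  if (!length(required_contexts))
    stop("`required_contexts` must be non-empty")
  if (anyDuplicated(required_contexts))
    stop("`required_contexts` contains duplicates")
  context_class(required_contexts)  # validates NYYN form
  structure(list(max_pyrimidine_run = max_pyrimidine_run,
                 required_contexts = required_contexts,
                 exact_coverage = isTRUE(exact_coverage)),
            class = "design_constraints")
}

#' @export
print.design_constraints <- function(x, ...) {
  cat(sprintf("design_constraints: %d required context(s), max pyrimidine run %d, %s coverage\n",
              length(x$required_contexts), x$max_pyrimidine_run,
              if (x$exact_coverage) "exact" else "at-least-once"))
  invisible(x)
}

# Internal run length of a context: the pyrimidine run it forces when placed.
.context_internal_run <- function(context) {
  vapply(context, function(ctx) max(.pyrimidine_runs(ctx)), integer(1),
         USE.NAMES = FALSE)
}

#' Counting lower bound on the core length
#'
#' Each required YY occurrence must live inside a maximal pyrimidine tract no
#' longer than `max_pyrimidine_run`, and every tract needs purine neighbours
#' on both sides (adjacent tracts can share one). A tract of length L holds
#' L - 1 dipyrimidine sites: its first site has class RYYY (RYYR when L = 2),
#' its last YYYR, and interior sites YYYY, so YYYY contexts force tracts of
#' length >= 4. Minimizing pyrimidines plus shared purine separators gives
#' the bound: for the full 64-context set with `max_pyrimidine_run = 4` it is
#' 16 x 4 + 16 x 4 + 1 = 129 nucleotides (16 RYYR tracts of length 2 plus 16
#' tracts of length 4 carrying all RYYY, YYYY and YYYR contexts).
#'
#' @param constraints A [design_constraints()] object.
#' @return Integer lower bound on the length of any core satisfying the
#'   constraints.
#' @examples
#' minimal_length_bound(design_constraints())               # 129
#' minimal_length_bound(design_constraints(required_contexts = "ATTA"))  # 4
#' @export
minimal_length_bound <- function(constraints) {
  stopifnot(inherits(constraints, "design_constraints"))
  m <- constraints$max_pyrimidine_run
  ctx <- constraints$required_contexts
  runs <- .context_internal_run(ctx)
  if (any(runs > m))
    stop("infeasible: context(s) ",
         paste(ctx[runs > m], collapse = ", "),
         " contain a pyrimidine run longer than max_pyrimidine_run = ", m)
  kl <- context_class(ctx)
  n_ryyr <- sum(kl == "RYYR")
  n_ryyy <- sum(kl == "RYYY")
  n_yyyr <- sum(kl == "YYYR")
  n_yyyy <- sum(kl == "YYYY")

  # Long tracts (length >= 4) supply the YYYY interiors; each also supplies
  # one RYYY and one YYYR. A tract of length L has L - 3 interior sites.
  k4 <- if (n_yyyy > 0L) ceiling(n_yyyy / (m - 3L)) else 0L
  py4 <- n_yyyy + 3L * k4
  # Leftover RYYY / YYYR demand pairs up in length-3 tracts.
  k3 <- max(n_ryyy - k4, n_yyyr - k4, 0L)
  py3 <- 3L * k3
  # Each RYYR needs its own length-2 tract.
  k2 <- n_ryyr
  py2 <- 2L * k2

  tracts <- k4 + k3 + k2
  as.integer(py4 + py3 + py2 + tracts + 1L)
}

# One randomized merge run. Fragments start as the required tetramers and
# are joined pairwise where a suffix of one equals a prefix of the other
# (overlap 1-3 nt). A merge is rejected if it lengthens any pyrimidine run
# beyond the maximum or creates a new NYYN window (in exact-coverage mode a
# new window is necessarily a duplicate or an unrequested context, because
# every required context is already present among the fragments).
#
# Candidate ordering matters for completion: fragments whose ends are
# pyrimidines (YYYY tetramers, part-built tracts) can only be absorbed via
# high-overlap merges while suitable partners remain, so candidates are
# restricted to merges involving the fragments with the most pyrimidine
# ends, ranked by overlap then combined fragment length, random tie-break.
.merge_run <- function(req, max_run, exact) {
  frags <- req
  counts <- vapply(frags, function(s) nrow(.nyyn_windows(s)), integer(1),
                   USE.NAMES = FALSE)
  py_ends <- function(s)
    is_pyrimidine(substr(s, 1L, 1L)) + is_pyrimidine(substr(s, nchar(s), nchar(s)))
  repeat {
    nf <- length(frags)
    if (nf == 1L) return(list(core = frags, fragments = frags))
    pe <- vapply(frags, py_ends, 0L, USE.NAMES = FALSE)
    focus <- pe == max(pe)
    merged <- FALSE
    for (ov in 3:1) {
      suf <- substr(frags, nchar(frags) - ov + 1L, nchar(frags))
      pre <- substr(frags, 1L, ov)
      ok <- outer(suf, pre, "==")
      diag(ok) <- FALSE
      ok <- ok & outer(focus, focus, "|")
      cand <- which(ok, arr.ind = TRUE)
      if (!nrow(cand)) next
      comb_len <- nchar(frags)[cand[, 1L]] + nchar(frags)[cand[, 2L]]
      ord <- order(-comb_len, sample.int(nrow(cand)))
      cand <- cand[ord, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        m <- paste0(frags[i], substr(frags[j], ov + 1L, nchar(frags[j])))
        if (.max_pyrimidine_run(m) > max_run) next
        new_count <- nrow(.nyyn_windows(m))
        if (exact && new_count != counts[i] + counts[j]) next
        if (!exact && new_count < counts[i] + counts[j]) next
        frags <- c(frags[-c(i, j)], m)
        counts <- c(counts[-c(i, j)], new_count)
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) return(list(core = NA_character_, fragments = frags))
  }
}

#' Design a minimal coverage sequence by randomized overlap merging
#'
#' Starting from one copy of each required tetramer, fragments are merged
#' pairwise wherever a suffix of one equals a prefix of the other (overlap
#' 1-3 nt); merges that would exceed the pyrimidine-run limit or duplicate a
#' required context are rejected. Each restart reshuffles the merge order
#' (restart r seeds the RNG with `seed + r`), and the shortest completed
#' core is kept, with ties broken by the lexicographically smallest string.
#'
#' @param constraints A [design_constraints()] object.
#' @param seed Integer base seed; the run is fully reproducible given
#'   `seed` and `restarts`.
#' @param restarts Number of randomized merge runs to attempt.
#' @param stop_at_bound If `TRUE` (default), stop restarting as soon as a
#'   core attains [minimal_length_bound()], which no sequence can beat; the
#'   lexicographic tie-break then applies to the restarts actually executed.
#' @return A `coverage_sequence` object: list with elements `core` (the DNA
#'   string), `sites` (site annotations, see [annotate_sites()]), `flank5`,
#'   `flank3` (empty until [pad_sequence()]), `seed`, `restarts`,
#'   `restart_lengths` (per-restart core length, `NA` for runs that stalled),
#'   and `constraints`.
#' @examples
#' dc <- design_constraints(required_contexts = c("ATTA", "ATCA", "ACTA", "ACCA"))
#' d <- design_coverage_sequence(dc, seed = 1, restarts = 50)
#' nchar(d$core)  # 13, the counting bound
#' @export
design_coverage_sequence <- function(constraints, seed = 1L, restarts = 100L,
                                     stop_at_bound = TRUE) {
  stopifnot(inherits(constraints, "design_constraints"))
  seed <- as.integer(seed)
  restarts <- as.integer(restarts)
  if (is.na(restarts) || restarts < 1L) stop("`restarts` must be >= 1")
  bound <- minimal_length_bound(constraints)  # also checks feasibility

  best <- NULL
  best_partial <- NULL
  lengths <- rep(NA_integer_, restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    run <- .merge_run(constraints$required_contexts,
                      constraints$max_pyrimidine_run,
                      constraints$exact_coverage)
    if (!is.na(run$core)) {
      rep_ok <- verify_coverage(run$core, constraints)$pass
      if (rep_ok) {
        lengths[r] <- nchar(run$core)
        if (is.null(best) ||
            nchar(run$core) < nchar(best) ||
            (nchar(run$core) == nchar(best) && run$core < best))
          best <- run$core
        if (stop_at_bound && nchar(best) == bound) {
          lengths <- lengths[seq_len(r)]
          break
        }
      }
    }
    if (is.na(lengths[r]) &&
        (is.null(best_partial) || length(run$fragments) < length(best_partial)))
      best_partial <- run$fragments
  }
  if (is.null(best)) {
    stop(sprintf(paste0(
      "no valid coverage sequence found in %d restart(s); best partial ",
      "assembly has %d unmerged fragment(s): %s"),
      restarts, length(best_partial),
      paste(utils::head(best_partial, 8L), collapse = ", ")))
  }
  structure(list(core = best,
                 sites = annotate_sites(best),
                 flank5 = "",
                 flank3 = "",
                 seed = seed,
                 restarts = restarts,
                 restart_lengths = lengths,
                 constraints = constraints),
            class = "coverage_sequence")
}

#' @export
print.coverage_sequence <- function(x, ...) {
  cat(sprintf("coverage_sequence: %d-nt core, %d annotated sites (seed %d)\n",
              nchar(x$core), nrow(x$sites), x$seed))
  if (nzchar(x$flank5) || nzchar(x$flank3))
    cat(sprintf("  padded: %d-nt 5' flank, %d-nt 3' flank, total %d nt\n",
                nchar(x$flank5), nchar(x$flank3),
                nchar(x$flank5) + nchar(x$core) + nchar(x$flank3)))
  cat("  ", x$core, "\n", sep = "")
  invisible(x)
}

#' Verify a sequence against coverage-design constraints
#'
#' Scans all NYYN windows of `seq` and compares them, as a multiset, with the
#' required contexts; also reports the maximal pyrimidine-run length and the
#' tract census (counts of maximal pyrimidine runs by length). For a valid
#' full-set 129-mer the census is 16 runs of length 2 and 16 of length 4.
#'
#' @param seq DNA string over {A,C,G,T}.
#' @param constraints A [design_constraints()] object.
#' @return A `coverage_report`: list with `pass`, `missing`, `duplicated`,
#'   `unrequested` (contexts found but not required; only fails the check in
#'   exact mode), `terminal_yy` (positions of YY occurrences lacking a full
#'   NYYN window), `max_pyrimidine_run`, `tract_census` (named integer
#'   vector), and `n_sites`.
#' @export
verify_coverage <- function(seq, constraints) {
  .check_dna(seq)
  stopifnot(inherits(constraints, "design_constraints"))
  win <- .nyyn_windows(seq)
  found <- win$context
  req <- constraints$required_contexts
  tab <- table(found)
  missing <- setdiff(req, found)
  dup <- names(tab)[tab > 1L]
  unreq <- setdiff(found, req)
  yy_all <- .yy_positions(seq)
  terminal <- setdiff(yy_all, win$position)
  runs <- .pyrimidine_runs(seq)
  census <- table(factor(runs, levels = sort(unique(runs))))
  census <- stats::setNames(as.integer(census), names(census))
  maxrun <- if (length(runs)) max(runs) else 0L
  pass <- length(missing) == 0L &&
    maxrun <= constraints$max_pyrimidine_run &&
    (!constraints$exact_coverage ||
       (length(dup) == 0L && length(unreq) == 0L && length(terminal) == 0L))
  structure(list(pass = pass,
                 missing = missing,
                 duplicated = dup,
                 unrequested = unreq,
                 terminal_yy = terminal,
                 max_pyrimidine_run = maxrun,
                 tract_census = census,
                 n_sites = nrow(win)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  sites: %d; max pyrimidine run: %d\n", x$n_sites,
              x$max_pyrimidine_run))
  cat("  tract census:",
      paste(sprintf("%s:%d", names(x$tract_census), x$tract_census),
            collapse = " "), "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = " "), "\n")
  if (length(x$duplicated)) cat("  duplicated:", paste(x$duplicated, collapse = " "), "\n")
  if (length(x$unrequested)) cat("  unrequested:", paste(x$unrequested, collapse = " "), "\n")
  if (length(x$terminal_yy)) cat("  terminal YY at:", paste(x$terminal_yy, collapse = " "), "\n")
  invisible(x)
}

#' Annotate all dipyrimidine sites of a sequence
#'
#' One annotation per YY dinucleotide. The site position is the 1-based
#' index of the 5' pyrimidine within the sequence, and the site name is
#' `<context>-<position>` (e.g. `"TTTA-75"`).
#'
#' @param seq DNA string (a core sequence; positions are relative to it).
#' @param require_full_context If `TRUE` (default), a YY at the first or
#'   last possible position, whose NYYN window is undefined, is an error;
#'   if `FALSE` such occurrences are silently dropped.
#' @return Data frame with columns `name`, `context`, `position`, `klass`.
#' @examples
#' annotate_sites("ATTA")     # one site, ATTA-2
#' annotate_sites("GTTTTA")   # GTTT-2, TTTT-3, TTTA-4
#' @export
annotate_sites <- function(seq, require_full_context = TRUE) {
  .check_dna(seq)
  yy <- .yy_positions(seq)
  win <- .nyyn_windows(seq)
  if (require_full_context && length(setdiff(yy, win$position)))
    stop("YY dinucleotide at position ",
         paste(setdiff(yy, win$position), collapse = ", "),
         " lacks a full NYYN window (sequence terminus)")
  if (!nrow(win))
    return(data.frame(name = character(0), context = character(0),
                      position = integer(0), klass = character(0),
                      stringsAsFactors = FALSE))
  data.frame(name = paste0(win$context, "-", win$position),
             context = win$context,
             position = win$position,
             klass = context_class(win$context),
             stringsAsFactors = FALSE)
}

# Sample a dipyrimidine-free flank of given length. Bases are drawn
# uniformly from the alphabet, restricted to purines wherever a pyrimidine
# would sit next to another pyrimidine (within the flank or at the core
# junction).
.sample_flank <- function(len, left_neighbor_py = FALSE, right_neighbor_py = FALSE) {
  if (len == 0L) return("")
  out <- character(len)
  prev_py <- left_neighbor_py
  for (i in seq_len(len)) {
    pool <- if (prev_py) PURINES else c("A", "C", "G", "T")
    if (i == len && right_neighbor_py) pool <- intersect(pool, PURINES)
    out[i] <- sample(pool, 1L)
    prev_py <- is_pyrimidine(out[i])
  }
  paste(out, collapse = "")
}

#' Pad a designed core with dipyrimidine-free flanks
#'
#' Adds random flanks containing no YY dinucleotide to both ends, without
#' creating a YY across either flank-core junction (a flank base adjacent to
#' a pyrimidine core terminus is forced to be a purine). Padding a 129-mer
#' core with 10-mers gives a 149-mer; this emulates buffering the probe so
#' that end effects stay outside the analyzed sites. Site positions remain
#' indexed within the core.
#'
#' @param design A `coverage_sequence` object.
#' @param flank_length Length of each flank (default 10; 0 returns the
#'   design unchanged).
#' @param seed Integer seed; flanks are deterministic given the seed.
#' @return The `coverage_sequence` with `flank5`/`flank3` filled in.
#' @export
pad_sequence <- function(design, flank_length = 10L, seed = 1L) {
  stopifnot(inherits(design, "coverage_sequence"))
  flank_length <- as.integer(flank_length)
  if (is.na(flank_length) || flank_length < 0L)
    stop("`flank_length` must be a non-negative integer")
  if (flank_length == 0L) return(design)
  set.seed(as.integer(seed))
  n <- nchar(design$core)
  first_py <- is_pyrimidine(substr(design$core, 1L, 1L))
  last_py <- is_pyrimidine(substr(design$core, n, n))
  design$flank5 <- .sample_flank(flank_length, right_neighbor_py = first_py)
  design$flank3 <- .sample_flank(flank_length, left_neighbor_py = last_py)
  design
}

#' Full padded sequence of a design
#'
#' @param design A `coverage_sequence` object.
#' @return The concatenated `flank5 + core + flank3` string.
#' @export
full_sequence <- function(design) {
  stopifnot(inherits(design, "coverage_sequence"))
  paste0(design$flank5, design$core, design$flank3)
}
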