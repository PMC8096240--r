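# Tetranucleotide (NYYN) context utilities.
#
# A CPD can form at any dipyrimidine (YY = C or T, twice); its photochemical
# environment is summarized by the flanking bases, giving 4 x 2 x 2 x 4 = 64
# NYYN contexts. Contexts are classified by whether the flanks are purine (R)
# or pyrimidine (Y): RYYR, RYYY, YYYR or YYYY.

PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")
DIPYRIMIDINES <- c("TT", "TC", "CT", "CC")

is_pyrimidine <- function(base) base == "C" | base == "T"

.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

.check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single DNA string")
  if (grepl("[^ACGT]", seq))
    stop("`seq` contains characters outside {A,C,G,T}")
  invisible(seq)
}

#' Enumerate all NYYN tetramer contexts
#'
#' Every 4-mer over {A,C,G,T} whose two central bases are pyrimidines; there
#' are exactly 64. The class records whether the flanking bases are purines
#' (R) or pyrimidines (Y).
#'
#' @return A data frame with columns `context` (4-character string) and
#'   `klass` (one of `"RYYR"`, `"RYYY"`, `"YYYR"`, `"YYYY"`), 64 rows.
#' @examples
#' ctx <- nyyn_contexts()
#' nrow(ctx)              # 64
#' table(ctx$klass)       # 16 of each class
#' @export
nyyn_contexts <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(n3 = b, y2 = PYRIMIDINES, y1 = PYRIMIDINES, n5 = b,
                      stringsAsFactors = FALSE)
  context <- paste0(grid$n5, grid$y1, grid$y2, grid$n3)
  context <- sort(unique(context))
  data.frame(context = context, klass = context_class(context),
             stringsAsFactors = FALSE)
}

#' Classify NYYN contexts by their flanking bases
#'
#' @param context Character vector of 4-mers with central dipyrimidines.
#' @return Character vector over `"RYYR"`, `"RYYY"`, `"YYYR"`, `"YYYY"`.
#' @export
context_class <- function(context) {
  stopifnot(is.character(context), all(nchar(context) == 4L))
  mid1 <- substr(context, 2, 2)
  mid2 <- substr(context, 3, 3)
  if (!all(is_pyrimidine(mid1) & is_pyrimidine(mid2)))
    stop("central two bases of an NYYN context must be pyrimidines")
  five  <- ifelse(is_pyrimidine(substr(context, 1, 1)), "Y", "R")
  three <- ifelse(is_pyrimidine(substr(context, 4, 4)), "Y", "R")
  paste0(five, "YY", three)
}

# Positions (1-based index of the 5' pyrimidine) of all YY dinucleotides,
# including those at the sequence termini that lack a full NYYN window.
.yy_positions <- function(seq) {
  ch <- .chars(seq)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  py <- is_pyrimidine(ch)
  which(py[-n] & py[-1L])
}

# Full NYYN windows: YY occurrences with at least one base on each side.
.nyyn_windows <- function(seq) {
  pos <- .yy_positions(seq)
  pos <- pos[pos >= 2L & pos + 2L <= nchar(seq)]
  if (!length(pos))
    return(data.frame(position = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  data.frame(position = pos,
             context = substring(seq, pos - 1L, pos + 2L),
             stringsAsFactors = FALSE)
}

# Lengths of maximal pyrimidine runs, as an integer vector (one per run).
.pyrimidine_runs <- function(seq) {
  ch <- .chars(seq)
  if (!length(ch)) return(integer(0))
  r <- rle(is_pyrimidine(ch))
  r$lengths[r$values]
}

.max_pyrimidine_run <- function(seq) {
  runs <- .pyrimidine_runs(seq)
  if (length(runs)) max(runs) else 0L
}
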