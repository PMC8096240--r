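# Flanking-context analyses of per-site CPD percentage tables:
# dipyrimidine totals and ratios, NYYN heatmaps with marginals, fold
# ranges, flanking-class summaries, pyrimidine-tract statistics and
# between-condition correlations.

# Percentage column: site_frequency_table uses mean_pct; raw per-replicate
# tables use pct.
.pct_col <- function(table) {
  if ("mean_pct" %in% names(table)) return(table$mean_pct)
  if ("pct" %in% names(table)) return(table$pct)
  stop("table has neither a `mean_pct` nor a `pct` column")
}

.check_site_table <- function(table, n_required = NULL) {
  stopifnot(is.data.frame(table), "context" %in% names(table))
  if (!is.null(n_required) && nrow(table) != n_required)
    stop(sprintf("expected a %d-site table, got %d sites", n_required,
                 nrow(table)))
  invisible(table)
}

#' Total CPD percentage per dipyrimidine type
#'
#' @param table A 64-site frequency table (e.g. from
#'   [quantify_experiment()]).
#' @return Named numeric vector `c(TT=, TC=, CT=, CC=)` summing to 100.
#' @export
dipyrimidine_totals <- function(table) {
  .check_site_table(table, 64L)
  pct <- .pct_col(table)
  dipy <- substr(table$context, 2, 3)
  vapply(DIPYRIMIDINES, function(d) sum(pct[dipy == d]), numeric(1))
}

#' Ratio between two dipyrimidine totals
#'
#' @param totals Named totals from [dipyrimidine_totals()] (or any named
#'   numeric vector of percentages).
#' @param numerator,denominator Dipyrimidine names (e.g. `"TT"`, `"TC"`).
#' @return The ratio rounded to 2 decimals, e.g. totals 44 and 25 give
#'   1.76.
#' @export
dipyrimidine_ratio <- function(totals, numerator = "TT", denominator = "TC") {
  num <- totals[[numerator]]
  den <- totals[[denominator]]
  if (den == 0) stop("denominator total is zero")
  round(num / den, 2L)
}

#' Fold range of per-site CPD percentages
#'
#' @param table A site frequency table.
#' @return List with `max_site`, `min_site` (site names when a `name`
#'   column exists, positions otherwise), `max_pct`, `min_pct` and `fold`
#'   (max/min, rounded to 1 decimal; 6.0% over 0.28% gives 21.4).
#' @export
fold_range <- function(table) {
  pct <- .pct_col(table)
  if (min(pct) <= 0) stop("minimum site percentage is zero; fold undefined")
  lab <- if ("name" %in% names(table)) table$name else table$position
  i_max <- which.max(pct)
  i_min <- which.min(pct)
  list(max_site = lab[i_max], min_site = lab[i_min],
       max_pct = pct[i_max], min_pct = pct[i_min],
       fold = round(pct[i_max] / pct[i_min], 1L))
}

#' 4 x 4 flanking-base heatmap for one dipyrimidine
#'
#' Cell (r, c) holds the percentage of the context `r + YY + c`; rows are
#' the 5' base and columns the 3' base, in order A, C, G, T.
#'
#' @param table A 64-site frequency table.
#' @param dipyrimidine One of `"TT"`, `"TC"`, `"CT"`, `"CC"`.
#' @return A `context_heatmap`: the 4 x 4 matrix with attributes
#'   `row_marginals`, `col_marginals`, `dipyrimidine` and
#'   `dipyrimidine_total`.
#' @export
context_heatmap <- function(table, dipyrimidine = c("TT", "TC", "CT", "CC")) {
  dipyrimidine <- match.arg(dipyrimidine)
  .check_site_table(table, 64L)
  pct <- .pct_col(table)
  keep <- substr(table$context, 2, 3) == dipyrimidine
  ctx <- table$context[keep]
  val <- pct[keep]
  b <- c("A", "C", "G", "T")
  m <- matrix(NA_real_, 4, 4, dimnames = list(five_prime = b, three_prime = b))
  m[cbind(substr(ctx, 1, 1), substr(ctx, 4, 4))] <- val
  structure(m,
            row_marginals = rowSums(m),
            col_marginals = colSums(m),
            dipyrimidine = dipyrimidine,
            dipyrimidine_total = sum(val),
            class = c("context_heatmap", "matrix", "array"))
}

#' @export
print.context_heatmap <- function(x, digits = 2, ...) {
  cat(sprintf("%s heatmap (total %.2f%%); rows = 5' base, cols = 3' base\n",
              attr(x, "dipyrimidine"), attr(x, "dipyrimidine_total")))
  m <- cbind(unclass(x), total = attr(x, "row_marginals"))
  m <- rbind(m, total = c(attr(x, "col_marginals"), sum(unclass(x))))
  print(round(m, digits))
  invisible(x)
}

#' Percentage of CPDs in a context class
#'
#' Sums percentages over all sites whose context matches `pattern`, a
#' 4-character pattern over the alphabet A, C, G, T, R (purine), Y
#' (pyrimidine), N (any); e.g. `"YYYR"`, `"GYYN"`, `"TYYA"`.
#'
#' @param table A site frequency table.
#' @param pattern 4-character context pattern.
#' @return List with `pattern`, `n_sites` and `total_pct`.
#' @export
context_subset_total <- function(table, pattern) {
  stopifnot(nchar(pattern) == 4L)
  code <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]", N = ".")
  ch <- .chars(toupper(pattern))
  if (!all(ch %in% names(code))) stop("pattern may only use A,C,G,T,R,Y,N")
  rx <- paste0("^", paste(code[ch], collapse = ""), "$")
  keep <- grepl(rx, table$context)
  list(pattern = pattern, n_sites = sum(keep),
       total_pct = sum(.pct_col(table)[keep]))
}

#' Flanking-class summary of a 64-site table
#'
#' Totals (percent of all CPDs) for the standard flanking classes: 5'
#' pyrimidine (YYY) vs purine (RYY), 5' G, 3' purine/pyrimidine/G, the four
#' tetramer classes, and the TYYA subset. On a uniform table YYY is 50%,
#' GYY 25%, YYYR 25% and TYYA 6.25% (class sizes 32, 16, 16 and 4 of 64).
#'
#' @param table A 64-site frequency table.
#' @return Data frame with columns `class`, `pattern`, `n_sites`,
#'   `total_pct`.
#' @export
flanking_class_summary <- function(table) {
  .check_site_table(table, 64L)
  classes <- c(five_prime_Y = "YYYN", five_prime_R = "RYYN",
               five_prime_G = "GYYN", three_prime_R = "NYYR",
               three_prime_Y = "NYYY", three_prime_G = "NYYG",
               RYYR = "RYYR", RYYY = "RYYY", YYYR = "YYYR", YYYY = "YYYY",
               TYYA = "TYYA")
  rows <- lapply(classes, function(p) context_subset_total(table, p))
  data.frame(class = names(classes),
             pattern = unname(classes),
             n_sites = vapply(rows, `[[`, numeric(1), "n_sites"),
             total_pct = vapply(rows, `[[`, numeric(1), "total_pct"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Statistical expectation for k of n equally likely sites
#'
#' The uniform-null percentage `100 * k / site_set_size`, rounded as the
#' field reports it: 1 of 64 sites is 1.6%, 4 of 64 is 6%.
#'
#' @param k Number of sites in the subset.
#' @param site_set_size Total number of sites (e.g. 64).
#' @param decimals Decimal places for rounding (default 1).
#' @return The expected percentage.
#' @export
statistical_expectation <- function(k, site_set_size, decimals = 1L) {
  stopifnot(k >= 0, k <= site_set_size, site_set_size > 0)
  round(100 * k / site_set_size, decimals)
}

#' Per-tract CPD statistics for RYYYYR tracts
#'
#' Each maximal pyrimidine run of length 4 carries three overlapping
#' dipyrimidine sites. For each tract the three site percentages are
#' reported 5' to 3', together with whether the 3'-most site is the strict
#' maximum (ties are not counted), the tract mean, and globally the number
#' of 3'-max tracts and the grand mean over all tract sites.
#'
#' @param table A site frequency table covering the tract sites.
#' @param design The `coverage_sequence` whose core defines the tracts.
#' @return A `tract_report`: list with `tracts` (data frame: `tract`,
#'   `start`, `pct1`, `pct2`, `pct3`, `max_index` (NA on ties),
#'   `is_3prime_max`, `tract_mean`), `n_three_prime_max` and `grand_mean`.
#' @export
tract_analysis <- function(table, design) {
  stopifnot(inherits(design, "coverage_sequence"))
  core <- design$core
  ch <- .chars(core)
  r <- rle(is_pyrimidine(ch))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr4 <- which(r$values & r$lengths == 4L)
  if (!length(tr4)) stop("design core contains no pyrimidine tract of length 4")
  pct <- .pct_col(table)
  rows <- lapply(tr4, function(i) {
    s <- starts[i]
    site_pos <- s + 0:2
    idx <- match(site_pos, table$position)
    if (anyNA(idx))
      stop("table lacks tract site(s) at position ",
           paste(site_pos[is.na(idx)], collapse = ", "))
    v <- pct[idx]
    is_tie <- sum(v == max(v)) > 1L
    label <- paste0(if (s > 1L) ch[s - 1L] else "", substring(core, s, s + 3L),
                    if (s + 4L <= length(ch)) ch[s + 4L] else "")
    data.frame(tract = label, start = s,
               pct1 = v[1L], pct2 = v[2L], pct3 = v[3L],
               max_index = if (is_tie) NA_integer_ else which.max(v),
               is_3prime_max = !is_tie && which.max(v) == 3L,
               tract_mean = mean(v), stringsAsFactors = FALSE)
  })
  tracts <- do.call(rbind, rows)
  structure(list(tracts = tracts,
                 n_three_prime_max = sum(tracts$is_3prime_max),
                 grand_mean = mean(c(tracts$pct1, tracts$pct2, tracts$pct3))),
            class = "tract_report")
}

#' @export
print.tract_report <- function(x, ...) {
  cat(sprintf("tract_report: %d tract(s); %d with strict 3'-end maximum; grand mean %.2f%%\n",
              nrow(x$tracts), x$n_three_prime_max, x$grand_mean))
  print(x$tracts, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation of site percentages between two conditions
#'
#' @param table_a,table_b Site frequency tables sharing the subset's
#'   sites (matched by position).
#' @param subset `"YY"` for all sites, or one dipyrimidine (`"TT"`,
#'   `"TC"`, `"CT"`, `"CC"`).
#' @return List with `subset`, `n_sites` and `r` (Pearson coefficient on
#'   raw percentages).
#' @export
condition_correlation <- function(table_a, table_b,
                                  subset = c("YY", "TT", "TC", "CT", "CC")) {
  subset <- match.arg(subset)
  keep <- if (subset == "YY") rep(TRUE, nrow(table_a))
          else substr(table_a$context, 2, 3) == subset
  pos <- table_a$position[keep]
  ia <- match(pos, table_a$position)
  ib <- match(pos, table_b$position)
  if (anyNA(ib))
    stop("second table lacks site(s) at position ",
         paste(pos[is.na(ib)], collapse = ", "))
  a <- .pct_col(table_a)[ia]
  b <- .pct_col(table_b)[ib]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant percentage vector")
  list(subset = subset, n_sites = length(pos), r = stats::cor(a, b))
}
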