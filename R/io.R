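# Plain-text input/output: FASTA for designed sequences, TSV for lane
# tables, CSV for per-site frequency tables.

#' Write a designed sequence and its site annotations
#'
#' Writes `<prefix>.fasta` (the full padded sequence; header records seed,
#' lengths and the constraint summary) and `<prefix>_sites.tsv` (columns
#' `name`, `context`, `position`, `klass`).
#'
#' @param design A `coverage_sequence`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_design <- function(design, prefix) {
  stopifnot(inherits(design, "coverage_sequence"))
  seq <- full_sequence(design)
  header <- sprintf("design seed=%d core_len=%d total_len=%d contexts=%d max_run=%d",
                    design$seed, nchar(design$core), nchar(seq),
                    length(design$constraints$required_contexts),
                    design$constraints$max_pyrimidine_run)
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- header
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, "_sites.tsv")
  Biostrings::writeXStringSet(dna, fa)
  utils::write.table(design$sites, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, sites = tsv))
}

#' Write lane profiles as a TSV table
#'
#' One row per band; the full-length (uncut) band uses position 0. Columns:
#' `condition`, `replicate`, `loading`, `role`, `window_lo`, `window_hi`,
#' `position`, `volume`.
#'
#' @param lanes List of `lane_profile` objects.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_lanes <- function(lanes, file) {
  rows <- lapply(lanes, function(x) {
    data.frame(condition = x$condition_name,
               replicate = x$replicate_id,
               loading = x$loading_id,
               role = x$role,
               window_lo = x$window[1L],
               window_hi = x$window[2L],
               position = c(x$positions, 0L),
               volume = c(x$volumes, x$full_length_volume),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read lane profiles from a TSV table
#'
#' Inverse of [write_lanes()]; accepts any table with the same columns
#' (e.g. hand-entered densitometry volumes).
#'
#' @param file Path to the TSV.
#' @return List of `lane_profile` objects.
#' @export
read_lanes <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "loading", "role", "window_lo",
            "window_hi", "position", "volume")
  if (!all(need %in% names(d)))
    stop("lane table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(d$condition, d$replicate, d$loading, d$role, drop = TRUE)
  lapply(split(d, key), function(g) {
    full <- g$volume[g$position == 0L]
    if (length(full) != 1L)
      stop("each lane needs exactly one full-length row (position 0)")
    g2 <- g[g$position != 0L, ]
    g2 <- g2[order(g2$position), ]
    lane_profile(g2$position, g2$volume, full,
                 role = g$role[1L],
                 window = c(g$window_lo[1L], g$window_hi[1L]),
                 replicate_id = g$replicate[1L],
                 loading_id = g$loading[1L],
                 condition_name = g$condition[1L])
  })
}

#' Write a per-site frequency table as CSV
#'
#' @param table A `site_frequency_table` (or compatible data frame).
#' @param file Output path.
#' @param digits Decimal places for the percentage columns in the file
#'   (default 2); the in-memory table keeps full precision.
#' @return Invisibly, `file`.
#' @export
write_site_table <- function(table, file, digits = 2L) {
  out <- as.data.frame(table)
  for (col in intersect(c("mean_pct", "sd_pct", "pct"), names(out)))
    out[[col]] <- round(out[[col]], digits)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a per-site frequency table from CSV
#'
#' @param file Path to a CSV written by [write_site_table()].
#' @return A `site_frequency_table` data frame.
#' @export
read_site_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(d) <- c("site_frequency_table", "data.frame")
  d
}
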