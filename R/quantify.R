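# Poisson-corrected quantification of cleavage band volumes.
#
# On a 5'-labeled strand only the 5'-most cut of each molecule produces a
# band, so raw band volumes underestimate cleavage at 3' sites. Dividing
# each band volume by the total volume of all bands to its 3' side
# (including the uncut band) inverts this cascade: on noise-free data the
# ratio equals q/(1-q), the per-molecule cut odds at the site.

#' Poisson-corrected relative band frequencies of a lane
#'
#' For each site i resolved by the lane's loading window,
#' `f_i = V_i / (sum of volumes of all bands 3' of i + full-length volume)`.
#' The denominator always uses every band 3' of the site, whether or not it
#' is inside the window.
#'
#' @param lane A `lane_profile`.
#' @return Data frame with columns `position` and `f`, restricted to the
#'   lane's window, carrying the lane's `window`, `role`, `replicate_id`
#'   and `loading_id` as attributes.
#' @examples
#' lane <- expected_lane(c(0.1, 0.2), n_molecules = 1000)
#' relative_frequency(lane)$f   # 0.1111..., 0.25  (= q/(1-q))
#' @export
relative_frequency <- function(lane) {
  stopifnot(inherits(lane, "lane_profile"))
  k <- length(lane$positions)
  # sum of all volumes strictly 3' of each band, plus the uncut band
  downstream <- rev(cumsum(rev(c(lane$volumes[-1L], lane$full_length_volume))))
  if (any(downstream <= 0))
    stop("zero 3'-side denominator at position ",
         paste(lane$positions[downstream <= 0], collapse = ", "))
  f <- lane$volumes / downstream
  keep <- lane$positions >= lane$window[1] & lane$positions <= lane$window[2]
  out <- data.frame(position = lane$positions[keep], f = f[keep])
  attr(out, "window") <- lane$window
  attr(out, "role") <- lane$role
  attr(out, "replicate_id") <- lane$replicate_id
  attr(out, "loading_id") <- lane$loading_id
  out
}

#' Subtract control-lane frequencies from treated-lane frequencies
#'
#' Background cleavage present in the unirradiated control is removed
#' site-by-site; negative net frequencies are clipped to zero and counted.
#'
#' @param treated,control Frequency tables from [relative_frequency()] over
#'   the same site set.
#' @return The treated table with `f` replaced by `max(f - f_control, 0)`;
#'   the number of clipped sites is reported in attribute `n_clipped` and
#'   via a warning when nonzero.
#' @export
subtract_control <- function(treated, control) {
  if (!identical(treated$position, control$position))
    stop("treated and control tables cover different site sets")
  net <- treated$f - control$f
  n_clip <- sum(net < 0)
  if (n_clip > 0)
    warning(sprintf("%d site(s) had control frequency above treated; clipped to 0",
                    n_clip))
  treated$f <- pmax(net, 0)
  attr(treated, "n_clipped") <- n_clip
  treated
}

#' Normalize frequencies across gel loadings via shared bands
#'
#' Lanes loaded at different times carry arbitrary per-lane scale factors.
#' Adjacent loadings are put on a common scale using bands resolved in
#' both: loading i is rescaled by the median ratio of shared-site
#' frequencies to loading i-1, chained back to the first (reference)
#' loading. The merged table takes each site's value from the first listed
#' loading whose window resolves it.
#'
#' @param tables List of frequency tables (one per loading, same replicate),
#'   ordered; each carries its `window` attribute.
#' @param shared_sites List of length `length(tables) - 1`; element i gives
#'   the site positions used to normalize loadings i and i+1. `NULL`
#'   (default) uses all sites present in both tables.
#' @return Merged data frame with columns `position`, `f` and `loading_id`
#'   (which loading supplied each value), plus attribute `scale_factors`.
#' @export
normalize_loadings <- function(tables, shared_sites = NULL) {
  k <- length(tables)
  stopifnot(k >= 1L)
  if (k == 1L) {
    out <- tables[[1L]]
    out$loading_id <- 1L
    attr(out, "scale_factors") <- 1
    return(out)
  }
  if (is.null(shared_sites))
    shared_sites <- lapply(seq_len(k - 1L), function(i)
      intersect(tables[[i]]$position, tables[[i + 1L]]$position))
  stopifnot(length(shared_sites) == k - 1L)
  fac <- numeric(k)
  fac[1L] <- 1
  for (i in 2L:k) {
    s <- shared_sites[[i - 1L]]
    a <- tables[[i - 1L]]$f[match(s, tables[[i - 1L]]$position)]
    b <- tables[[i]]$f[match(s, tables[[i]]$position)]
    if (anyNA(a) || anyNA(b))
      stop("shared site(s) missing from a loading: ",
           paste(s[is.na(a) | is.na(b)], collapse = ", "))
    ok <- a > 0 & b > 0
    if (!any(ok))
      stop(sprintf("no usable shared band between loadings %d and %d (all zero)",
                   i - 1L, i))
    fac[i] <- fac[i - 1L] * stats::median(a[ok] / b[ok])
  }
  pos_all <- sort(unique(unlist(lapply(tables, `[[`, "position"))))
  src <- rep(NA_integer_, length(pos_all))
  val <- rep(NA_real_, length(pos_all))
  for (i in seq_len(k)) {
    idx <- match(tables[[i]]$position, pos_all)
    new <- is.na(src[idx])
    src[idx[new]] <- i
    val[idx[new]] <- tables[[i]]$f[new] * fac[i]
  }
  out <- data.frame(position = pos_all, f = val, loading_id = src)
  attr(out, "scale_factors") <- fac
  out
}

#' Convert merged frequencies to percentages over a site set
#'
#' `percentage_i = 100 * f_i / sum(f)` over the analyzed site set (all 64
#' NYYN sites, or the 16 NTTN sites for sensitizer experiments where only
#' TT bands are quantifiable).
#'
#' @param merged Data frame with `position` and `f` (from
#'   [normalize_loadings()]).
#' @param site_positions Positions forming the analyzed site set; default
#'   all positions in `merged`.
#' @return Data frame with columns `position` and `pct` summing to 100.
#' @export
site_percentages <- function(merged, site_positions = merged$position) {
  idx <- match(site_positions, merged$position)
  if (anyNA(idx))
    stop("site(s) absent from the merged table: ",
         paste(site_positions[is.na(idx)], collapse = ", "))
  f <- merged$f[idx]
  tot <- sum(f)
  if (tot <= 0) stop("total frequency over the site set is zero")
  data.frame(position = site_positions, pct = 100 * f / tot)
}

#' Average per-replicate percentage tables
#'
#' @param tables List of data frames with `position` and `pct`, one per
#'   replicate, over identical site sets.
#' @return Data frame with `position`, `mean_pct`, `sd_pct` (sample SD,
#'   n - 1 denominator; 0 when n = 1) and `n`.
#' @export
average_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  pos <- tables[[1L]]$position
  for (t in tables)
    if (!identical(t$position, pos))
      stop("replicate tables cover different site sets")
  m <- vapply(tables, `[[`, numeric(length(pos)), "pct")
  m <- matrix(m, nrow = length(pos))
  n <- ncol(m)
  data.frame(position = pos,
             mean_pct = rowMeans(m),
             sd_pct = if (n > 1) apply(m, 1L, stats::sd) else rep(0, length(pos)),
             n = n)
}

#' Full quantification pipeline for a simulated or imported experiment
#'
#' Applies, in order: Poisson-corrected relative frequencies per lane,
#' control subtraction per loading, cross-loading normalization via shared
#' bands, percentage normalization over the analyzed site set, and
#' replicate averaging.
#'
#' @param lanes List of `lane_profile` objects (control and treated lanes
#'   per loading per replicate, as from [simulate_experiment()]).
#' @param design The `coverage_sequence` the lanes derive from.
#' @param shared_sites Optional list of shared-site positions per adjacent
#'   loading pair (see [normalize_loadings()]).
#' @param site_set `"all64"` for every annotated site, `"tt16"` for the
#'   NTTN sites only.
#' @return A `site_frequency_table`: data frame with columns `name`,
#'   `context`, `position`, `klass`, `mean_pct`, `sd_pct`, `n`; the mean
#'   percentages sum to 100 over the site set.
#' @export
quantify_experiment <- function(lanes, design, shared_sites = NULL,
                                site_set = c("all64", "tt16")) {
  site_set <- match.arg(site_set)
  stopifnot(inherits(design, "coverage_sequence"))
  sites <- design$sites
  sel <- if (site_set == "tt16") sites[substr(sites$context, 2, 3) == "TT", ]
         else sites
  reps <- sort(unique(vapply(lanes, `[[`, integer(1), "replicate_id")))
  per_rep <- lapply(reps, function(r) {
    rl <- Filter(function(x) x$replicate_id == r, lanes)
    loads <- sort(unique(vapply(rl, `[[`, integer(1), "loading_id")))
    tabs <- lapply(loads, function(l) {
      tr <- Filter(function(x) x$loading_id == l && x$role == "treated", rl)
      co <- Filter(function(x) x$loading_id == l && x$role == "control", rl)
      if (length(tr) != 1L || length(co) != 1L)
        stop(sprintf("replicate %d loading %d: need exactly one treated and one control lane",
                     r, l))
      subtract_control(relative_frequency(tr[[1L]]),
                       relative_frequency(co[[1L]]))
    })
    merged <- normalize_loadings(tabs, shared_sites)
    site_percentages(merged, sel$position)
  })
  avg <- average_replicates(per_rep)
  out <- merge(sites, avg, by = "position", sort = TRUE)
  out <- out[order(out$position),
             c("name", "context", "position", "klass", "mean_pct", "sd_pct", "n")]
  rownames(out) <- NULL
  class(out) <- c("site_frequency_table", "data.frame")
  out
}
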