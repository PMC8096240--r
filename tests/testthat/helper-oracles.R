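# Independent oracles and shared fixtures, built in code at test time.

# Brute-force expected lane: enumerate all 2^k cut/no-cut patterns of k
# sites, observe the 5'-most cut of each pattern, and accumulate exact
# probabilities. Independent of the cumulative-product implementation.
brute_force_lane <- function(q, n_molecules) {
  k <- length(q)
  vol <- numeric(k)
  full <- 0
  for (mask in 0:(2^k - 1)) {
    cut <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    prob <- prod(ifelse(cut, q, 1 - q))
    first <- which(cut)[1]
    if (is.na(first)) full <- full + prob else vol[first] <- vol[first] + prob
  }
  list(volumes = n_molecules * vol, full_length_volume = n_molecules * full)
}

# Exhaustive minimal cover: depth-first search over every order of pairwise
# merges with overlap 1-3, applying the same validity rules as the designer
# (pyrimidine-run limit, conservation of NYYN windows, and no terminal YY
# in the finished string). Returns the minimum final length, or Inf if no
# complete merge exists. Memoized on the fragment multiset; practical for
# up to ~6 tetramers.
exhaustive_min_cover <- function(contexts, max_run = 4L) {
  memo <- new.env(parent = emptyenv())
  is_py <- function(ch) ch == "C" | ch == "T"
  nwin <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < 4) return(0L)
    py <- is_py(ch)
    sum(py[2:(n - 2)] & py[3:(n - 1)])
  }
  mrun <- function(s) {
    r <- rle(is_py(strsplit(s, "")[[1]]))
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  no_terminal_yy <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    !(is_py(ch[1]) && is_py(ch[2])) && !(is_py(ch[n - 1]) && is_py(ch[n]))
  }
  solve <- function(frags) {
    if (length(frags) == 1L)
      return(if (no_terminal_yy(frags)) nchar(frags) else Inf)
    key <- paste(sort(frags), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    nf <- length(frags)
    for (i in seq_len(nf)) for (j in seq_len(nf)) {
      if (i == j) next
      for (ov in 1:3) {
        if (substr(frags[i], nchar(frags[i]) - ov + 1L, nchar(frags[i])) !=
            substr(frags[j], 1L, ov)) next
        m <- paste0(frags[i], substr(frags[j], ov + 1L, nchar(frags[j])))
        if (mrun(m) > max_run) next
        if (nwin(m) != nwin(frags[i]) + nwin(frags[j])) next
        best <- min(best, solve(c(frags[-c(i, j)], m)))
      }
    }
    memo[[key]] <- best
    best
  }
  solve(contexts)
}

# Pearson correlation straight from the definition.
pearson_by_formula <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Shared full-coverage design (built once per test run).
.fixtures <- new.env(parent = emptyenv())
test_design <- function() {
  if (is.null(.fixtures$design)) {
    d <- design_coverage_sequence(design_constraints(), seed = 11L,
                                  restarts = 60L)
    .fixtures$design <- pad_sequence(d, 10L, seed = 12L)
  }
  .fixtures$design
}

# A minimal coverage_sequence wrapper around an arbitrary core, for tests
# that only exercise padding or tract extraction.
fake_design <- function(core) {
  structure(list(core = core,
                 sites = annotate_sites(core, require_full_context = FALSE),
                 flank5 = "", flank3 = "", seed = 0L, restarts = 0L,
                 restart_lengths = integer(0),
                 constraints = design_constraints()),
            class = "coverage_sequence")
}

# Uniform 64-site percentage table over a design's sites.
uniform_table <- function(design = test_design()) {
  s <- design$sites
  data.frame(name = s$name, context = s$context, position = s$position,
             klass = s$klass, mean_pct = rep(100 / nrow(s), nrow(s)),
             sd_pct = 0, n = 1, stringsAsFactors = FALSE)
}
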