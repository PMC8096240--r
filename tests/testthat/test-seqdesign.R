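test_that("nyyn_contexts enumerates all 64 contexts, 16 per class", {
  ctx <- nyyn_contexts()
  expect_equal(nrow(ctx), 64L)
  expect_equal(anyDuplicated(ctx$context), 0L)
  expect_true(all(is_pyrimidine(substr(ctx$context, 2, 2))))
  expect_true(all(is_pyrimidine(substr(ctx$context, 3, 3))))
  expect_equal(as.vector(table(ctx$klass)), rep(16L, 4L))
  expect_setequal(unique(ctx$klass), c("RYYR", "RYYY", "YYYR", "YYYY"))
})

test_that("context_class classifies flanks and rejects non-NYYN input", {
  expect_equal(context_class(c("ATTA", "ATTC", "CTTA", "CTTC")),
               c("RYYR", "RYYY", "YYYR", "YYYY"))
  expect_error(context_class("AATA"), "pyrimidine")
})

test_that("minimal_length_bound matches hand counts and flags infeasibility", {
  expect_equal(minimal_length_bound(
    design_constraints(required_contexts = "ATTA")), 4L)
  expect_equal(minimal_length_bound(design_constraints(
    required_contexts = c("ATTA", "ATCA", "ACTA", "ACCA"))), 13L)
  expect_equal(minimal_length_bound(design_constraints()), 129L)
  expect_error(minimal_length_bound(design_constraints(
    max_pyrimidine_run = 3L, required_contexts = "TTTT")), "infeasible")
})

test_that("designer solves the single-context and four-RYYR cases optimally", {
  d1 <- design_coverage_sequence(
    design_constraints(required_contexts = "ATTA"), seed = 1, restarts = 5)
  expect_equal(d1$core, "ATTA")

  req <- c("ATTA", "ATCA", "ACTA", "ACCA")
  d4 <- design_coverage_sequence(
    design_constraints(required_contexts = req), seed = 1, restarts = 50)
  expect_equal(nchar(d4$core), 13L)
  expect_equal(nchar(d4$core), exhaustive_min_cover(req))
  expect_true(verify_coverage(d4$core, d4$constraints)$pass)
})

test_that("designer matches the exhaustive-search oracle on random subsets", {
  # Random tetramer subsets are nearly always mutually unmergeable, so draw
  # structured ones: the three contexts of a random RYYYYR tract plus one
  # random RYYR tetramer. Some draws are still infeasible (the oracle
  # returns Inf); designer and oracle must agree either way.
  set.seed(606)
  PU <- c("A", "G"); PY <- c("C", "T")
  n_feasible <- 0L
  for (trial in 1:10) {
    y <- sample(PY, 4, replace = TRUE); r <- sample(PU, 2, replace = TRUE)
    tract <- c(paste0(r[1], y[1], y[2], y[3]),
               paste0(y[1], y[2], y[3], y[4]),
               paste0(y[2], y[3], y[4], r[2]))
    repeat {
      ryyr <- paste0(sample(PU, 1), sample(PY, 1), sample(PY, 1), sample(PU, 1))
      if (!ryyr %in% tract) break
    }
    req <- unique(c(tract, ryyr))
    if (length(req) < 4L) next
    oracle <- exhaustive_min_cover(req)
    d <- tryCatch(
      design_coverage_sequence(design_constraints(required_contexts = req),
                               seed = trial, restarts = 200,
                               stop_at_bound = FALSE),
      error = function(e) NULL)
    if (is.finite(oracle)) {
      n_feasible <- n_feasible + 1L
      expect_false(is.null(d))
      expect_equal(nchar(d$core), oracle)
    } else {
      expect_null(d)
    }
  }
  expect_gte(n_feasible, 5L)
})

test_that("designer is deterministic given seed and restarts", {
  dc <- design_constraints(required_contexts = c("ATTA", "GTCA", "ACTG", "GCCA"))
  d1 <- design_coverage_sequence(dc, seed = 7, restarts = 30)
  d2 <- design_coverage_sequence(dc, seed = 7, restarts = 30)
  expect_identical(d1$core, d2$core)
  expect_identical(d1$restart_lengths, d2$restart_lengths)
})

test_that("full 64-context design attains 129 nt with census {2:16, 4:16}", {
  d <- test_design()
  expect_equal(nchar(d$core), 129L)
  rep <- verify_coverage(d$core, d$constraints)
  expect_true(rep$pass)
  expect_equal(rep$n_sites, 64L)
  expect_equal(rep$tract_census, c("2" = 16L, "4" = 16L))
  expect_equal(rep$max_pyrimidine_run, 4L)
  expect_setequal(d$sites$context, nyyn_contexts()$context)
})

test_that("verify_coverage reports failures precisely", {
  dc <- design_constraints(required_contexts = c("ATTA", "ACCA"))
  good <- verify_coverage("ATTACCA", dc)
  expect_true(good$pass)
  bad_run <- verify_coverage("ATTTTTA", design_constraints(
    required_contexts = c("ATTT", "TTTT", "TTTA")))
  expect_false(bad_run$pass)
  expect_equal(bad_run$max_pyrimidine_run, 5L)
  missing <- verify_coverage("ATTAG", dc)
  expect_false(missing$pass)
  expect_equal(missing$missing, "ACCA")
  dup <- verify_coverage("ATTAGATTAG", design_constraints(
    required_contexts = "ATTA"))
  expect_false(dup$pass)
  expect_equal(dup$duplicated, "ATTA")
})

test_that("annotate_sites names and positions sites correctly", {
  a <- annotate_sites("ATTA")
  expect_equal(a$name, "ATTA-2")
  expect_equal(a$position, 2L)
  expect_equal(a$klass, "RYYR")

  b <- annotate_sites("GTTTTA")
  expect_equal(b$context, c("GTTT", "TTTT", "TTTA"))
  expect_equal(b$position, 2:4)
  expect_equal(b$name, c("GTTT-2", "TTTT-3", "TTTA-4"))

  expect_error(annotate_sites("TTAG"), "full NYYN window")
  expect_equal(nrow(annotate_sites("TTAG", require_full_context = FALSE)), 0L)
})

test_that("annotate_sites finds every YY dinucleotide (property)", {
  set.seed(99)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    ch <- strsplit(s, "")[[1]]
    py <- ch %in% c("C", "T")
    expected <- which(py[-40] & py[-1])
    expected <- expected[expected >= 2 & expected + 2 <= 40]
    got <- annotate_sites(s, require_full_context = FALSE)
    expect_equal(got$position, expected)
    expect_equal(got$context, substring(s, expected - 1L, expected + 2L))
  }
})

test_that("pad_sequence adds YY-free flanks without junction dipyrimidines", {
  d <- pad_sequence(test_design(), flank_length = 0L)
  expect_identical(d$flank5, test_design()$flank5)

  p <- test_design()  # built with 10-nt flanks
  full <- full_sequence(p)
  expect_equal(nchar(full), 149L)
  expect_equal(nchar(p$flank5), 10L)
  expect_equal(nchar(p$flank3), 10L)
  # the only YY sites of the full sequence are the 64 core sites
  shifted <- annotate_sites(full, require_full_context = FALSE)
  expect_equal(shifted$position, p$sites$position + 10L)
  # deterministic given the seed
  q1 <- pad_sequence(test_design(), 10L, seed = 12L)
  expect_identical(q1$flank5, p$flank5)
  expect_identical(q1$flank3, p$flank3)
  q2 <- pad_sequence(test_design(), 10L, seed = 13L)
  expect_false(identical(q2$flank5, p$flank5) && identical(q2$flank3, p$flank3))
})

test_that("design_constraints validates its arguments", {
  expect_error(design_constraints(max_pyrimidine_run = 1L), ">= 2")
  expect_error(design_constraints(required_contexts = character(0)), "non-empty")
  expect_error(design_constraints(required_contexts = c("ATTA", "ATTA")),
               "duplicates")
  expect_error(design_constraints(required_contexts = "AATA"), "pyrimidine")
})

test_that("designer errors with best-partial report when stuck", {
  # TCCC's pyrimidine 3' end can never be completed in exact mode with no
  # partner contexts present
  dc <- design_constraints(required_contexts = c("TCCT", "TCCC"))
  expect_error(design_coverage_sequence(dc, seed = 1, restarts = 5),
               "best partial")
})
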