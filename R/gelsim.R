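# Simulation of 5'-end-labeled cleavage gel lanes.
#
# CPDs are induced photochemically at each dipyrimidine site with a
# dose-dependent probability; CPD-specific glycosylase digestion converts
# every dimer into a strand break. On a 5'-labeled strand only the break
# nearest the label is visible, so the expected band volumes follow the
# single-hit (Poisson) cascade that the quantification module inverts.

#' Dose-response probability of CPD induction at a site
#'
#' CPD formation is opposed by direct photoreversal, so the occupied
#' fraction relaxes toward the steady state `k_f / (k_f + k_r)`:
#' `p(D) = k_f/(k_f + k_r) * (1 - exp(-(k_f + k_r) * D))`.
#' With no photoreversal (`k_r = 0`) this is `1 - exp(-k_f * D)`, linear in
#' dose at low dose. Vectorized over sites.
#'
#' @param k_f Forward CPD-formation rate per unit dose (m^2/J), >= 0.
#' @param k_r Photoreversal rate per unit dose (m^2/J), >= 0 (default 0).
#' @param dose Fluence in J/m^2, >= 0.
#' @return Per-site induction probability in [0, 1).
#' @export
induction_probability <- function(k_f, k_r = 0, dose) {
  if (any(k_f < 0) || any(k_r < 0)) stop("rate constants must be >= 0")
  if (any(dose < 0)) stop("`dose` must be >= 0")
  ktot <- k_f + k_r
  p <- ifelse(ktot == 0, 0, (k_f / ifelse(ktot == 0, 1, ktot)) *
                (1 - exp(-ktot * dose)))
  unname(p)
}

#' Construct a lane profile
#'
#' A lane is a vector of band volumes indexed by cleavage-site position
#' (the 1-based index of the 5' pyrimidine within the core), plus the
#' full-length (uncut) band.
#'
#' @param positions Integer site positions, 5' to 3'.
#' @param volumes Non-negative band volumes, same length as `positions`.
#' @param full_length_volume Volume of the uncut band.
#' @param role `"control"` or `"treated"`.
#' @param window Inclusive position range `c(lo, hi)` resolved in this
#'   loading (bands outside it are present but not considered resolved).
#' @param replicate_id,loading_id Integers identifying the experiment
#'   replicate and the gel loading.
#' @param condition_name Free-text condition label.
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(positions, volumes, full_length_volume,
                         role = c("treated", "control"),
                         window = range(positions),
                         replicate_id = 1L, loading_id = 1L,
                         condition_name = "") {
  role <- match.arg(role)
  positions <- as.integer(positions)
  if (length(positions) != length(volumes))
    stop("`positions` and `volumes` must have equal length")
  if (is.unsorted(positions, strictly = TRUE))
    stop("`positions` must be strictly increasing (5' to 3')")
  if (any(volumes < 0) || full_length_volume < 0)
    stop("band volumes must be non-negative")
  structure(list(positions = positions,
                 volumes = as.numeric(volumes),
                 full_length_volume = as.numeric(full_length_volume),
                 role = role,
                 window = as.integer(window),
                 replicate_id = as.integer(replicate_id),
                 loading_id = as.integer(loading_id),
                 condition_name = condition_name),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("lane_profile: %s, %d band(s), window %d-%d, replicate %d, loading %d%s\n",
              x$role, length(x$positions), x$window[1], x$window[2],
              x$replicate_id, x$loading_id,
              if (nzchar(x$condition_name)) paste0(" [", x$condition_name, "]") else ""))
  cat(sprintf("  full-length volume %.4g of %.4g total (%.1f%% uncut)\n",
              x$full_length_volume, x$full_length_volume + sum(x$volumes),
              100 * x$full_length_volume / (x$full_length_volume + sum(x$volumes))))
  invisible(x)
}

#' Noise model for simulated lanes
#'
#' @param molecules_per_lane Number of labeled molecules loaded per lane.
#' @param volume_cv Coefficient of variation of the multiplicative
#'   (densitometry) noise applied to each band volume.
#' @param background Per-site control cleavage probability; scalar or
#'   vector over sites, each in [0, 1).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(molecules_per_lane = 1e6, volume_cv = 0.1,
                        background = 5e-4) {
  if (molecules_per_lane < 1) stop("`molecules_per_lane` must be positive")
  if (volume_cv < 0) stop("`volume_cv` must be >= 0")
  if (any(background < 0) || any(background >= 1))
    stop("`background` probabilities must be in [0, 1)")
  structure(list(molecules_per_lane = molecules_per_lane,
                 volume_cv = volume_cv,
                 background = background),
            class = "noise_model")
}

# Composite per-site cut probability: background and CPD cleavage act
# independently on each molecule.
.cut_probability <- function(p, background) {
  1 - (1 - background) * (1 - p)
}

#' Expected (noise-free) band volumes of a lane
#'
#' With per-site cut probability `q_i = 1 - (1 - b_i)(1 - p_i)`, a 5'-labeled
#' molecule shows the 5'-most of its cuts, so the expected volume at site i
#' is `n * q_i * prod_{j<i} (1 - q_j)` and the uncut band carries
#' `n * prod_j (1 - q_j)`; volumes sum exactly to `n`.
#'
#' @param p Per-site CPD induction probabilities, ordered 5' to 3'.
#' @param background Per-site control cleavage probability (scalar or
#'   vector), default 0.
#' @param n_molecules Number of labeled molecules.
#' @param positions Site positions (default `seq_along(p)`).
#' @param ... Passed to [lane_profile()] (`role`, `window`, ids).
#' @return A `lane_profile` with expected volumes.
#' @examples
#' lane <- expected_lane(c(0.1, 0.2), n_molecules = 1000)
#' lane$volumes             # 100, 180
#' lane$full_length_volume  # 720
#' @export
expected_lane <- function(p, background = 0, n_molecules = 1e6,
                          positions = seq_along(p), ...) {
  if (any(p < 0) || any(p >= 1) || any(background < 0) || any(background >= 1))
    stop("probabilities must lie in [0, 1)")
  q <- .cut_probability(p, background)
  surv <- cumprod(1 - q)
  upstream <- c(1, surv[-length(surv)])
  vol <- n_molecules * q * upstream
  full <- n_molecules * (if (length(q)) surv[length(q)] else 1)
  lane_profile(positions, vol, full, ...)
}

#' Simulate a noisy lane
#'
#' Band counts are drawn multinomially from the expected-lane proportions,
#' then each band is scaled by multiplicative log-normal noise with the
#' requested coefficient of variation (mean 1).
#'
#' @param p Per-site CPD induction probabilities, 5' to 3'.
#' @param background Per-site control cleavage probability.
#' @param noise A [noise_model()].
#' @param seed Integer seed, or `NULL` to use the current RNG state (as
#'   when called inside [simulate_experiment()]).
#' @param positions Site positions (default `seq_along(p)`).
#' @param scale Per-lane multiplicative loading factor applied to all
#'   volumes (default 1).
#' @param ... Passed to [lane_profile()].
#' @return A `lane_profile`.
#' @export
simulate_lane <- function(p, background = noise$background, noise = noise_model(),
                          seed = NULL, positions = seq_along(p), scale = 1, ...) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  exp_lane <- expected_lane(p, background, n_molecules = 1, positions = positions, ...)
  probs <- c(exp_lane$volumes, exp_lane$full_length_volume)
  n <- noise$molecules_per_lane
  counts <- as.numeric(stats::rmultinom(1L, size = n, prob = probs))
  if (noise$volume_cv > 0) {
    sdlog <- sqrt(log(1 + noise$volume_cv^2))
    counts <- counts * stats::rlnorm(length(counts), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog)
  }
  counts <- counts * scale
  k <- length(positions)
  out <- exp_lane
  out$volumes <- counts[seq_len(k)]
  out$full_length_volume <- counts[k + 1L]
  out
}

#' Fraction of uncut (full-length) material in a lane
#'
#' Under quasi single-hit conditions at least 60% of the labeled DNA must
#' remain uncut; lanes below that are flagged as violating the guard.
#'
#' @param lane A `lane_profile`.
#' @param threshold Minimum acceptable uncut fraction (default 0.60).
#' @return List with `fraction` (full-length volume over total volume) and
#'   `single_hit` (`TRUE` when `fraction >= threshold`).
#' @export
fraction_uncut <- function(lane, threshold = 0.60) {
  stopifnot(inherits(lane, "lane_profile"))
  total <- lane$full_length_volume + sum(lane$volumes)
  if (total <= 0) stop("lane has zero total volume")
  frac <- lane$full_length_volume / total
  list(fraction = frac, single_hit = frac >= threshold)
}

#' Irradiation condition
#'
#' @param name Condition label (e.g. `"UVC"`, `"NB UVB"`).
#' @param dose_rate Dose rate in J/(m^2 s).
#' @param exposure_time Exposure in seconds.
#' @param kinetics Data frame of per-site kinetics with columns `position`,
#'   `context`, `k_f` and `k_r` (see [sensitizer_profile()]).
#' @param sensitizer One of `"none"`, `"acetone"`, `"NFX"`.
#' @return An object of class `irradiation_condition`.
#' @export
irradiation_condition <- function(name, dose_rate, exposure_time, kinetics,
                                  sensitizer = c("none", "acetone", "NFX")) {
  sensitizer <- match.arg(sensitizer)
  if (dose_rate < 0 || exposure_time < 0)
    stop("`dose_rate` and `exposure_time` must be >= 0")
  stopifnot(is.data.frame(kinetics),
            all(c("position", "k_f", "k_r") %in% names(kinetics)))
  structure(list(name = name, dose_rate = dose_rate,
                 exposure_time = exposure_time, sensitizer = sensitizer,
                 kinetics = kinetics),
            class = "irradiation_condition")
}

#' Planted per-site photochemical rate profiles
#'
#' Generates forward rate constants by dipyrimidine type and flanking
#' context, emulating the qualitative biology of each induction mode; the
#' returned values are the ground truth that recovery tests compare
#' against.
#'
#' * `"UV"` (direct excitation): all four dipyrimidines form CPDs, with
#'   5'-flanking G strongly suppressive (charge-transfer quenching), a
#'   5'-pyrimidine enhancing, and a mild 3'-purine preference; site-level
#'   log-normal variability is added and the profile is rescaled so the
#'   max/min spread across the 64 sites is exactly `fold_spread`
#'   (default 12).
#' * `"acetone"` (high-energy triplet sensitizer): CPDs concentrate at TT
#'   sites with detectable TC/CT; rates are rescaled so TT sites carry
#'   exactly `tt_share` (default 0.79) of the total forward rate; CC is
#'   zero.
#' * `"NFX"` (norfloxacin, low-energy triplet): only TT sites have nonzero
#'   rates.
#'
#' @param sites Site annotation data frame (from [annotate_sites()]).
#' @param mode One of `"UV"`, `"acetone"`, `"NFX"`.
#' @param seed Integer seed for the site-level variability.
#' @param fold_spread Max/min spread imposed in UV mode.
#' @param tt_share Fraction of total forward rate at TT sites in acetone
#'   mode.
#' @return Data frame with columns `position`, `context`, `k_f`, `k_r`
#'   (photoreversal, zero by default) and attribute `mode`. Rates are
#'   relative; scale them to a dose with [calibrate_kinetics()].
#' @export
sensitizer_profile <- function(sites, mode = c("UV", "acetone", "NFX"),
                               seed = 1L, fold_spread = 12, tt_share = 0.79) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(sites), all(c("position", "context") %in% names(sites)))
  set.seed(as.integer(seed))
  ctx <- sites$context
  dipy <- substr(ctx, 2, 3)
  five <- substr(ctx, 1, 1)
  three <- substr(ctx, 4, 4)
  n <- length(ctx)

  if (mode == "UV") {
    base <- c(TT = 1.0, TC = 0.75, CT = 0.5, CC = 0.45)[dipy]
    mod5 <- ifelse(five == "G", 0.3, ifelse(is_pyrimidine(five), 1.6, 1.0))
    mod3 <- ifelse(is_pyrimidine(three), 0.9, 1.1)
    k_f <- base * mod5 * mod3 * stats::rlnorm(n, 0, 0.2)
    # impose the target max/min spread exactly (affine rescale in log space)
    lk <- log(k_f)
    lk <- (lk - min(lk)) / (max(lk) - min(lk)) * log(fold_spread)
    k_f <- exp(lk)
  } else if (mode == "acetone") {
    k_f <- numeric(n)
    tt <- dipy == "TT"
    tctt <- dipy %in% c("TC", "CT")
    k_f[tt] <- stats::rlnorm(sum(tt), 0, 0.5)
    k_f[tctt] <- 0.08 * stats::rlnorm(sum(tctt), 0, 0.5)
    # rescale the TT block so its share of the total rate is exact
    s_tt <- sum(k_f[tt]); s_other <- sum(k_f[!tt])
    k_f[tt] <- k_f[tt] * tt_share / s_tt * s_other / (1 - tt_share)
  } else {
    k_f <- numeric(n)
    tt <- dipy == "TT"
    k_f[tt] <- stats::rlnorm(sum(tt), 0, 0.5)
  }
  out <- data.frame(position = sites$position, context = ctx,
                    k_f = unname(k_f), k_r = 0, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Scale a kinetics profile to a target uncut fraction
#'
#' Multiplies all forward rates by a common factor so that, at the given
#' dose, the expected full-length fraction equals `target_uncut`. This is
#' how exposure times are chosen in practice: long enough for quantifiable
#' bands, short enough that at least 60% of molecules stay uncut.
#'
#' @param kinetics Kinetics data frame (`position`, `k_f`, `k_r`).
#' @param dose Dose in J/m^2.
#' @param target_uncut Desired expected uncut fraction (default 0.7).
#' @param background Per-site background cleavage folded into the
#'   expectation (default 0).
#' @return The kinetics data frame with rescaled `k_f` (and `k_r`,
#'   preserving each site's steady state).
#' @export
calibrate_kinetics <- function(kinetics, dose, target_uncut = 0.7,
                               background = 0) {
  stopifnot(target_uncut > 0, target_uncut < 1, dose > 0)
  uncut_at <- function(scl) {
    p <- induction_probability(kinetics$k_f * scl, kinetics$k_r * scl, dose)
    q <- .cut_probability(p, background)
    prod(1 - q)
  }
  f <- function(scl) uncut_at(scl) - target_uncut
  upper <- 1
  while (f(upper) > 0) upper <- upper * 10
  scl <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  kinetics$k_f <- kinetics$k_f * scl
  kinetics$k_r <- kinetics$k_r * scl
  kinetics
}

# Validate loading windows: every annotated site must fall in some window
# and consecutive windows must share enough sites for normalization.
.check_windows <- function(windows, positions, min_shared = 3L) {
  windows <- lapply(windows, function(w) as.integer(w[1:2]))
  starts <- vapply(windows, `[`, integer(1), 1L)
  windows <- windows[order(starts)]
  covered <- Reduce(`|`, lapply(windows, function(w)
    positions >= w[1] & positions <= w[2]))
  if (!all(covered))
    stop("loading windows leave site(s) uncovered: ",
         paste(positions[!covered], collapse = ", "))
  if (length(windows) > 1L) {
    for (i in seq_len(length(windows) - 1L)) {
      shared <- sum(positions >= windows[[i + 1L]][1] &
                      positions <= windows[[i]][2])
      if (shared < min_shared)
        stop(sprintf("windows %d-%d and %d-%d share only %d site(s); >= %d required",
                     windows[[i]][1], windows[[i]][2],
                     windows[[i + 1L]][1], windows[[i + 1L]][2],
                     shared, min_shared))
    }
  }
  windows
}

#' Simulate a full multi-loading, replicated cleavage experiment
#'
#' For every replicate and loading window one control lane (background
#' cleavage only) and one treated lane are generated, each with an
#' independent per-lane scale factor drawn log-uniformly from [0.5, 2]
#' (emulating unequal loading, which the quantification pipeline must
#' normalize away). Deterministic given `seed`.
#'
#' @param design A `coverage_sequence` (provides the annotated sites).
#' @param condition An [irradiation_condition()]; its kinetics rows must
#'   match the design's sites.
#' @param loadings List of inclusive windows `c(lo, hi)`; together they
#'   must cover all sites and consecutive windows must share at least 3
#'   sites.
#' @param replicates Number of independent replicates (default 3).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return List of `lane_profile` objects (2 x loadings x replicates).
#' @export
simulate_experiment <- function(design, condition, loadings, replicates = 3L,
                                noise = noise_model(), seed = 1L) {
  stopifnot(inherits(design, "coverage_sequence"),
            inherits(condition, "irradiation_condition"),
            inherits(noise, "noise_model"))
  sites <- design$sites
  kin <- condition$kinetics
  if (!identical(sort(kin$position), sort(sites$position)))
    stop("condition kinetics do not match the design's site positions")
  kin <- kin[order(kin$position), , drop = FALSE]
  windows <- .check_windows(loadings, sites$position)
  dose <- condition$dose_rate * condition$exposure_time
  p <- induction_probability(kin$k_f, kin$k_r, dose)
  set.seed(as.integer(seed))
  lanes <- list()
  for (rep_id in seq_len(as.integer(replicates))) {
    for (l in seq_along(windows)) {
      for (role in c("control", "treated")) {
        scl <- exp(stats::runif(1, log(0.5), log(2)))
        lanes[[length(lanes) + 1L]] <- simulate_lane(
          p = if (role == "treated") p else rep(0, length(p)),
          background = noise$background,
          noise = noise, seed = NULL,
          positions = kin$position, scale = scl,
          role = role, window = windows[[l]],
          replicate_id = rep_id, loading_id = l,
          condition_name = condition$name)
      }
    }
  }
  lanes
}
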