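#' Automated data-quality metric schema
#'
#' The 31 column names of the automated diffusion/T1 data-quality metrics
#' table (ImageQC.csv-style), in their conventional order: 14 motion/quality
#' summaries followed by 17 acquisition descriptors that are constant within
#' a scanning site.
#'
#' @return character vector of length 31.
#' @export
qc_metric_names <- function() {
  c(
    "raw_neighbor_corr", "max_rel_translation", "raw_num_bad_slices",
    "t1_neighbor_corr", "raw_incoherence_index", "raw_coherence_index",
    "max_rel_rotation", "mean_fd", "max_fd", "max_rotation",
    "t1_coherence_index", "t1_dice_distance", "max_translation",
    "t1_incoherence_index",
    "raw_voxel_size_x", "raw_voxel_size_y", "raw_voxel_size_z",
    "raw_num_directions", "raw_max_b", "raw_dimension_y", "raw_dimension_z",
    "t1_voxel_size_x", "t1_dimension_x", "t1_dimension_y", "t1_dimension_z",
    "t1_voxel_size_y", "t1_voxel_size_z", "t1_max_b", "t1_num_bad_slices",
    "t1_num_directions", "raw_dimension_x"
  )
}

#' The 24 white-matter bundles of the tract-profile schema
#'
#' Eight bilateral bundles (left/right) plus eight callosal segments.
#'
#' @return character vector of length 24.
#' @export
bundle_names <- function() {
  lateral <- c("IFO", "UNC", "ATR", "CST", "ARC", "SLF", "ILF", "CGC")
  c(paste0(lateral, "_L"), paste0(lateral, "_R"),
    c("Orbital", "AntFrontal", "SupFrontal", "Motor",
      "SupParietal", "Temporal", "PostParietal", "Occipital"))
}

#' Generate a synthetic multi-site cohort
#'
#' Draws per-participant ground truth: scanning site, age, sex and a latent
#' data-quality score `q` in \[0,1\]. Quality is Beta-distributed and linked
#' to age through a Gaussian copula, reproducing the direct age-quality
#' association seen in pediatric imaging (older children move less); `q` is
#' independent of sex and site by construction. `true_label` is 1 where
#' `q >= 0.5`.
#'
#' @param n number of participants (>= 1).
#' @param site_proportions named numeric vector summing to 1; defaults to the
#'   four-site composition of a large pediatric study (RU/CBIC/CUNY/SI).
#' @param age_range age bounds in years (uniform marginal).
#' @param age_quality_corr copula correlation between age and `q`, in (-1,1).
#' @param q_shape1,q_shape2 Beta shape parameters of the latent quality
#'   marginal; the defaults give a predominantly passing cohort.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return data frame of class `latent_cohort` with columns
#'   `participant_id`, `site`, `age`, `sex`, `q`, `true_label`.
#' @export
generate_cohort <- function(n,
                            site_proportions = c(RU = 0.409, CBIC = 0.416,
                                                 CUNY = 0.034, SI = 0.141),
                            age_range = c(5, 21),
                            age_quality_corr = 0.31,
                            q_shape1 = 2.5, q_shape2 = 1.2,
                            seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (abs(sum(site_proportions) - 1) > 1e-6) {
    stop("site_proportions must sum to 1")
  }
  if (abs(age_quality_corr) >= 1) stop("age_quality_corr must be in (-1, 1)")
  set.seed(seed)
  rho <- age_quality_corr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  age <- age_range[1] + diff(age_range) * stats::pnorm(z1)
  q <- stats::qbeta(stats::pnorm(z2), q_shape1, q_shape2)
  out <- data.frame(
    participant_id = sprintf("sub-%05d", seq_len(n)),
    site = sample(names(site_proportions), n, replace = TRUE,
                  prob = site_proportions),
    age = age,
    sex = sample(c("male", "female"), n, replace = TRUE),
    q = q,
    true_label = as.integer(q >= 0.5),
    stringsAsFactors = FALSE
  )
  class(out) <- c("latent_cohort", "data.frame")
  out
}

# Per-site values of the acquisition-descriptor columns: constant within
# site (and hence carry no quality information), mirroring their zero
# feature importance.
acquisition_constants <- function(site) {
  base <- list(
    raw_voxel_size_x = 1.8, raw_voxel_size_y = 1.8, raw_voxel_size_z = 1.8,
    raw_num_directions = 128, raw_dimension_x = 128, raw_dimension_y = 128,
    raw_dimension_z = 80,
    t1_voxel_size_x = 0.8, t1_voxel_size_y = 0.8, t1_voxel_size_z = 0.8,
    t1_dimension_x = 256, t1_dimension_y = 256, t1_dimension_z = 224,
    t1_max_b = 0, t1_num_bad_slices = 0, t1_num_directions = 1
  )
  max_b <- c(RU = 2000, CBIC = 3000, CUNY = 2000, SI = 1000)[site]
  max_b[is.na(max_b)] <- 2000
  c(base, list(raw_max_b = unname(max_b)))
}

#' Generate the automated quality-metrics table
#'
#' Produces the 31-column metrics table for a cohort. The 14 quality
#' summaries are monotone transforms of the latent quality `q` plus noise,
#' with the sign structure observed empirically: the neighboring DWI
#' correlation increases with quality while motion summaries (relative
#' translation/rotation, framewise displacement, outlier slice counts)
#' decrease with it. The 17 acquisition descriptors are constant within
#' site. Count columns are nonnegative integers.
#'
#' @param cohort a `latent_cohort`.
#' @param noise_sd nonnegative global noise multiplier; 0 gives deterministic
#'   monotone transforms of `q`. The default is calibrated so the
#'   metric-quality correlations sit in the regime observed for automated
#'   metrics against expert ratings (|Pearson| roughly 0.7-0.85) rather than
#'   being near-deterministic.
#' @param seed integer seed.
#' @return data frame with `participant_id` plus the 31 metric columns of
#'   [qc_metric_names()].
#' @export
generate_metrics <- function(cohort, noise_sd = 1.75, seed = 1L) {
  if (nrow(cohort) == 0L) stop("cohort must be nonempty")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  n <- nrow(cohort)
  q <- cohort$q
  nz <- function(scale) noise_sd * scale * stats::rnorm(n)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  counts <- function(lambda) {
    as.integer(round(pmax(0, lambda + nz(2) * sqrt(lambda + 1))))
  }
  m <- data.frame(participant_id = cohort$participant_id,
                  stringsAsFactors = FALSE)
  m$raw_neighbor_corr <- clamp(0.55 + 0.35 * q + nz(0.045), 0, 1)
  m$max_rel_translation <- pmax(0, 0.3 + 3.5 * (1 - q) + nz(0.35))
  m$raw_num_bad_slices <- counts(45 * (1 - q)^2)
  m$t1_neighbor_corr <- clamp(0.82 + 0.12 * q + nz(0.02), 0, 1)
  m$raw_incoherence_index <- pmax(0, 0.2 + 0.6 * (1 - q) + nz(0.08))
  m$raw_coherence_index <- pmax(0, 0.4 + 0.5 * q + nz(0.08))
  m$max_rel_rotation <- pmax(0, 0.2 + 2.5 * (1 - q) + nz(0.3))
  m$mean_fd <- pmax(0, 0.1 + 1.2 * (1 - q) + nz(0.12))
  m$max_fd <- pmax(0, 0.3 + 4 * (1 - q) + nz(0.5))
  m$max_rotation <- pmax(0, 0.3 + 3 * (1 - q) + nz(0.4))
  m$t1_coherence_index <- pmax(0, 0.5 + 0.3 * q + nz(0.1))
  m$t1_dice_distance <- pmax(0, 0.02 + 0.1 * (1 - q) + nz(0.015))
  m$max_translation <- pmax(0, 0.5 + 5 * (1 - q) + nz(0.7))
  m$t1_incoherence_index <- pmax(0, 0.15 + 0.3 * (1 - q) + nz(0.06))
  ac <- acquisition_constants(cohort$site)
  for (nm in setdiff(qc_metric_names(), names(m))) m[[nm]] <- ac[[nm]]
  m[, c("participant_id", qc_metric_names())]
}

#' Simulate expert ratings
#'
#' Each expert rates each participant on the five-level ordinal scale
#' -2 (definitely fail), -1 (probably fail), 0 (not sure), 1 (probably
#' pass), 2 (definitely pass). Expert `r` thresholds `q + bias_r + noise`
#' at shared cutpoints 0.2/0.4/0.6/0.8, so higher latent quality yields
#' stochastically higher ratings; rater differences enter only through the
#' bias and noise terms.
#'
#' The default noise level is calibrated so that pairwise quadratic-weighted
#' kappa among simulated experts falls in the moderate-to-substantial
#' agreement regime typical of expert dMRI QC panels.
#'
#' @param cohort a `latent_cohort`.
#' @param n_experts number of raters (>= 2).
#' @param bias_sd standard deviation of per-expert bias.
#' @param noise_sd standard deviation of per-rating noise.
#' @param seed integer seed.
#' @return integer matrix participants x experts with entries in -2..2;
#'   rownames are participant ids.
#' @export
simulate_expert_ratings <- function(cohort, n_experts = 6L, bias_sd = 0.04,
                                    noise_sd = 0.12, seed = 1L) {
  if (n_experts < 2L) stop("n_experts must be >= 2")
  set.seed(seed)
  n <- nrow(cohort)
  bias <- stats::rnorm(n_experts, 0, bias_sd)
  ratings <- vapply(seq_len(n_experts), function(r) {
    score <- cohort$q + bias[r] + stats::rnorm(n, 0, noise_sd)
    findInterval(score, c(0.2, 0.4, 0.6, 0.8)) - 2L
  }, integer(n))
  if (n == 1L) ratings <- matrix(ratings, nrow = 1L)
  rownames(ratings) <- cohort$participant_id
  colnames(ratings) <- sprintf("expert%02d", seq_len(n_experts))
  ratings
}

#' Simulate community (crowd) ratings
#'
#' Community raters assign binary pass/fail labels to slice views of each
#' participant's image. Each rater has a drawn sensitivity and specificity
#' applied to the true pass/fail label; an `optimism` parameter shifts every
#' rater's pass probability upward, emulating the observation that community
#' raters are less conservative than experts. Views are conditionally i.i.d.
#' given the rater and participant, and rater-participant assignment is
#' random and sparse. The defaults (40 mixed-reliability raters x 10 views
#' at 50% coverage) give about 200 ratings per participant on average.
#'
#' @param cohort a `latent_cohort`.
#' @param n_raters number of community raters (>= 1).
#' @param views_per_participant views rated per (rater, participant) pair.
#' @param reliability list with Beta shapes `sens_shape` and `spec_shape`
#'   (each length 2) from which rater sensitivity/specificity are drawn.
#' @param rater_reliability optional data frame with columns `sensitivity`
#'   and `specificity` fixing each rater's operating point (overrides
#'   `reliability`).
#' @param optimism nonnegative upward shift of pass probability:
#'   `p <- p + optimism * (1 - p)`.
#' @param coverage probability that a given rater rates a given participant.
#' @param seed integer seed.
#' @return long data frame (`participant_id`, `rater_id`, `view`, `rating`)
#'   with `rating` in {0, 1}.
#' @export
simulate_community_ratings <- function(cohort, n_raters = 40L,
                                       views_per_participant = 10L,
                                       reliability = list(
                                         sens_shape = c(9, 2.2),
                                         spec_shape = c(4, 3)
                                       ),
                                       rater_reliability = NULL,
                                       optimism = 0.45, coverage = 0.5,
                                       seed = 1L) {
  if (n_raters < 1L) stop("n_raters must be >= 1")
  if (views_per_participant < 1L) stop("views_per_participant must be >= 1")
  if (optimism < 0) stop("optimism must be nonnegative")
  set.seed(seed)
  if (is.null(rater_reliability)) {
    sens <- stats::rbeta(n_raters, reliability$sens_shape[1],
                         reliability$sens_shape[2])
    spec <- stats::rbeta(n_raters, reliability$spec_shape[1],
                         reliability$spec_shape[2])
  } else {
    stopifnot(nrow(rater_reliability) == n_raters)
    sens <- rater_reliability$sensitivity
    spec <- rater_reliability$specificity
  }
  n <- nrow(cohort)
  out <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    rated <- which(stats::runif(n) <= coverage)
    if (length(rated) == 0L) next
    p <- ifelse(cohort$true_label[rated] == 1L, sens[r], 1 - spec[r])
    p <- p + optimism * (1 - p)
    k <- views_per_participant
    ratings <- stats::rbinom(length(rated) * k, 1L, rep(p, each = k))
    out[[r]] <- data.frame(
      participant_id = rep(cohort$participant_id[rated], each = k),
      rater_id = sprintf("rater%03d", r),
      view = rep(seq_len(k), times = length(rated)),
      rating = ratings,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "rater_reliability") <- data.frame(
    rater_id = sprintf("rater%03d", seq_len(n_raters)),
    sensitivity = sens, specificity = spec, stringsAsFactors = FALSE
  )
  res
}

#' Generate a synthetic 4-channel QC phantom volume
#'
#' A smooth head-like b=0 intensity blob plus three tube-shaped "bundles"
#' whose directionally-encoded-color FA energy concentrates in the channel
#' matching their orientation (lateral tube in `decfa_x`, anterior-posterior
#' in `decfa_y`, superior-inferior in `decfa_z`). Degraded quality (`q < 1`)
#' adds an alternating-slice intensity banding artifact along the
#' inferior-superior axis of the b=0 channel and attenuates and blurs the
#' DEC-FA channels; severity scales with `1 - q`.
#'
#' @param q latent quality in \[0,1\].
#' @param shape 3 spatial extents, each >= 16.
#' @param band_depth banding modulation depth at `q = 0` (fraction of slice
#'   intensity; the alternating slice gain is `1 +/- band_depth * (1 - q)`).
#' @param noise_sd additive measurement noise on the b=0 channel.
#' @param seed integer seed.
#' @return array (D, H, W, 4) with channels `b0`, `decfa_x`, `decfa_y`,
#'   `decfa_z` (DEC-FA in \[0,1\]); attribute `bundle_masks` holds logical
#'   masks of the three synthetic bundles.
#' @export
generate_volume <- function(q, shape = c(32L, 32L, 32L), band_depth = 0.35,
                            noise_sd = 0.02, seed = 1L) {
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("each extent must be >= 16")
  }
  set.seed(seed)
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  gx <- seq(-1, 1, length.out = D)
  gy <- seq(-1, 1, length.out = H)
  gz <- seq(-1, 1, length.out = W)
  X <- array(rep(gx, times = H * W), dim = shape)
  Y <- array(rep(rep(gy, each = D), times = W), dim = shape)
  Z <- array(rep(gz, each = D * H), dim = shape)
  r2 <- (X / 0.85)^2 + (Y / 0.95)^2 + (Z / 0.85)^2
  b0 <- 0.15 + 0.85 / (1 + exp(20 * (sqrt(r2) - 0.85)))

  tube <- function(d1, d2, c1, c2, radius = 0.18) {
    exp(-((d1 - c1)^2 + (d2 - c2)^2) / (2 * radius^2))
  }
  # lateral (x-oriented), anterior-posterior (y-oriented),
  # superior-inferior (z-oriented) bundles
  fx <- tube(Y, Z, -0.35, 0.05) * (abs(X) < 0.7)
  fy <- tube(X, Z, 0.3, -0.1) * (abs(Y) < 0.7)
  fz <- tube(X, Y, -0.25, 0.3) * (abs(Z) < 0.7)
  atten <- 1 - 0.7 * (1 - q)
  decfa <- list(x = 0.85 * fx * atten, y = 0.85 * fy * atten,
                z = 0.85 * fz * atten)

  if (q < 1) {
    # alternating slice gain along the inferior-superior (3rd) axis
    gain <- 1 + band_depth * (1 - q) * cos(pi * (seq_len(W) - 1))
    b0 <- sweep(b0, 3L, gain, `*`)
    w <- 0.5 * (1 - q)  # axial blur of the DEC-FA channels
    blur_z <- function(v) {
      sm <- v
      sm[, , 2:(W - 1)] <- (v[, , 1:(W - 2)] + v[, , 2:(W - 1)] +
                              v[, , 3:W]) / 3
      (1 - w) * v + w * sm
    }
    decfa <- lapply(decfa, blur_z)
  }
  b0 <- pmax(b0 + stats::rnorm(length(b0), 0, noise_sd), 0)
  vol <- array(0, dim = c(shape, 4L))
  vol[, , , 1] <- b0
  vol[, , , 2] <- pmin(pmax(decfa$x, 0), 1)
  vol[, , , 3] <- pmin(pmax(decfa$y, 0), 1)
  vol[, , , 4] <- pmin(pmax(decfa$z, 0), 1)
  dimnames(vol) <- list(NULL, NULL, NULL,
                        c("b0", "decfa_x", "decfa_y", "decfa_z"))
  attr(vol, "bundle_masks") <- list(x = fx > 0.3, y = fy > 0.3, z = fz > 0.3)
  vol
}

#' Alternating-slice modulation depth of a volume
#'
#' Quantifies banding: the contrast between even- and odd-indexed axial
#' slice mean intensities, `(even - odd) / (even + odd)` in magnitude. An
#' artifact-free smooth volume scores near 0; a volume with alternating
#' slice gain `1 +/- a` scores near `a`.
#'
#' @param volume (D,H,W,4) array or a single (D,H,W) channel; the b=0
#'   channel is used when 4D.
#' @return modulation depth in \[0, 1\].
#' @export
slice_alternation <- function(volume) {
  ch <- if (length(dim(volume)) == 4L) volume[, , , 1] else volume
  s <- apply(ch, 3L, mean)
  even <- mean(s[seq(1, length(s), by = 2)])
  odd <- mean(s[seq(2, length(s), by = 2)])
  abs(even - odd) / (even + odd)
}

#' Generate synthetic white-matter bundle profiles
#'
#' For each participant, FA and MD are sampled at 100 nodes along each of
#' the 24 bundles: a fixed node-wise template per (bundle, metric) plus a
#' node-varying logarithmic age trend, additive and multiplicative site
#' effects, and i.i.d. noise. Each profile is then shrunk toward its own
#' mean by a factor proportional to `1 - q` ("flattening": low-quality data
#' looks artifactually homogeneous along the bundle) and MD receives a small
#' artifactual downward shift proportional to `1 - q`, so that poor quality
#' mimics maturation. A `missing_rate` fraction of (participant, bundle)
#' pairs is dropped to exercise imputation.
#'
#' @param cohort a `latent_cohort`.
#' @param site_effects list with `location_sd` and `scale_sd` of the
#'   per-(site, metric) additive and multiplicative effects; 0 disables.
#' @param missing_rate fraction in \[0,1) of (participant, bundle) pairs
#'   dropped.
#' @param flatten shrinkage coefficient `s`: profile deviations from the
#'   profile mean are multiplied by `1 - s * (1 - q)`. Set 0 to disable the
#'   quality dependence (negative control).
#' @param md_bias artifactual MD decrease at `q = 0` (same units as MD).
#' @param distort artifactual apparent-age corruption: each participant's
#'   log-age entering the maturation trend is shifted by a draw with
#'   standard deviation `distort * min(1, 2 (1 - q)^2)` (log-year units), so
#'   clearly bad scans look artifactually older or younger while good scans
#'   are untouched. Set 0 to disable (negative control).
#' @param noise_sd node-wise noise standard deviation (FA units; MD noise is
#'   scaled by the MD template magnitude).
#' @param seed integer seed.
#' @return long data frame (`participant_id`, `bundle`, `metric`, `node`,
#'   `value`) with `node` in 0..99; a complete participant has exactly
#'   24 x 2 x 100 = 4,800 values.
#' @export
generate_bundle_profiles <- function(cohort,
                                     site_effects = list(location_sd = 0.02,
                                                         scale_sd = 0.03),
                                     missing_rate = 0, flatten = 0.8,
                                     md_bias = 0.06, distort = 0.5,
                                     noise_sd = 0.015, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  set.seed(seed)
  bundles <- bundle_names()
  nodes <- 0:99
  tmpl <- bundle_templates()
  sites <- unique(cohort$site)
  site_loc <- matrix(stats::rnorm(length(sites) * 2, 0,
                                  site_effects$location_sd),
                     length(sites), 2, dimnames = list(sites, c("FA", "MD")))
  site_scl <- matrix(1 + stats::rnorm(length(sites) * 2, 0,
                                      site_effects$scale_sd),
                     length(sites), 2, dimnames = list(sites, c("FA", "MD")))
  n <- nrow(cohort)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- bundles[stats::runif(length(bundles)) >= missing_rate]
    if (length(keep) == 0L) keep <- bundles[1]
    shrink <- 1 - flatten * (1 - cohort$q[i])
    la <- log(cohort$age[i]) +
      distort * min(1, 2 * (1 - cohort$q[i])^2) * stats::rnorm(1)
    rows <- lapply(keep, function(b) {
      t_b <- tmpl[[b]]
      fa <- t_b$fa + 0.055 * la * t_b$age_w +
        site_loc[cohort$site[i], "FA"] +
        stats::rnorm(100, 0, noise_sd)
      fa <- fa * site_scl[cohort$site[i], "FA"]
      md <- t_b$md - 0.09 * la * t_b$age_w +
        site_loc[cohort$site[i], "MD"] +
        stats::rnorm(100, 0, noise_sd * 1.5)
      md <- md * site_scl[cohort$site[i], "MD"]
      fa <- mean(fa) + shrink * (fa - mean(fa))
      md <- mean(md) + shrink * (md - mean(md)) - md_bias * (1 - cohort$q[i])
      data.frame(
        participant_id = cohort$participant_id[i],
        bundle = b,
        metric = rep(c("FA", "MD"), each = 100),
        node = c(nodes, nodes),
        value = c(fa, md),
        stringsAsFactors = FALSE
      )
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

# Fixed node-wise templates: 1-3 Gaussian bumps per bundle on a common
# baseline, plus a node-varying age-trend weight. Deterministic (internal
# fixed seed) so templates are a property of the schema, not of the cohort.
bundle_templates <- function() {
  nodes <- seq(0, 1, length.out = 100)
  bundles <- bundle_names()
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(20220)
  tmpl <- lapply(seq_along(bundles), function(i) {
    k <- sample(1:3, 1)
    ctr <- stats::runif(k, 0.15, 0.85)
    wid <- stats::runif(k, 0.05, 0.2)
    amp <- stats::runif(k, 0.05, 0.15) * sample(c(-1, 1), k, replace = TRUE)
    bump <- rowSums(vapply(seq_len(k), function(j) {
      amp[j] * exp(-(nodes - ctr[j])^2 / (2 * wid[j]^2))
    }, numeric(100)))
    aw_ctr <- stats::runif(1, 0.2, 0.8)
    aw <- exp(-(nodes - aw_ctr)^2 / (2 * 0.15^2))
    list(
      fa = 0.45 + bump,
      md = 0.85 - bump,
      # age trend is zero-mean across nodes: maturation reshapes the
      # profile rather than shifting it, so profile flattening destroys it
      age_w = aw - mean(aw)
    )
  })
  names(tmpl) <- bundles
  tmpl
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
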