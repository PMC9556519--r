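test_that("cohort generation is deterministic and validates proportions", {
  a <- generate_cohort(50, seed = 3)
  b <- generate_cohort(50, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(50, seed = 4)))
  expect_error(generate_cohort(10, site_proportions = c(RU = 0.5, SI = 0.2)),
               "sum to 1")
  expect_error(generate_cohort(0), ">= 1")
  expect_error(generate_cohort(10, age_quality_corr = 1), "age_quality_corr")
})

test_that("latent quality has the declared marginal structure", {
  co <- generate_cohort(2000, age_quality_corr = 0.31, seed = 11)
  expect_true(all(co$q >= 0 & co$q <= 1))
  expect_identical(co$true_label, as.integer(co$q >= 0.5))
  expect_lt(abs(cor(co$age, co$q) - 0.31), 0.05)
  co0 <- generate_cohort(2000, age_quality_corr = 0, seed = 11)
  expect_lt(abs(cor(co0$age, co0$q)), 0.05)
  # q independent of sex and site by construction
  expect_gt(stats::kruskal.test(co$q, factor(co$site))$p.value, 0.001)
  expect_gt(stats::wilcox.test(co$q ~ factor(co$sex))$p.value, 0.001)
})

test_that("pass fraction responds monotonically to the quality shape", {
  frac <- vapply(c(1, 2.5, 6), function(s1) {
    mean(generate_cohort(1500, q_shape1 = s1, seed = 5)$true_label)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("metrics table has the full schema and the expected sign structure", {
  co <- generate_cohort(600, seed = 2)
  m <- generate_metrics(co, seed = 2)
  expect_identical(colnames(m), c("participant_id", qc_metric_names()))
  expect_length(qc_metric_names(), 31L)
  expect_gt(cor(m$raw_neighbor_corr, co$q, method = "spearman"), 0)
  expect_lt(cor(m$max_rel_translation, co$q, method = "spearman"), 0)
  expect_lt(cor(m$raw_num_bad_slices, co$q, method = "spearman"), 0)
  expect_true(all(m$raw_num_bad_slices >= 0))
  expect_true(all(m$raw_num_bad_slices == round(m$raw_num_bad_slices)))
  # acquisition descriptors are constant within site
  for (s in unique(co$site)) {
    expect_equal(stats::var(m$raw_voxel_size_x[co$site == s]), 0)
    expect_equal(stats::var(m$raw_max_b[co$site == s]), 0)
  }
  expect_error(generate_metrics(co, noise_sd = -1), "nonnegative")
  expect_error(generate_metrics(co[0, ]), "nonempty")
})

test_that("noiseless metrics are deterministic monotone transforms of q", {
  co <- generate_cohort(100, seed = 9)
  m1 <- generate_metrics(co, noise_sd = 0, seed = 1)
  m2 <- generate_metrics(co, noise_sd = 0, seed = 99)
  expect_equal(m1, m2)
  ord <- order(co$q)
  expect_true(all(diff(m1$raw_neighbor_corr[ord]) >= 0))
  expect_true(all(diff(m1$max_rel_translation[ord]) <= 0))
})

test_that("expert ratings live on the 5-level scale and track quality", {
  co <- generate_cohort(150, seed = 4)
  r <- simulate_expert_ratings(co, seed = 4)
  expect_true(all(r %in% -2:2))
  expect_identical(dim(r), c(150L, 6L))
  # noiseless, unbiased raters are identical and kappa = 1
  r0 <- simulate_expert_ratings(co, bias_sd = 0, noise_sd = 0, seed = 1)
  expect_true(all(r0 == r0[, 1]))
  km <- pairwise_kappa_matrix(r0[, 1:2])
  expect_equal(km[1, 2], 1)
  # q = 1 boundary rates "definitely pass"
  top <- manual_cohort(rep(1, 5))
  expect_true(all(simulate_expert_ratings(top, bias_sd = 0, noise_sd = 0) == 2L))
  expect_error(simulate_expert_ratings(co, n_experts = 1), ">= 2")
})

test_that("default expert noise lands in the moderate-agreement regime", {
  co <- generate_cohort(200, seed = 8)
  ks <- vapply(1:3, function(s) {
    km <- pairwise_kappa_matrix(simulate_expert_ratings(co, seed = s))
    mean(km[upper.tri(km)])
  }, numeric(1))
  expect_true(all(ks > 0.5 & ks < 0.8))
})

test_that("rater noise monotonically degrades agreement", {
  co <- generate_cohort(200, seed = 8)
  mean_k <- vapply(c(0.05, 0.15, 0.3), function(nsd) {
    mean(vapply(1:3, function(s) {
      km <- pairwise_kappa_matrix(
        simulate_expert_ratings(co, noise_sd = nsd, seed = s)
      )
      mean(km[upper.tri(km)])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_k) < 0))
})

test_that("community ratings: oracle rater, optimism, and rating density", {
  co <- generate_cohort(120, seed = 6)
  oracle <- data.frame(sensitivity = 1, specificity = 1)
  cr <- simulate_community_ratings(co, n_raters = 1, rater_reliability = oracle,
                                   optimism = 0, coverage = 1, seed = 6)
  truth <- co$true_label[match(cr$participant_id, co$participant_id)]
  expect_identical(cr$rating, truth)
  expect_true(all(cr$rating %in% 0:1))
  # defaults: about 200 ratings per participant (sparse random assignment)
  cr2 <- simulate_community_ratings(co, seed = 6)
  expect_equal(nrow(cr2) / nrow(co), 200, tolerance = 0.15)
  # community raters are less conservative than the experts
  expert_pass <- mean(aggregate_expert(simulate_expert_ratings(co, seed = 1))$binary)
  expect_gt(mean(cr2$rating), expert_pass)
  expect_error(simulate_community_ratings(co, optimism = -0.1), "nonnegative")
})

test_that("phantom volumes carry banding and oriented bundles", {
  v1 <- generate_volume(1, seed = 2)
  v0 <- generate_volume(0, seed = 2)
  expect_identical(dim(v1), c(32L, 32L, 32L, 4L))
  expect_true(all(is.finite(v1)) && all(is.finite(v0)))
  expect_true(all(v1[, , , 2:4] >= 0 & v1[, , , 2:4] <= 1))
  # artifact-free limit: adjacent-slice modulation near zero
  expect_lt(slice_alternation(v1), 0.02)
  # full-severity banding exceeds the configured depth floor
  expect_gte(slice_alternation(v0), 0.2)
  # orientation encoding: each tube's energy is maximal in its own channel
  masks <- attr(v1, "bundle_masks")
  for (ch in c(x = 2L, y = 3L, z = 4L)) {
    nm <- names(which(c(x = 2L, y = 3L, z = 4L) == ch))
    sums <- vapply(2:4, function(k) sum(v1[, , , k][masks[[nm]]]), numeric(1))
    expect_equal(which.max(sums), ch - 1L)
  }
  expect_error(generate_volume(1.2), "in \\[0, 1\\]")
  expect_error(generate_volume(0.5, shape = c(8, 32, 32)), ">= 16")
  expect_identical(generate_volume(0.4, seed = 5), generate_volume(0.4, seed = 5))
})

test_that("bundle profiles: completeness, clean limit, flattening", {
  co <- generate_cohort(5, seed = 3)
  pr <- generate_bundle_profiles(co, seed = 3)
  expect_equal(sum(pr$participant_id == co$participant_id[1]), 4800)
  expect_setequal(unique(pr$bundle), bundle_names())
  expect_length(bundle_names(), 24L)

  # q = 1, no site effects, no noise: profile equals template + age trend
  c1 <- manual_cohort(1, age = 12)
  p1 <- generate_bundle_profiles(
    c1, site_effects = list(location_sd = 0, scale_sd = 0), noise_sd = 0,
    seed = 1
  )
  tmpl <- hybridqc:::bundle_templates()
  for (b in c("UNC_L", "Motor")) {
    fa <- p1$value[p1$bundle == b & p1$metric == "FA"]
    expect_equal(fa, tmpl[[b]]$fa + 0.055 * log(12) * tmpl[[b]]$age_w,
                 tolerance = 1e-12)
  }

  # within-profile node variance decreases monotonically as q decreases
  vr <- vapply(c(1, 0.5, 0), function(qv) {
    p <- generate_bundle_profiles(manual_cohort(qv), seed = 5)
    stats::var(p$value[p$bundle == "ARC_L" & p$metric == "FA"])
  }, numeric(1))
  expect_true(all(diff(vr) < 0))

  # missing bundles are dropped at the requested rate
  co2 <- generate_cohort(80, seed = 4)
  pm <- generate_bundle_profiles(co2, missing_rate = 0.2, seed = 4)
  observed <- nrow(pm) / (nrow(co2) * 4800)
  expect_lt(abs(observed - 0.8), 0.05)
  expect_error(generate_bundle_profiles(co, missing_rate = 1), "missing_rate")
})
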