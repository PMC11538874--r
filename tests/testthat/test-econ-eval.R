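test_that("SURE with identical regressors equals per-equation OLS", {
  set.seed(5)
  n <- 120
  X <- cbind(1, rep(0:1, each = n / 2), stats::rnorm(n))
  y1 <- X %*% c(100, -40, 5) + stats::rnorm(n, 0, 50)
  y2 <- X %*% c(0.3, 0.02, 0.1) + stats::rnorm(n, 0, 0.05)
  f <- stressecon:::.sure_fgls(X, drop(y1), X, drop(y2))
  ols1 <- stats::lm.fit(X, drop(y1))$coefficients
  ols2 <- stats::lm.fit(X, drop(y2))$coefficients
  expect_equal(unname(f$coef_cost), unname(ols1), tolerance = 1e-8)
  expect_equal(unname(f$coef_effect), unname(ols2), tolerance = 1e-8)
})

test_that("SURE recovers the generating incremental cost and effect", {
  ds <- generate_trial(trial_config(n_per_arm = 4000, seed = 611))
  f <- fit_sure(analysis_frame(ds$records), effect = "qaly")
  # truths: -38 euro, 0.015 QALYs; SEs at n = 4000/arm ~ 50 and 0.0012
  expect_lt(abs(f$delta_cost - (-38)), 160)
  expect_lt(abs(f$delta_effect - 0.015), 0.004)
})

test_that("SURE rejects singular designs", {
  fr <- constant_frame()
  fr$baseline_total_cost <- 1  # constant column, collinear with intercept
  expect_error(fit_sure(fr), "singular design")
})

test_that("degenerate within-arm data collapse the bootstrap cloud", {
  fr <- constant_frame()
  frames <- list(fr, fr)
  cl <- bootstrap_cea(frames, B = 40, effect = "qaly", seed = 3)
  expect_equal(unname(cl$pairs[, "delta_cost"]), rep(-175, 40))
  expect_equal(unname(cl$pairs[, "delta_effect"]), rep(0.02, 40))
  expect_equal(cl$point_estimate$delta_cost$estimate, -175)
})

test_that("bootstrap allocation and consistency", {
  expect_error(bootstrap_cea(fix_frames, B = 2), "must be >=")
  cl1 <- bootstrap_cea(fix_frames, B = 3, effect = "qaly", seed = 1)
  expect_equal(nrow(cl1$pairs), 3)

  cl <- bootstrap_cea(fix_frames, B = 600, effect = "qaly", seed = 2)
  pe <- cl$point_estimate$delta_cost
  boot_se <- stats::sd(cl$pairs[, 1])
  expect_lt(abs(mean(cl$pairs[, 1]) - pe$estimate), 3 * boot_se)
  # same seed, same cloud
  cl2 <- bootstrap_cea(fix_frames, B = 600, effect = "qaly", seed = 2)
  expect_identical(cl$pairs, cl2$pairs)
})

test_that("BCa reduces to the percentile interval in the symmetric limit", {
  reps <- 1:1000
  got <- bca_ci(reps, point_estimate = 500.5)
  expect_equal(got, stats::quantile(reps, c(0.025, 0.975), names = FALSE),
               tolerance = 1e-8)
  expect_equal(bca_ci(rep(7, 200), 7), c(7, 7))
  expect_warning(bca_ci(1:50, 25), "fewer than 100")

  # agreement with an established implementation on a mean statistic
  set.seed(11)
  x <- stats::rgamma(60, 2, 0.1)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  got <- bca_ci(bt$t[, 1], mean(x), jack)
  expect_equal(got, ref, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("ICER taxonomy covers all quadrants", {
  expect_equal(icer(-38, 0.39)$label, "dominant")
  expect_equal(icer(100, -0.1)$label, "dominated")
  r <- icer(162, 0.39)
  expect_equal(r$label, "ratio")
  expect_equal(r$value, 162 / 0.39)
  expect_equal(icer(0, 0.1)$label, "dominant")
  expect_equal(icer(10, 0)$label, "undefined")
  sw <- icer(-100, -0.1)
  expect_equal(sw$label, "southwest_ratio")
})

test_that("the CE plane partition is exhaustive and exclusive", {
  all_se <- cbind(rep(-10, 5), rep(0.1, 5))
  expect_equal(ce_plane_distribution(all_se),
               c(NE = 0, SE = 100, SW = 0, NW = 0))
  four <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1))
  expect_equal(ce_plane_distribution(four),
               c(NE = 25, SE = 25, SW = 25, NW = 25))
  set.seed(3)
  cloud <- cbind(stats::rnorm(500), stats::rnorm(500))
  expect_equal(sum(ce_plane_distribution(cloud)), 100)
  expect_error(ce_plane_distribution(cloud[0, , drop = FALSE]), "empty")
})

test_that("the CEAC is the net-benefit exceedance curve", {
  one <- cbind(10, 1)
  expect_equal(ceac(one, c(10))$probability, 0)
  expect_equal(ceac(one, c(10.01))$probability, 1)
  expect_error(ceac(one, -5), ">= 0")

  set.seed(4)
  cloud <- cbind(stats::rnorm(400, 0, 100), stats::runif(400, 0.01, 0.5))
  cv <- ceac(cloud, seq(0, 5000, 100))
  # lambda = 0: probability of cost savings = SE + SW share
  q <- ce_plane_distribution(cloud)
  expect_equal(cv$probability[1], unname(q["SE"] + q["SW"]) / 100)
  # all delta-effects positive: monotone non-decreasing, tends to 1
  expect_true(all(diff(cv$probability) >= 0))
  expect_equal(ceac(cloud, 1e9)$probability, 1)
})

test_that("logistic effect matches the contingency-table odds ratio", {
  arm <- rep(c("intervention", "control"), each = 100)
  sf <- c(rep(1, 50), rep(0, 50), rep(1, 25), rep(0, 75))
  fr <- data.frame(arm = arm, symptom_free = sf)
  out <- logistic_effect(list(fr, fr))
  expect_equal(out$odds_ratio, (50 * 75) / (50 * 25), tolerance = 1e-6)

  fr_eq <- data.frame(arm = arm,
                      symptom_free = rep(c(1, 0), 100))
  expect_equal(logistic_effect(list(fr_eq, fr_eq))$odds_ratio, 1,
               tolerance = 1e-6)
})

test_that("net-benefit moderation recovers a built-in interaction", {
  # lambda = 0: NB = -C, so moderation is cost moderation with sign flip
  ds <- generate_trial(trial_config(n_per_arm = 1500, seed = 911,
                                    gender_cost_interaction_eur = 2000))
  fr <- analysis_frame(ds$records)
  md <- nbrf_moderation(list(fr, fr), lambda = 0, moderators = "gender")
  # female intervention participants carry +2000 cost -> NB 2000 lower;
  # the treat:gendermale contrast is therefore +2000
  expect_equal(md$term, "treat:gendermale")
  expect_lt(abs(md$estimate - 2000), 600)

  expect_error(nbrf_moderation(list(fr), lambda = -1, "gender"), "lambda")
  fr$const <- 1
  expect_error(nbrf_moderation(list(fr, fr), 0, "const"), "constant")
  expect_error(nbrf_moderation(list(fr, fr), 0, "nope"), "absent")
})

test_that("net benefit arithmetic underlies the moderation outcome", {
  fr <- constant_frame(qaly_int = 0.315, qaly_ctl = 0.3,
                       cost_int = 2000, cost_ctl = 2038)
  fr$nb <- fr$qaly * 20000 - fr$societal_total
  d_nb <- incremental_difference(fr$nb, fr$arm)
  expect_equal(d_nb, 0.015 * 20000 + 38)
})

test_that("run_cea assembles a coherent result", {
  r <- run_cea(fix_frames, B = 300, effect = "qaly", seed = 5,
               wtp_grid = seq(0, 20000, 1000))
  expect_s3_class(r, "cea_result")
  expect_equal(sum(r$quadrants), 100)
  expect_lte(r$ci_cost[1], r$ci_cost[2])
  expect_equal(nrow(r$ceac), 21)
  expect_true(all(r$ceac$probability >= 0 & r$ceac$probability <= 1))
})
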