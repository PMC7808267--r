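test_that("the noncentrality solver reproduces known values", {
  expect_equal(getncp(df = 5, alpha = 0.05, beta = 0.20, d = 1e-4,
                      start = 5), 12.8249, tolerance = 1e-3)
  # df = 1 has the classical closed form (z_{1-a/2} + z_{1-b})^2
  expect_equal(getncp(df = 1, alpha = 0.05, beta = 0.20, d = 1e-6),
               (qnorm(0.975) + qnorm(0.80))^2, tolerance = 1e-3)
  # result independent of the starting point
  expect_equal(getncp(5, 0.05, 0.20, 1e-4, start = 0.5),
               getncp(5, 0.05, 0.20, 1e-4, start = 80), tolerance = 1e-6)
})

test_that("the solved noncentrality attains the targeted power", {
  for (df in c(2, 5, 9)) for (beta in c(0.1, 0.2)) {
    l <- getncp(df, 0.05, beta, d = 1e-6)
    crit <- qchisq(0.95, df)
    expect_equal(pchisq(crit, df, ncp = l, lower.tail = FALSE), 1 - beta,
                 tolerance = 1e-5)
  }
})

test_that("the noncentrality parameter moves the right way", {
  grid_df <- c(1, 3, 5, 9)
  v <- vapply(grid_df, function(df) getncp(df, 0.05, 0.20, 1e-6), 1)
  expect_true(all(diff(v) > 0))                        # increasing in df
  v <- vapply(c(0.3, 0.2, 0.1, 0.05), function(b)
    getncp(5, 0.05, b, 1e-6), 1)
  expect_true(all(diff(v) > 0))                        # increasing in power
  v <- vapply(c(0.01, 0.05, 0.10), function(a)
    getncp(5, a, 0.20, 1e-6), 1)
  expect_true(all(diff(v) < 0))                        # decreasing in alpha
})

test_that("design-stage strategy values come from response-weighted means", {
  m <- design_moments(codiacs_sim())
  expect_equal(unname(m$theta),
               c(6, 5.5, 9.5, 9, 14.5, 10.5, 13, 9))
  # delta-method per-subject variance of the first strategy value
  expect_equal(m$sigma[1, 1], 0.25 * (100 / 0.125) * 2 + 0.5 * (11 - 1)^2)
  expect_equal(m$sigma[1, 1], 450)
})

test_that("the design covariance is block-diagonal across stage-1 arms", {
  set.seed(411)
  for (i in 1:5) {
    m <- design_moments(random_sim())
    arm <- m$strategies$d0
    cross <- outer(arm, arm, "!=")
    expect_true(all(m$sigma[cross] == 0))
    expect_equal(m$sigma, t(m$sigma))
    expect_true(all(eigen(m$sigma, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
  }
  mi <- design_moments(codiacs_sim(), method = "ipw")
  expect_true(all(mi$sigma[1:4, 5:8] == 0))
})

test_that("rank structure: contrast covariance has rank df", {
  m <- design_moments(codiacs_sim())
  C <- smartats:::contrast_matrix(8)
  expect_equal(numerical_rank(C %*% m$sigma %*% t(C)), 5)
  expect_equal(numerical_rank(m$sigma), 6)  # one extra dimension: the level
})

test_that("the effect size is scale- and shift-invariant", {
  sim <- codiacs_sim()
  d0 <- effect_size(design_moments(sim))
  sim2 <- sim; sim2$MEAN <- sim$MEAN * 3; sim2$SD <- sim$SD * 3
  expect_equal(effect_size(design_moments(sim2)), d0, tolerance = 1e-10)
  sim3 <- sim; sim3$MEAN <- sim$MEAN + 100
  expect_equal(effect_size(design_moments(sim3)), d0, tolerance = 1e-8)
  null <- sim; null$MEAN <- 7
  expect_error(effect_size(design_moments(null)), "null design")
})

test_that("the effect size matches a Monte Carlo oracle for the Wald mean", {
  # Under the alternative, Q is approximately noncentral chi-squared with
  # mean n*Delta + df; estimate the mean by simulation and compare.
  sim <- codiacs_sim()
  des <- smart_design(sim)
  ctx <- smartats:::design_context(des)
  delta <- effect_size(design_moments(sim))
  df <- smart_df(des)
  n <- 1000; reps <- 300
  C <- smartats:::contrast_matrix(8)
  set.seed(412)
  Q <- replicate(reps, {
    dat <- sim_smart(des, n)
    f <- smartats:::fit_gcomp(dat, des, ctx = ctx)
    ct <- drop(C %*% f$theta)
    drop(t(ct) %*% MASS::ginv(C %*% f$sigma %*% t(C)) %*% ct)
  })
  se <- sd(Q) / sqrt(reps)
  expect_lt(abs(mean(Q) - (n * delta + df)), 4 * se)
})

test_that("global sizing reproduces the worked depression-trial example", {
  res <- smartsize(delta = 0.1213, df = 5, alpha = 0.05, beta = 0.20)
  expect_equal(res$NCP, 12.8249, tolerance = 1e-3)
  expect_identical(res$N, 106L)
})

test_that("the SIM input path is self-consistent with its components", {
  sim <- codiacs_sim()
  res <- smartsize(sim = sim)
  expect_identical(res$df, 5L)
  expect_equal(res$delta, effect_size(design_moments(sim)))
  expect_identical(res$N, as.integer(ceiling(res$NCP / res$delta)))
})

test_that("pairwise sizing matches the two-arm normal approximation", {
  expect_identical(smartsize(delta = 0.90, global = FALSE)$n_per_ats, 20L)
  expect_identical(smartsize(delta = 0.20, global = FALSE)$n_per_ats,
                   as.integer(ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2 /
                                        0.04)))
  # Bonferroni-adjusted alpha via ntest increases n
  expect_gt(smartsize(delta = 0.9, global = FALSE, ntest = 28)$n_per_ats, 20)
})

test_that("required N responds monotonically to the design knobs", {
  n_of <- function(delta = 0.12, alpha = 0.05, beta = 0.2)
    smartsize(delta = delta, df = 5, alpha = alpha, beta = beta)$N
  expect_true(all(diff(vapply(c(0.08, 0.12, 0.2), function(d) n_of(d),
                              1L)) <= 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.1), function(a)
    n_of(alpha = a), 1L)) <= 0))
  expect_true(all(diff(vapply(c(0.3, 0.2, 0.1), function(b)
    n_of(beta = b), 1L)) >= 0))
  expect_error(smartsize(df = 5), "delta")
  expect_error(smartsize(global = FALSE), "delta")
})
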