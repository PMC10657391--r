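test_that("segregation test equals the hand-computed Pearson statistic", {
  st <- segregation_test(c(a = 100, b = 100, c = 0), c(0.25, 0.5, 0.25))
  expect_equal(st$statistic, 100)
  expect_equal(st$df, 2L)
  expect_equal(segregation_test(c(a = 50, b = 100, c = 50),
                                c(0.25, 0.5, 0.25))$statistic, 0)
  st2 <- segregation_test(c(a = 52, b = 48), c(0.5, 0.5))
  expect_equal(st2$statistic, 0.16)
  expect_equal(st2$df, 1L)

  # independent oracle: stats::chisq.test on random tables
  set.seed(501)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    obs <- rmultinom(1, sample(50:400, 1), rep(1 / k, k))[, 1]
    names(obs) <- letters[1:k]
    pr <- rgamma(k, 2); pr <- pr / sum(pr)
    mine <- segregation_test(obs, pr, exact_max_n = 0)
    ref <- suppressWarnings(chisq.test(obs, p = pr))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("exact multinomial tail matches the exact binomial for two classes", {
  set.seed(502)
  for (i in 1:5) {
    n <- sample(20:120, 1)
    x <- rbinom(1, n, 0.5)
    p <- runif(1, 0.2, 0.8)
    mine <- segregation_test(c(a = x, b = n - x), c(p, 1 - p))
    ref <- binom.test(x, n, p)
    expect_equal(mine$exact_p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("impossible classes flag an infinite statistic with exact fallback", {
  st <- segregation_test(c(a = 10, b = 5, c = 1), c(0.7, 0.3, 0))
  expect_equal(st$statistic, Inf)
  expect_equal(st$p_value, 0)
  expect_equal(st$exact_p, 0)
})

test_that("killing-efficiency MLE matches the closed form and a grid-search oracle", {
  cnt <- ta_counts(c(`1M1M` = 4940, `1D1M` = 4952, `1D1D` = 108),
                   design = "self_het")
  fit <- fit_killing_efficiency(cnt)
  # exact MLE: the het class prob is 1/2 whatever k, so only MM vs DD inform k
  expect_equal(unname(coef(fit)), (4940 - 108) / 4940, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), 0.978, tolerance = 5e-4)
  # the double-null proportion inversion agrees to first order
  p_dd <- 108 / 10000
  expect_equal((1 - 4 * p_dd) / (1 - 2 * p_dd), unname(coef(fit)),
               tolerance = 5e-4)

  # grid-search ML oracle over k in {0, 1e-4, ..., 1}
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(k) {
    m <- 1 / (2 - k); d <- (1 - k) / (2 - k)
    dmultinom(c(4940, 4952, 108),
              prob = c(0.5 * m, 0.5 * m + 0.5 * d, 0.5 * d), log = TRUE)
  }, numeric(1))
  expect_equal(unname(coef(fit)), grid[which.max(ll)], tolerance = 1e-4)
  expect_true(fit$ci["k", 1] <= coef(fit) && coef(fit) <= fit$ci["k", 2])
})

test_that("a zero double-null count gives the boundary estimate k = 1", {
  cnt <- ta_counts(c(`1M1M` = 210, `1D1M` = 190, `1D1D` = 0),
                   design = "self_het")
  fit <- fit_killing_efficiency(cnt)
  expect_equal(unname(coef(fit)), 1)
  expect_true(fit$boundary)
  expect_equal(fit$ci["k", 2], 1)
  expect_lt(fit$ci["k", 1], 1)
  expect_error(ta_counts(c(`1M1M` = 0, `1D1M` = 0, `1D1D` = 0)), "all zero")
})

test_that("analytic design probabilities agree with the crossing module", {
  for (k in c(0, 0.3, 0.7, 0.978, 1)) {
    pan <- p1(k)
    het <- ta_genotype("1M1D", pan)
    d_self <- self_progeny(het, pan)
    info <- tadote:::.design_info("self_het")
    pr <- info$probs(k)
    names(pr) <- info$labels
    for (lab in info$labels)
      expect_equal(unname(pr[lab]), prob_of(d_self, lab), tolerance = 1e-12)
    d_tc <- cross(ta_genotype("1D1D", pan), het, pan)
    info_tc <- tadote:::.design_info("testcross")
    pr_tc <- info_tc$probs(k)
    names(pr_tc) <- info_tc$labels
    for (lab in info_tc$labels)
      expect_equal(unname(pr_tc[lab]), prob_of(d_tc, lab), tolerance = 1e-12)
  }
})

test_that("killing efficiency is recovered from simulated counts", {
  cnt <- gen_cross_counts("self_het", n = 5000, seed = 11, k = 0.9)
  fit <- fit_killing_efficiency(cnt)
  expect_lt(abs(coef(fit) - 0.9), 0.02)
  # testcross design fits too
  cnt_tc <- gen_cross_counts("testcross", n = 5000, seed = 12, k = 0.9)
  fit_tc <- fit_killing_efficiency(cnt_tc)
  expect_lt(abs(coef(fit_tc) - 0.9), 0.03)
})

test_that("the estimator is consistent: error shrinks as the sample grows", {
  err <- lapply(c(200, 2000, 20000), function(n) {
    khats <- vapply(1:200, function(r) {
      cnt <- gen_cross_counts("self_het", n = n, seed = 7000 + r, k = 0.9)
      unname(coef(fit_killing_efficiency(cnt)))
    }, numeric(1))
    c(rmse = sqrt(mean((khats - 0.9)^2)), bias = abs(mean(khats) - 0.9))
  })
  rmse <- vapply(err, `[[`, numeric(1), "rmse")
  bias <- vapply(err, `[[`, numeric(1), "bias")
  expect_true(all(diff(rmse) < 0))   # strictly shrinking error
  # the MLE is near-unbiased at every n; any residual bias is within
  # Monte-Carlo noise and vanishes at large n
  expect_true(all(bias < 0.01))
  expect_lt(bias[3], 0.002)
})

test_that("female-weight MLE is the vector of sample proportions", {
  even <- fit_female_weights(ta_counts(c(A = 25, B = 25, C = 25, D = 25),
                                       design = "f2_double_het"), seed = 1)
  expect_equal(unname(coef(even)), rep(0.25, 4))
  expect_equal(even$null_test$statistic, 0)

  fw <- fit_female_weights(ta_counts(c(A = 10, B = 20, C = 30, D = 40),
                                     design = "f2_double_het"), seed = 1)
  expect_equal(unname(coef(fw)), c(0.1, 0.2, 0.3, 0.4))
  expect_true(all(fw$ci[, 1] <= coef(fw) & coef(fw) <= fw$ci[, 2]))

  # closed form vs numeric optimiser (multinomial logit parameterisation,
  # analytic gradient so the optimum is sharp)
  cn <- c(10, 20, 30, 40)
  nll <- function(th) {
    p <- exp(c(0, th)); p <- p / sum(p)
    -sum(cn * log(p))
  }
  gr <- function(th) {
    p <- exp(c(0, th)); p <- p / sum(p)
    (sum(cn) * p - cn)[-1]
  }
  opt <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  p_opt <- exp(c(0, opt$par)); p_opt <- p_opt / sum(p_opt)
  expect_equal(unname(coef(fw)), p_opt, tolerance = 1e-8)

  zero <- fit_female_weights(ta_counts(c(A = 0, B = 30, C = 30, D = 40),
                                       design = "f2_double_het"), seed = 1)
  expect_equal(unname(coef(zero))[1], 0)
  expect_true(zero$boundary)
})

test_that("the transmission-bias LRT has power and calibrated size", {
  # power at a real bias
  w <- female_weights(c("1D/7M" = 0.15, "1M/7M" = 0.2, "1D/7D" = 0.25,
                        "1M/7D" = 0.4))
  rejections <- vapply(1:200, function(r) {
    cnt <- gen_cross_counts("f2_double_het", n = 600, seed = 9000 + r,
                            weights = w)
    fit_female_weights(cnt, seed = r)$null_test$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejections), 0.9)

  # size under the uniform null
  size <- vapply(1:500, function(r) {
    cnt <- gen_cross_counts("f2_double_het", n = 400, seed = 20000 + r)
    fit_female_weights(cnt, seed = r)$null_test$p_value < 0.05
  }, logical(1))
  expect_gte(mean(size), 0.02)
  expect_lte(mean(size), 0.08)
})

test_that("goodness-of-fit report joins observed and model-expected counts", {
  p <- p1()
  d <- self_progeny(het1(), p)
  perfect <- ta_counts(c(`1D1M` = 100, `1M1M` = 100), design = "self_het")
  rep1 <- goodness_of_fit(perfect, d)
  expect_equal(rep1$residual, c(0, 0))
  expect_equal(attr(rep1, "test")$statistic, 0)

  # under the fitted k the model usually fits its own simulated data
  ok <- vapply(1:100, function(r) {
    cnt <- gen_cross_counts("self_het", n = 2000, seed = 31000 + r, k = 0.978)
    fit <- fit_killing_efficiency(cnt)
    pr <- predict(fit)
    attr(goodness_of_fit(cnt, structure(
      data.frame(genotype = pr$class, probability = pr$probability),
      class = c("ta_progeny", "data.frame"))), "test")$p_value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  bad <- ta_counts(c(`1D1M` = 100, `oops` = 100))
  fitlike <- self_progeny(ta_genotype("1M1D", p1(0.5)), p1(0.5))
  expect_error(goodness_of_fit(bad, fitlike), "missing from the count table")
})

test_that("profile-likelihood intervals achieve near-nominal coverage", {
  covered <- vapply(1:500, function(r) {
    cnt <- gen_cross_counts("self_het", n = 2000, seed = 40000 + r, k = 0.9)
    ci <- fit_killing_efficiency(cnt)$ci
    ci["k", 1] <= 0.9 && 0.9 <= ci["k", 2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("ta_fit methods expose the usual modelling interface", {
  cnt <- gen_cross_counts("self_het", n = 1000, seed = 77, k = 0.9)
  fit <- fit_killing_efficiency(cnt)
  pr <- predict(fit)
  expect_equal(sum(pr$probability), 1, tolerance = 1e-12)
  expect_equal(sum(pr$expected), fit$n, tolerance = 1e-9)
  expect_length(residuals(fit), 3L)
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3L)
  expect_true(all(vapply(sims, function(s) sum(s$counts), numeric(1)) == fit$n))
  expect_identical(simulate(fit, nsim = 2, seed = 9)[[1]]$counts,
                   simulate(fit, nsim = 2, seed = 9)[[1]]$counts)
})

test_that("count tables round-trip through TSV", {
  cnt <- ta_counts(c(`1M1M` = 3, `1D1M` = 5, `1D1D` = 1), design = "self_het")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, path)
  back <- read_counts_tsv(path, design = "self_het")
  expect_equal(back$counts, cnt$counts)
  expect_equal(back$n, 9)
})
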