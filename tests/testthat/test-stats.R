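test_that("relative frequencies count into left-closed bins and sum to 100%", {
  fd <- relative_frequency(c(1, 1, 1, 3), 2)
  expect_equal(fd$freq, c(75, 25))
  expect_equal(fd$centers, c(1, 3))
  expect_equal(sum(fd$freq), 100)

  set.seed(8)
  x <- rexp(300, 1 / 20)
  fd2 <- relative_frequency(x, 5)
  expect_equal(sum(fd2$freq), 100, tolerance = 1e-9)

  # tortuosity-style origin at 1
  fd3 <- relative_frequency(c(1.05, 1.15, 1.25), 0.1, origin = 1)
  expect_equal(fd3$centers[1], 1.05)

  expect_error(relative_frequency(numeric(0), 1), "no values")
  expect_error(relative_frequency(c(1, 2), 0), "bin_width > 0")
})

test_that("binned exponential frequencies match the analytic CDF differences", {
  x <- sample_distribution("exponential", list(scale = 16.9), 1e4, seed = 12)
  fd <- relative_frequency(x, 5)
  edges <- seq(0, by = 5, length.out = length(fd$centers) + 1)
  analytic <- 100 * (pexp(edges[-1], 1 / 16.9) - pexp(edges[-length(edges)], 1 / 16.9))
  expect_lt(max(abs(fd$freq - analytic)), 2)
})

test_that("exponential-decay fit is exact on noise-free model points", {
  x <- seq(2.5, 97.5, by = 5)
  fd <- structure(list(centers = x, freq = (30 - 0) * exp(-0.1 * x) + 0,
                       counts = rep(1, length(x)), bin_width = 5,
                       n = length(x), origin = 0),
                  class = "FrequencyDistribution")
  fit <- fit_exponential_decay(fd)
  expect_equal(unname(fit$params["F0"]), 30, tolerance = 1e-6)
  expect_equal(unname(fit$params["K"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(fit$derived["lambda"]), 10, tolerance = 1e-5)
  # lambda = 1/K exactly
  expect_equal(fit$derived[["lambda"]], 1 / fit$params[["K"]])

  # flat distribution: flagged poor fit through r2
  fdf <- structure(list(centers = x, freq = rep(5, length(x)),
                        counts = rep(1, length(x)), bin_width = 5,
                        n = length(x), origin = 0),
                   class = "FrequencyDistribution")
  ff <- fit_exponential_decay(fdf)
  expect_true(is.na(ff$r2) || ff$r2 < 0.5)
})

test_that("gaussian fit is exact on noise-free model points and symmetric data", {
  x <- seq(0.5, 19.5, by = 1)
  fd <- structure(list(centers = x, freq = 10 * exp(-0.5 * ((x - 5) / 2)^2),
                       counts = rep(1, length(x)), bin_width = 1,
                       n = length(x), origin = 0),
                  class = "FrequencyDistribution")
  fit <- fit_gaussian(fd)
  expect_equal(unname(fit$params["A"]), 10, tolerance = 1e-6)
  expect_equal(unname(fit$params["mu"]), 5, tolerance = 1e-6)
  expect_equal(unname(fit$params["sigma"]), 2, tolerance = 1e-6)

  # symmetric closely-spaced two-spike data: the broad Gaussian centred at
  # the midpoint is the least-squares optimum (for well-separated spikes LS
  # instead locks onto one spike, so symmetry alone fixes mu only when the
  # spikes overlap within the fitted width)
  spikes <- structure(list(centers = 1:9, freq = c(0, 0, 0, 30, 30, 0, 0, 0, 0),
                           counts = rep(1, 9), bin_width = 1, n = 9, origin = 0),
                      class = "FrequencyDistribution")
  fs <- fit_gaussian(spikes)
  expect_equal(unname(fs$params["mu"]), 4.5, tolerance = 1e-2)

  expect_error(fit_gaussian(relative_frequency(c(1, 2), 1)), "4 bins")
})

test_that("lambda and mu are recovered from 10^4-sample distributions", {
  # median relative error over 20 seeds stays below 5%
  rel_l <- rel_m <- numeric(20)
  for (s in 1:20) {
    x <- sample_distribution("exponential", list(scale = 16.9), 1e4, seed = s)
    f <- fit_exponential_decay(relative_frequency(x, 5))
    rel_l[s] <- abs(f$derived[["lambda"]] - 16.9) / 16.9
    y <- sample_distribution("gaussian", list(mean = 4.81, sd = 2.52), 1e4,
                             seed = 100 + s)
    g <- fit_gaussian(relative_frequency(y[y >= 0], 1))
    rel_m[s] <- abs(g$params[["mu"]] - 4.81) / 4.81
  }
  expect_lt(median(rel_l), 0.05)
  expect_lt(median(rel_m), 0.05)
})

test_that("model comparison prefers the generating family and handles ties", {
  x <- seq(2.5, 97.5, by = 5)
  mk <- function(freq) structure(
    list(centers = x, freq = freq, counts = rep(1, length(x)), bin_width = 5,
         n = length(x), origin = 0), class = "FrequencyDistribution")
  fde <- mk(25 * exp(-0.08 * x))
  ce <- compare_fits(fit_exponential_decay(fde), fit_gaussian(fde))
  expect_equal(ce$preferred, "exp_decay")

  fdg <- mk(12 * exp(-0.5 * ((x - 40) / 12)^2))
  cg <- compare_fits(fit_exponential_decay(fdg), fit_gaussian(fdg))
  expect_equal(cg$preferred, "gaussian")

  # identical SSEs: F = 1, p = 0.5, tie flagged, first model by order wins
  fa <- fit_exponential_decay(fde)
  fb <- fa
  fb$model <- "gaussian"
  tie <- compare_fits(fa, fb)
  expect_equal(tie$f_stat, 1)
  expect_equal(tie$p, 0.5)
  expect_true(tie$tie)
  expect_equal(tie$preferred, "exp_decay")

  mismatched <- fit_gaussian(fdg)
  mismatched$n_bins <- 3L
  expect_error(compare_fits(fa, mismatched), "same frequency")
})

test_that("group curve comparison: identical groups give F = 0, different K is detected", {
  x <- sample_distribution("exponential", list(scale = 15), 5000, seed = 9)
  fd <- relative_frequency(x, 5)
  same <- compare_curves_groups(list(fd, fd), "exp_decay")
  expect_equal(same$f_stat, 0, tolerance = 1e-8)
  expect_equal(same$p, 1, tolerance = 1e-6)

  # 3-fold K difference at n = 10^4: clearly significant
  a <- sample_distribution("exponential", list(scale = 15), 1e4, seed = 21)
  b <- sample_distribution("exponential", list(scale = 5), 1e4, seed = 22)
  diffk <- compare_curves_groups(list(relative_frequency(a, 5),
                                      relative_frequency(b, 5)), "exp_decay")
  expect_lt(diffk$p, 0.05)

  expect_error(compare_curves_groups(list(fd), "exp_decay"), "at least 2")
})

test_that("Kruskal-Wallis H matches the rank formula; Dunn output is complete", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_wallis_dunn(groups)
  # hand-computed: mean ranks 2, 5, 8; H = 12/(9*10) * 3*((2-5)^2+(5-5)^2+(8-5)^2)
  expect_equal(res$H, 12 / 90 * 3 * (9 + 0 + 9), tolerance = 1e-9)
  expect_equal(nrow(res$dunn), 3L)
  expect_true(all(c("z", "p", "p_adj", "significant") %in% names(res$dunn)))
  expect_true(all(res$dunn$p_adj >= res$dunn$p))

  ident <- kruskal_wallis_dunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)

  # tie correction increases H relative to the uncorrected statistic
  gt <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4, 5), c = c(5, 6, 7, 7))
  pooled <- unlist(gt)
  rk <- rank(pooled)
  sizes <- lengths(gt)
  ends <- cumsum(sizes); starts <- c(1, head(ends, -1) + 1)
  N <- length(pooled)
  h_uncorr <- 12 / (N * (N + 1)) *
    sum(sizes * (vapply(seq_along(gt), function(i)
      mean(rk[starts[i]:ends[i]]), 0) - (N + 1) / 2)^2)
  expect_gte(kruskal_wallis_dunn(gt)$H, h_uncorr - 1e-12)
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(17)
  g <- list(a = runif(8), b = runif(10) + 0.2, c = runif(6))
  h1 <- kruskal_wallis_dunn(g)$H
  g2 <- lapply(g, function(x) exp(3 * x) + 1)
  expect_equal(kruskal_wallis_dunn(g2)$H, h1, tolerance = 1e-12)
})
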