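#' Relative frequency distribution of a segment parameter
#'
#' Left-closed, right-open bins of constant width starting at the variable's
#' natural origin (0 for lengths and diameters, 1 for tortuosity); relative
#' frequencies are percentages summing to 100.
#'
#' @param values numeric vector (>= 1 value).
#' @param bin_width bin width in the variable's units (> 0).
#' @param origin left edge of the first bin.
#' @return An object of class `FrequencyDistribution`: `centers`, `freq`
#'   (percent), `counts`, `bin_width`, `n`.
#' @export
relative_frequency <- function(values, bin_width, origin = 0) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values")
  stopifnot(bin_width > 0, all(values >= origin))
  idx <- floor((values - origin) / bin_width)
  nb <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nb)
  structure(list(
    centers = origin + (seq_len(nb) - 0.5) * bin_width,
    freq = 100 * counts / length(values),
    counts = counts, bin_width = bin_width, n = length(values),
    origin = origin
  ), class = "FrequencyDistribution")
}

#' @export
print.FrequencyDistribution <- function(x, ...) {
  cat(sprintf("FrequencyDistribution: %d bins of width %g, n = %d\n",
              length(x$centers), x$bin_width, x$n))
  invisible(x)
}

fit_result <- function(model, params, derived, fitted, fd) {
  resid <- fd$freq - fitted
  sse <- sum(resid^2)
  sst <- sum((fd$freq - mean(fd$freq))^2)
  structure(list(model = model, params = params, derived = derived,
                 fitted = fitted, sse = sse,
                 df = length(fd$freq) - length(params),
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 n_bins = length(fd$freq), fd = fd),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s]: %s; %s; SSE = %.4g, df = %d, R^2 = %.4f\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              paste(sprintf("%s = %.4g", names(x$derived), x$derived),
                    collapse = ", "),
              x$sse, x$df, x$r2))
  invisible(x)
}

# deterministic restart schedule for nonlinear fits
nls_restarts <- function(formula, data, start, lower, upper = NULL,
                         factors = c(1, 0.3, 3, 0.1, 10)) {
  last_err <- NULL
  for (f in factors) {
    st <- start
    st$K <- if (!is.null(st$K)) st$K * f else NULL
    st$sg <- if (!is.null(st$sg)) st$sg * f else NULL
    fit <- tryCatch(
      if (is.null(upper))
        minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      else
        minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                          upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    last_err <- fit
  }
  stop("nonlinear fit did not converge after restarts: ",
       conditionMessage(last_err))
}

#' One-phase exponential-decay fit of a frequency distribution
#'
#' Fits `F = (F0 - Finf) * exp(-K * x) + Finf` by nonlinear least squares
#' (K > 0, Finf >= 0). The reciprocal rate constant 1/K is reported as the
#' length constant lambda (for segment lengths) or the tortuosity constant
#' tau (for tortuosity); smaller values mean the distribution concentrates
#' at short (or straight) segments.
#'
#' @param fd a `FrequencyDistribution` with >= 4 bins.
#' @return A `FitResult` with params `(F0, Finf, K)` and derived `lambda`.
#' @export
fit_exponential_decay <- function(fd) {
  stopifnot(inherits(fd, "FrequencyDistribution"))
  if (length(fd$centers) < 4L) stop("need at least 4 bins")
  dat <- data.frame(x = fd$centers, y = fd$freq)
  if (diff(range(fd$freq)) < 1e-10) {
    # flat distribution: the decay rate is unidentifiable; report a degenerate
    # fit (K at its lower bound) that r2 flags as uninformative
    pars <- c(F0 = mean(fd$freq), Finf = mean(fd$freq), K = 1e-8)
    return(fit_result("exp_decay", pars, c(lambda = 1 / pars[["K"]]),
                      rep(mean(fd$freq), length(fd$freq)), fd))
  }
  start <- list(F0 = max(fd$freq), Finf = min(fd$freq),
                K = 1 / max(weighted.mean(fd$centers, fd$freq), fd$bin_width))
  fit <- nls_restarts(y ~ (F0 - Finf) * exp(-K * x) + Finf, dat, start,
                      lower = c(F0 = 0, Finf = 0, K = 1e-8))
  cf <- coef(fit)
  fit_result("exp_decay",
             c(F0 = unname(cf["F0"]), Finf = unname(cf["Finf"]),
               K = unname(cf["K"])),
             c(lambda = 1 / unname(cf["K"])),
             (cf["F0"] - cf["Finf"]) * exp(-cf["K"] * fd$centers) + cf["Finf"],
             fd)
}

#' Gaussian fit of a frequency distribution
#'
#' Fits `F = A * exp(-0.5 * ((x - mu)/sigma)^2)` by nonlinear least squares
#' (sigma > 0), as used for segment diameter distributions.
#'
#' @param fd a `FrequencyDistribution` with >= 4 bins.
#' @return A `FitResult` with params `(A, mu, sigma)`.
#' @export
fit_gaussian <- function(fd) {
  stopifnot(inherits(fd, "FrequencyDistribution"))
  if (length(fd$centers) < 4L) stop("need at least 4 bins")
  dat <- data.frame(x = fd$centers, y = fd$freq)
  mu0 <- weighted.mean(fd$centers, fd$freq)
  sd0 <- sqrt(weighted.mean((fd$centers - mu0)^2, fd$freq))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- fd$bin_width
  start <- list(A = max(fd$freq), mu = mu0, sg = sd0)
  # the mode must lie inside the observed support; unbounded mu lets the
  # optimizer drift to huge-sigma plateau fits on multimodal inputs
  fit <- nls_restarts(y ~ A * exp(-0.5 * ((x - mu)/sg)^2), dat, start,
                      lower = c(A = 0, mu = min(fd$centers), sg = 1e-8),
                      upper = c(A = Inf, mu = max(fd$centers), sg = Inf))
  cf <- coef(fit)
  fit_result("gaussian",
             c(A = unname(cf["A"]), mu = unname(cf["mu"]),
               sigma = unname(cf["sg"])),
             c(mu = unname(cf["mu"])),
             cf["A"] * exp(-0.5 * ((fd$centers - cf["mu"])/cf["sg"])^2),
             fd)
}

#' F-test comparison of two fitted models on one distribution
#'
#' With equal free-parameter counts (Gaussian vs three-parameter exponential
#' decay), the preferred model is the one with lower SSE and the variance
#' ratio F = SSE_worse / SSE_better is referred to the F distribution on
#' (df, df). With unequal counts, the extra-sum-of-squares F-test is used
#' (the simpler model as null).
#'
#' @param a,b `FitResult`s on the same `FrequencyDistribution`.
#' @return An object of class `ModelComparison`: `f_stat`, `p`, `preferred`,
#'   `method`, `tie`.
#' @export
compare_fits <- function(a, b) {
  stopifnot(inherits(a, "FitResult"), inherits(b, "FitResult"))
  if (a$n_bins != b$n_bins ||
      !isTRUE(all.equal(a$fd$centers, b$fd$centers)))
    stop("fits are not on the same frequency distribution")
  if (a$df == b$df) {
    tie <- isTRUE(all.equal(a$sse, b$sse)) ||
      (a$sse < 1e-12 && b$sse < 1e-12)
    better <- if (b$sse < a$sse) b else a
    worse <- if (b$sse < a$sse) a else b
    f <- if (tie) 1 else worse$sse / better$sse
    p <- pf(f, worse$df, better$df, lower.tail = FALSE)
    structure(list(f_stat = f, p = p, preferred = better$model,
                   method = "sse_compare", tie = tie),
              class = "ModelComparison")
  } else {
    simple <- if (a$df > b$df) a else b
    full <- if (a$df > b$df) b else a
    num <- (simple$sse - full$sse) / (simple$df - full$df)
    den <- full$sse / full$df
    f <- max(0, num / den)
    p <- pf(f, simple$df - full$df, full$df, lower.tail = FALSE)
    preferred <- if (p < 0.05) full$model else simple$model
    structure(list(f_stat = f, p = p, preferred = preferred,
                   method = "extra_ss", tie = FALSE),
              class = "ModelComparison")
  }
}

#' @export
print.ModelComparison <- function(x, ...) {
  cat(sprintf("ModelComparison [%s]: F = %.4g, p = %.4g, preferred = %s%s\n",
              x$method, x$f_stat, x$p, x$preferred,
              if (isTRUE(x$tie)) " (tie)" else ""))
  invisible(x)
}

#' Extra-sum-of-squares F-test between groups of frequency curves
#'
#' Pooled fit (one shared parameter set across all groups' points) versus
#' separate per-group fits of the same model family:
#' F = ((SSE_pooled - SSE_sep) / (df_pooled - df_sep)) / (SSE_sep / df_sep).
#' A small p indicates the groups' curves differ.
#'
#' @param fds list of >= 2 `FrequencyDistribution`s.
#' @param model `"exp_decay"` or `"gaussian"`.
#' @return A `ModelComparison` with `method = "pooled_vs_separate"` plus the
#'   underlying fits.
#' @export
compare_curves_groups <- function(fds, model = c("exp_decay", "gaussian")) {
  model <- match.arg(model)
  if (!is.list(fds) || length(fds) < 2L)
    stop("need at least 2 frequency distributions")
  fitter <- if (model == "exp_decay") fit_exponential_decay else fit_gaussian
  sep <- lapply(fds, fitter)
  sse_sep <- sum(vapply(sep, function(f) f$sse, 0))
  df_sep <- sum(vapply(sep, function(f) f$df, 0L))
  # pooled: concatenate all (center, freq) points into one pseudo-distribution
  pooled_fd <- structure(list(
    centers = unlist(lapply(fds, function(f) f$centers)),
    freq = unlist(lapply(fds, function(f) f$freq)),
    counts = unlist(lapply(fds, function(f) f$counts)),
    bin_width = fds[[1]]$bin_width,
    n = sum(vapply(fds, function(f) f$n, 0L)),
    origin = fds[[1]]$origin
  ), class = "FrequencyDistribution")
  pooled <- fitter(pooled_fd)
  df_pooled <- length(pooled_fd$freq) - length(pooled$params)
  f <- max(0, ((pooled$sse - sse_sep) / (df_pooled - df_sep)) /
                (sse_sep / df_sep))
  p <- pf(f, df_pooled - df_sep, df_sep, lower.tail = FALSE)
  structure(list(f_stat = f, p = p,
                 preferred = if (p < 0.05) "separate" else "pooled",
                 method = "pooled_vs_separate", tie = FALSE,
                 fits_separate = sep, fit_pooled = pooled),
            class = "ModelComparison")
}

#' Kruskal-Wallis test with Dunn's post-hoc pairwise comparisons
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()]),
#' followed by Dunn's z-tests on all group pairs with a multiplicity
#' adjustment (classical Bonferroni by default). Significance threshold for
#' reporting: p < 0.05.
#'
#' @param groups named list of >= 2 numeric vectors (>= 2 values each).
#' @param p_adjust_method method for [stats::p.adjust()].
#' @return List `(H, p, dunn)` where `dunn` is a data frame of pairwise z,
#'   raw and adjusted p-values, and significance flags.
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust_method = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 0L) >= 2L))
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    kw <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kt <- kruskal.test(groups)
    kw <- list(statistic = c(H = unname(kt$statistic)), p.value = kt$p.value)
  }
  # Dunn's pairwise z-tests on mean ranks of the pooled sample
  N <- length(pooled)
  rk <- rank(pooled)
  sizes <- vapply(groups, length, 0L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  rbar <- vapply(seq_along(groups),
                 function(i) mean(rk[starts[i]:ends[i]]), 0)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
    z[c_i] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[c_i] <- 2 * pnorm(-abs(z[c_i]))
  }
  p_adj <- p.adjust(p_raw, method = p_adjust_method)
  dunn <- data.frame(group1 = names(groups)[pairs[1, ]],
                     group2 = names(groups)[pairs[2, ]],
                     z = z, p = p_raw, p_adj = p_adj,
                     significant = p_adj < 0.05)
  list(H = unname(kw$statistic["H"]), p = kw$p.value, dunn = dunn)
}
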