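#' Genotype-class count table
#'
#' @param counts Named nonnegative integer vector (class label -> count).
#' @param design One of `"custom"`, `"self_het"`, `"testcross"`,
#'   `"f2_double_het"`. Named designs fix the model's class probabilities as
#'   functions of the killing efficiency / transmission weights and enable
#'   closed-form estimation.
#' @return An object of class `ta_counts` with fields `counts`, `design`, `n`.
#' @export
ta_counts <- function(counts, design = c("custom", "self_het", "testcross",
                                         "f2_double_het")) {
  design <- match.arg(design)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by genotype class", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("count table is all zero", call. = FALSE)
  structure(list(counts = counts, design = design, n = n), class = "ta_counts")
}

#' @export
print.ta_counts <- function(x, ...) {
  cat("Genotype count table (design: ", x$design, ", n = ", x$n, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Read / write a count table as TSV
#'
#' Two tab-separated columns with header `class` and `count`.
#'
#' @param path File path.
#' @param design Design tag attached on read.
#' @return `read_counts_tsv` returns a `ta_counts`; `write_counts_tsv`
#'   returns `path` invisibly.
#' @export
read_counts_tsv <- function(path, design = "custom") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class", "count") %in% names(df)))
    stop("count TSV needs columns 'class' and 'count'", call. = FALSE)
  ta_counts(stats::setNames(df$count, df$class), design = design)
}

#' @rdname read_counts_tsv
#' @param x A `ta_counts`.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "ta_counts"))
  utils::write.table(data.frame(class = names(x$counts), count = x$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- segregation test ------------------------------------------------------

## All compositions of n into k nonnegative parts (k small, n <= ~200).
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(0:n, function(i) cbind(i, .compositions(n - i, k - 1L))))
}

.exact_multinomial_p <- function(obs, probs) {
  n <- sum(obs)
  comp <- .compositions(n, length(obs))
  lp <- lgamma(n + 1) - rowSums(lgamma(comp + 1))
  for (j in seq_along(probs)) {
    pj <- probs[j]
    lp <- lp + ifelse(comp[, j] == 0, 0,
                      if (pj > 0) comp[, j] * log(pj) else -Inf)
  }
  lp_obs <- lgamma(n + 1) - sum(lgamma(obs + 1)) +
    sum(ifelse(obs == 0, 0, obs * log(ifelse(probs > 0, probs, 1)))) +
    if (any(obs > 0 & probs == 0)) -Inf else 0
  sum(exp(lp[lp <= lp_obs + 1e-9]))
}

#' Segregation test against fixed class probabilities
#'
#' Pearson chi-square goodness-of-fit without continuity correction,
#' `df = classes - 1`, plus an exact multinomial tail probability (sum of the
#' probabilities of all outcomes no more likely than the observed one) when
#' the total count does not exceed `exact_max_n`.
#'
#' If a class with expected probability 0 is observed, the chi-square
#' statistic is `Inf` and the exact p-value (0) is the meaningful answer.
#'
#' @param observed A [ta_counts()] or named count vector.
#' @param expected_probs Numeric vector of class probabilities summing to 1,
#'   either unnamed in the order of the counts or named by class.
#' @param exact_max_n Largest total count for which the exact test is
#'   computed by enumeration (default 200).
#' @return An object of class `ta_segtest` with fields `statistic`, `df`,
#'   `p_value`, `exact_p` (`NA` when not computed), `observed`, `expected`.
#' @examples
#' segregation_test(c(`M/M` = 52, `M/D` = 48), c(0.5, 0.5))
#' @export
segregation_test <- function(observed, expected_probs, exact_max_n = 200L) {
  if (inherits(observed, "ta_counts")) observed <- observed$counts
  obs <- as.numeric(observed)
  if (!is.null(names(expected_probs))) {
    if (!setequal(names(expected_probs), names(observed)))
      stop("class labels of counts and expected_probs disagree", call. = FALSE)
    expected_probs <- expected_probs[names(observed)]
  }
  if (length(expected_probs) != length(obs))
    stop("expected_probs must have one entry per class", call. = FALSE)
  if (abs(sum(expected_probs) - 1) > 1e-8)
    stop("expected_probs must sum to 1", call. = FALSE)
  n <- sum(obs)
  e <- n * expected_probs
  if (any(e == 0 & obs > 0)) {
    stat <- Inf
  } else {
    nz <- e > 0
    stat <- sum((obs[nz] - e[nz])^2 / e[nz])
  }
  df <- length(obs) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  exact <- if (n <= exact_max_n)
    .exact_multinomial_p(obs, expected_probs) else NA_real_
  structure(list(statistic = stat, df = df, p_value = p, exact_p = exact,
                 n = n, observed = stats::setNames(obs, names(observed)),
                 expected = e),
            class = "ta_segtest")
}

#' @export
print.ta_segtest <- function(x, ...) {
  cat("Segregation chi-square test\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.na(x$exact_p))
    cat(sprintf("  exact multinomial p = %.4g (n = %d)\n", x$exact_p, x$n))
  invisible(x)
}

## ---- design class probabilities -------------------------------------------

## Analytic class probabilities as functions of k for the named designs.
## Pollen pool of the heterozygote: functional 1/(2-k), null (1-k)/(2-k).
## These are validated against the crossing module in the test suite.
.design_info <- function(design, panel = NULL) {
  if (is.null(panel)) panel <- qhms1_panel()
  lc <- panel$loci[[1L]]
  disp <- function(tok) .display_token(tok, lc)
  key2 <- function(a, b) paste(sort(c(disp(a), disp(b))), collapse = "")
  switch(design,
    self_het = list(
      labels = c(key2("FA", "FA"), key2("FA", "fa"), key2("fa", "fa")),
      probs = function(k) {
        m <- 1 / (2 - k); d <- (1 - k) / (2 - k)     # male pool
        c(0.5 * m, 0.5 * m + 0.5 * d, 0.5 * d)       # x female (1/2, 1/2)
      },
      # the heterozygote class has probability 1/2 whatever k is, so the
      # multinomial MLE depends only on the homozygote split:
      # 1/(2-k) : (1-k)/(2-k), hence khat = (MM - DD) / MM
      khat = function(cn) {
        if (cn[1L] <= 0) return(0)
        max(0, min(1, (cn[1L] - cn[3L]) / cn[1L]))
      },
      null_class = key2("fa", "fa")),
    testcross = list(
      # null homozygote as female x heterozygote as pollen parent; the two
      # classes are the male pool itself, khat = (het - DD) / het
      labels = c(key2("FA", "fa"), key2("fa", "fa")),
      probs = function(k) c(1 / (2 - k), (1 - k) / (2 - k)),
      khat = function(cn) {
        if (cn[1L] <= 0) return(0)
        max(0, min(1, (cn[1L] - cn[2L]) / cn[1L]))
      },
      null_class = key2("fa", "fa")),
    stop("no analytic class probabilities for design: ", design, call. = FALSE))
}

## ---- ta_fit object ---------------------------------------------------------

.new_ta_fit <- function(estimate, loglik, ci, method, design, counts, n,
                        boundary = FALSE, converged = TRUE, probs_fun = NULL,
                        null_test = NULL) {
  structure(list(estimate = estimate, loglik = loglik, ci = ci,
                 method = method, design = design, counts = counts, n = n,
                 boundary = boundary, converged = converged,
                 probs_fun = probs_fun, null_test = null_test),
            class = "ta_fit")
}

#' @export
print.ta_fit <- function(x, ...) {
  cat("Toxin-antidote model fit (", x$method, ", design: ", x$design,
      ", n = ", x$n, ")\n", sep = "")
  est <- cbind(estimate = x$estimate, x$ci)
  print(round(est, 4))
  cat("log-likelihood:", format(x$loglik, digits = 6), "\n")
  if (x$boundary) cat("note: estimate on the parameter boundary; one-sided CI\n")
  invisible(x)
}

#' @export
coef.ta_fit <- function(object, ...) object$estimate

#' @export
logLik.ta_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimate), class = "logLik")
}

#' @export
confint.ta_fit <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && abs(level - 0.95) > 1e-8)
    warning("intervals were computed at the 95% level")
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.ta_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$null_test)) {
    cat("\nLikelihood-ratio test against uniform transmission:\n")
    cat(sprintf("  LRT = %.4g, df = %d, p-value = %.4g\n",
                object$null_test$statistic, object$null_test$df,
                object$null_test$p_value))
  }
  invisible(object)
}

#' @export
predict.ta_fit <- function(object, ...) {
  # expected class probabilities and counts at the fitted parameters
  p <- object$probs_fun(object$estimate)
  data.frame(class = names(object$counts$counts), probability = p,
             expected = object$n * p, row.names = NULL)
}

#' @export
residuals.ta_fit <- function(object, type = c("pearson"), ...) {
  type <- match.arg(type)
  pr <- predict(object)
  (as.numeric(object$counts$counts) - pr$expected) /
    sqrt(pmax(pr$expected, .Machine$double.eps))
}

#' @export
simulate.ta_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object)
  draws <- stats::rmultinom(nsim, object$n, pr$probability)
  rownames(draws) <- pr$class
  lapply(seq_len(nsim), function(j)
    ta_counts(draws[, j], design = object$design))
}

## ---- killing-efficiency fit ------------------------------------------------

#' Maximum-likelihood killing efficiency from genotype counts
#'
#' Fits the per-locus killing efficiency `k` to a genotype count table from a
#' named cross design by maximising the multinomial likelihood with class
#' probabilities predicted by the gamete-killing model. For the heterozygote
#' self (`self_het`) the heterozygote class has probability 1/2 regardless of
#' `k`, so the MLE has the closed form `k = (MM - DD) / MM` in the two
#' homozygote counts, clipped to `[0, 1]` (equivalently, inverting the
#' expected double-null proportion `p` gives `k = (1 - 4p) / (1 - 2p)`, which
#' coincides with the MLE when the heterozygote count is exactly half the
#' sample). The closed form and the numeric optimum agree and both are
#' computed. The 95% interval is a profile-likelihood interval (chi-square
#' cutoff 3.84); a boundary estimate (`k = 1` when no double-null plant is
#' seen) is reported with a one-sided interval.
#'
#' @param observed A [ta_counts()] whose labels match the design's class keys
#'   (as produced by [gen_cross_counts()]); unnamed designs are rejected.
#' @param design Cross design; defaults to the table's own design tag.
#' @param panel Single-locus panel naming the locus being fitted.
#' @return A `ta_fit` with estimate `k`.
#' @examples
#' cnt <- ta_counts(c(`1M1M` = 4940, `1D1M` = 4952, `1D1D` = 108),
#'                  design = "self_het")
#' fit_killing_efficiency(cnt)
#' @export
fit_killing_efficiency <- function(observed, design = observed$design,
                                   panel = qhms1_panel()) {
  stopifnot(inherits(observed, "ta_counts"))
  info <- .design_info(design, panel)
  cn <- observed$counts
  if (!setequal(names(cn), info$labels))
    stop("count classes ", paste(names(cn), collapse = ", "),
         " do not match design classes ", paste(info$labels, collapse = ", "),
         call. = FALSE)
  cn <- cn[info$labels]
  n <- sum(cn)

  ll <- function(k) stats::dmultinom(cn, prob = info$probs(k), log = TRUE)
  khat <- info$khat(as.numeric(cn))
  boundary <- khat >= 1 - 1e-12 || khat <= 1e-12
  # numeric confirmation of the closed form (guards against clipping cases)
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-10)
  if (ll(opt$maximum) > ll(khat) + 1e-9) khat <- opt$maximum
  ll_hat <- ll(khat)

  cutoff <- ll_hat - stats::qchisq(0.95, 1) / 2
  lower <- if (khat <= 1e-12) 0 else if (ll(0) >= cutoff) 0 else
    stats::uniroot(function(k) ll(k) - cutoff, c(0, khat), tol = 1e-9)$root
  upper <- if (khat >= 1 - 1e-12) 1 else if (ll(1) >= cutoff) 1 else
    stats::uniroot(function(k) ll(k) - cutoff, c(khat, 1), tol = 1e-9)$root

  ci <- matrix(c(lower, upper), 1, 2,
               dimnames = list("k", c("2.5 %", "97.5 %")))
  .new_ta_fit(estimate = c(k = khat), loglik = ll_hat, ci = ci,
              method = "profile ML", design = design,
              counts = ta_counts(cn, design = design), n = n,
              boundary = boundary,
              probs_fun = function(est) info$probs(est[["k"]]))
}

## ---- female transmission weights -------------------------------------------

#' Female transmission weights from the stacked-heterozygote F2
#'
#' In the F2 of the double heterozygote with complete killing, the male
#' gamete is fixed and each of the four genotype classes maps one-to-one to a
#' female joint gamete class, so the saturated multinomial MLE of the
#' transmission weights is the vector of observed proportions. A
#' likelihood-ratio test against uniform transmission (1:1:1:1, df = 3) and
#' seeded nonparametric bootstrap percentile intervals (1000 resamples) are
#' attached.
#'
#' @param observed A [ta_counts()] with the four F2 classes.
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @param boot Number of bootstrap resamples.
#' @return A `ta_fit` whose estimate is the weight vector; absent classes get
#'   weight 0 and flag the boundary.
#' @export
fit_female_weights <- function(observed, seed, boot = 1000L) {
  stopifnot(inherits(observed, "ta_counts"))
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  cn <- observed$counts
  n <- sum(cn)
  what <- cn / n
  ll <- sum(ifelse(cn == 0, 0, cn * log(what)))
  lrt <- 2 * sum(ifelse(cn == 0, 0, cn * log(what / (1 / length(cn)))))
  df <- length(cn) - 1L
  null_test <- list(statistic = lrt, df = df,
                    p_value = stats::pchisq(lrt, df, lower.tail = FALSE))
  bs <- withr::with_seed(seed, {
    stats::rmultinom(boot, n, what) / n
  })
  ci <- t(apply(bs, 1, stats::quantile, probs = c(0.025, 0.975)))
  dimnames(ci) <- list(names(cn), c("2.5 %", "97.5 %"))
  # point estimate must sit inside its interval even in degenerate cases
  ci[, 1] <- pmin(ci[, 1], what)
  ci[, 2] <- pmax(ci[, 2], what)
  .new_ta_fit(estimate = stats::setNames(as.numeric(what), names(cn)),
              loglik = ll, ci = ci, method = "multinomial MLE + bootstrap",
              design = "f2_double_het", counts = observed, n = n,
              boundary = any(cn == 0),
              probs_fun = function(est) as.numeric(est),
              null_test = null_test)
}

## ---- goodness of fit -------------------------------------------------------

#' Goodness-of-fit report against a model prediction
#'
#' Joins an observed count table with the class probabilities of a model
#' prediction (a `ta_progeny` distribution or a fitted `ta_fit`), and reports
#' expected counts, Pearson residuals and the overall segregation test.
#'
#' @param observed A [ta_counts()].
#' @param model A `ta_progeny` (classes matched by genotype key) or a
#'   `ta_fit` (its fitted class probabilities are used).
#' @return A data frame with columns `class`, `observed`, `expected`,
#'   `residual`, with the `ta_segtest` attached as attribute `"test"`.
#' @export
goodness_of_fit <- function(observed, model) {
  stopifnot(inherits(observed, "ta_counts"))
  if (inherits(model, "ta_fit")) {
    pr <- predict(model)
    probs <- stats::setNames(pr$probability, pr$class)
  } else if (inherits(model, "ta_progeny")) {
    probs <- stats::setNames(model$probability, model$genotype)
  } else stop("model must be a ta_progeny or ta_fit", call. = FALSE)
  extra <- setdiff(names(observed$counts), names(probs))
  # observed classes absent from the model carry probability 0
  probs[extra] <- 0
  if (!setequal(names(probs), names(observed$counts))) {
    miss <- setdiff(names(probs), names(observed$counts))
    stop("model classes missing from the count table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  probs <- probs[names(observed$counts)]
  st <- segregation_test(observed, probs)
  out <- data.frame(class = names(observed$counts),
                    observed = as.numeric(observed$counts),
                    expected = st$expected,
                    residual = (as.numeric(observed$counts) - st$expected) /
                      sqrt(pmax(st$expected, .Machine$double.eps)),
                    row.names = NULL)
  attr(out, "test") <- st
  out
}
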