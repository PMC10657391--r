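## Single-locus population dynamics over the four haplotype classes
## FA (toxin+ antidote+), fA, Fa, fa.

.DRIVE_CLASSES <- c("FA", "fA", "Fa", "fa")

.check_freqs <- function(freqs) {
  if (is.null(names(freqs)) || !setequal(names(freqs), .DRIVE_CLASSES)) {
    if (length(freqs) == length(.DRIVE_CLASSES) && is.null(names(freqs)))
      names(freqs) <- .DRIVE_CLASSES
    else {
      full <- stats::setNames(numeric(4), .DRIVE_CLASSES)
      if (!all(names(freqs) %in% .DRIVE_CLASSES))
        stop("haplotype classes must be among ",
             paste(.DRIVE_CLASSES, collapse = ", "), call. = FALSE)
      full[names(freqs)] <- freqs
      freqs <- full
    }
  }
  freqs <- freqs[.DRIVE_CLASSES]
  if (any(freqs < 0)) stop("haplotype frequencies must be nonnegative", call. = FALSE)
  s <- sum(freqs)
  if (abs(s - 1) > 1e-8) stop("haplotype frequencies must sum to 1", call. = FALSE)
  freqs / s
}

## Precompute genotype-level machinery for one killing efficiency.
## Genotypes are unordered haplotype pairs (10 of them).
.drive_tables <- function(k) {
  panel <- ta_panel(ta_locus("locus", "1", k = k, abortion_stage = "uninucleate"))
  pairs <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  G <- nrow(pairs)
  ovule <- matrix(0, G, 4, dimnames = list(NULL, .DRIVE_CLASSES))
  pollen <- matrix(0, G, 4, dimnames = list(NULL, .DRIVE_CLASSES))
  viable <- numeric(G)
  for (g in seq_len(G)) {
    i <- pairs[g, 1L]; j <- pairs[g, 2L]
    geno <- ta_genotype(.DRIVE_CLASSES[i], panel, hapB = .DRIVE_CLASSES[j])
    ovule[g, i] <- ovule[g, i] + 0.5
    ovule[g, j] <- ovule[g, j] + 0.5
    mg <- male_gametes(geno, panel)
    viable[g] <- mg$viable_fraction
    if (viable[g] > 0)
      for (r in seq_len(nrow(mg$classes)))
        pollen[g, mg$classes$hap[[r]]] <-
          pollen[g, mg$classes$hap[[r]]] + mg$classes$post[r]
  }
  list(pairs = pairs, ovule = ovule, pollen = pollen, viable = viable)
}

## Hardy-Weinberg genotype frequencies from haplotype frequencies.
.hw_freqs <- function(freqs, pairs) {
  f <- numeric(nrow(pairs))
  for (g in seq_len(nrow(pairs))) {
    i <- pairs[g, 1L]; j <- pairs[g, 2L]
    f[g] <- if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j]
  }
  f
}

## One generation: offspring genotype distribution (over unordered pairs) and
## mean pollen fertility of the parental population.
.offspring_dist <- function(freqs, tab, s) {
  fg <- .hw_freqs(freqs, tab$pairs)
  male_w <- fg * tab$viable
  if (sum(male_w) <= 0)
    stop("population male-extinct: every genotype is fully male-sterile",
         call. = FALSE)
  pollen_pool <- colSums(tab$pollen * male_w) / sum(male_w)
  ovule_pool <- colSums(tab$ovule * fg)   # equals freqs: no female selection

  pair_prob <- function(ov, po) {
    # unordered genotype probabilities from independent ovule x pollen draw
    p <- numeric(nrow(tab$pairs))
    for (g in seq_len(nrow(tab$pairs))) {
      i <- tab$pairs[g, 1L]; j <- tab$pairs[g, 2L]
      p[g] <- if (i == j) ov[i] * po[i] else ov[i] * po[j] + ov[j] * po[i]
    }
    p
  }
  out_cross <- pair_prob(ovule_pool, pollen_pool)

  if (s > 0) {
    fertile <- which(tab$viable > 0 & fg > 0)
    selfed <- numeric(nrow(tab$pairs))
    if (!length(fertile))
      stop("population male-extinct: every genotype is fully male-sterile",
           call. = FALSE)
    w <- fg[fertile] / sum(fg[fertile])
    for (idx in seq_along(fertile)) {
      g <- fertile[idx]
      selfed <- selfed + w[idx] * pair_prob(tab$ovule[g, ], tab$pollen[g, ])
    }
    dist <- (1 - s) * out_cross + s * selfed
  } else dist <- out_cross

  list(dist = dist / sum(dist),
       mean_fertility = sum(fg * tab$viable))
}

.dist_to_freqs <- function(dist, pairs) {
  freqs <- stats::setNames(numeric(4), .DRIVE_CLASSES)
  for (g in seq_along(dist)) {
    freqs[pairs[g, 1L]] <- freqs[pairs[g, 1L]] + dist[g] / 2
    freqs[pairs[g, 2L]] <- freqs[pairs[g, 2L]] + dist[g] / 2
  }
  freqs
}

#' One deterministic generation of toxin-antidote haplotype dynamics
#'
#' Infinite population, single toxin-antidote locus. Parents form genotypes
#' in Hardy-Weinberg proportions from the current haplotype frequencies. The
#' ovule pool is the unselected haplotype contribution of each genotype; the
#' pollen pool weights each genotype by its frequency times its viable pollen
#' fraction and draws from its post-selection gamete pool. A fraction `s` of
#' offspring come from selfing (male-fertile mothers only); the rest from
#' random ovule-by-pollen union.
#'
#' @param freqs Named frequencies over the classes `FA`, `fA`, `Fa`, `fa`
#'   (missing classes taken as 0).
#' @param k Killing efficiency of the locus.
#' @param s Selfing rate in `[0, 1]`. Rice is predominantly selfing
#'   (default 0.95); use `s = 0` for clean outcrossing dynamics.
#' @return Next-generation haplotype frequencies (named, summing to 1).
#' @export
drive_step <- function(freqs, k = 1, s = 0.95) {
  freqs <- .check_freqs(freqs)
  tab <- .drive_tables(k)
  od <- .offspring_dist(freqs, tab, s)
  .dist_to_freqs(od$dist, tab$pairs)
}

#' Deterministic haplotype-frequency trajectory
#'
#' Iterates [drive_step()] and records the haplotype frequencies and mean
#' pollen fertility each generation.
#'
#' @inheritParams drive_step
#' @param generations Number of generations to run.
#' @return An object of class `ta_trajectory`: a data frame with columns
#'   `generation`, `FA`, `fA`, `Fa`, `fa`, `mean_fertility` (row 0 = initial
#'   state).
#' @examples
#' drive_trajectory(c(FA = 0.05, fa = 0.95), generations = 20, k = 1, s = 0)
#' @export
drive_trajectory <- function(freqs, generations, k = 1, s = 0.95) {
  freqs <- .check_freqs(freqs)
  tab <- .drive_tables(k)
  rows <- matrix(NA_real_, generations + 1L, 6L)
  colnames(rows) <- c("generation", .DRIVE_CLASSES, "mean_fertility")
  cur <- freqs
  for (t in 0:generations) {
    od <- .offspring_dist(cur, tab, s)
    rows[t + 1L, ] <- c(t, cur, od$mean_fertility)
    if (t < generations) cur <- .dist_to_freqs(od$dist, tab$pairs)
  }
  out <- as.data.frame(rows)
  attr(out, "params") <- list(k = k, s = s, N = Inf, seed = NA_integer_)
  class(out) <- c("ta_trajectory", "data.frame")
  out
}

#' Wright-Fisher run of toxin-antidote haplotype dynamics
#'
#' Stochastic counterpart of [drive_trajectory()]: each generation the
#' deterministic offspring genotype distribution is computed from the current
#' haplotype frequencies and `N` offspring genotypes are drawn multinomially.
#' Bit-reproducible under a fixed seed.
#'
#' @inheritParams drive_trajectory
#' @param N Population size (`>= 2`).
#' @param seed Integer seed.
#' @return A `ta_trajectory` data frame.
#' @export
wright_fisher_run <- function(freqs, N, generations, seed, k = 1, s = 0.95) {
  stopifnot(N >= 2)
  freqs <- .check_freqs(freqs)
  tab <- .drive_tables(k)
  rows <- matrix(NA_real_, generations + 1L, 6L)
  colnames(rows) <- c("generation", .DRIVE_CLASSES, "mean_fertility")
  withr::with_seed(as.integer(seed), {
    cur <- freqs
    for (t in 0:generations) {
      od <- .offspring_dist(cur, tab, s)
      rows[t + 1L, ] <- c(t, cur, od$mean_fertility)
      if (t < generations) {
        draw <- stats::rmultinom(1, N, od$dist)[, 1L]
        cur <- .dist_to_freqs(draw / N, tab$pairs)
      }
    }
  })
  out <- as.data.frame(rows)
  attr(out, "params") <- list(k = k, s = s, N = N, seed = as.integer(seed))
  class(out) <- c("ta_trajectory", "data.frame")
  out
}

#' @export
plot.ta_trajectory <- function(x, ...) {
  graphics::matplot(x$generation, as.matrix(x[, .DRIVE_CLASSES]),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#7570b3", "#d95f02", "#666666"),
                    xlab = "generation", ylab = "haplotype frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = .DRIVE_CLASSES, lty = 1, lwd = 2,
                   col = c("#1b9e77", "#7570b3", "#d95f02", "#666666"),
                   bty = "n")
  invisible(x)
}

#' Fate of a newly arisen haplotype
#'
#' Introduces a mutant haplotype into a resident population at low frequency
#' and reports its deterministic trajectory and, optionally, its fate across
#' seeded Wright-Fisher replicates. The scenarios encode the evolutionary
#' ordering argument: an antidote-silenced haplotype (`fa`) can establish
#' only where the functional toxin is already gone, and a toxin-only
#' haplotype (`Fa`) is always purged.
#'
#' @param scenario One of `"fa_into_FA_background"`, `"fa_into_fA_background"`,
#'   `"Fa_into_any"`, `"FA_into_fa_background"`.
#' @param p0 Introduction frequency for the deterministic recursion
#'   (default 0.005). In Wright-Fisher replicates the mutant starts at one
#'   copy, `1/(2N)`.
#' @param generations Generations to run.
#' @param k,s Killing efficiency and selfing rate.
#' @param resident Optional named resident frequencies overriding the
#'   scenario default.
#' @param N,reps,seed If `N` is given, `reps` Wright-Fisher replicates are
#'   run at population size `N` with seeds derived from `seed`.
#' @return An object of class `ta_mutant_fate`: list with the mutant class,
#'   the deterministic `ta_trajectory`, the deterministic final mutant
#'   frequency, a monotonicity flag, and (when `N` is given) the replicate
#'   final frequencies and the fractions lost / established.
#' @export
mutation_order_experiment <- function(scenario = c("fa_into_FA_background",
                                                   "fa_into_fA_background",
                                                   "Fa_into_any",
                                                   "FA_into_fa_background"),
                                      p0 = 0.005, generations = 200,
                                      k = 1, s = 0, resident = NULL,
                                      N = NULL, reps = 100, seed = 1) {
  scenario <- match.arg(scenario)
  mut <- switch(scenario,
                fa_into_FA_background = "fa",
                fa_into_fA_background = "fa",
                Fa_into_any = "Fa",
                FA_into_fa_background = "FA")
  if (is.null(resident)) {
    resident <- switch(scenario,
      fa_into_FA_background = c(FA = 1),
      fa_into_fA_background = c(fA = 1),
      Fa_into_any = c(FA = 0.5, fA = 0.5),
      FA_into_fa_background = c(fa = 1))
  }
  resident <- .check_freqs(resident)
  init <- resident * (1 - p0)
  init[mut] <- init[mut] + p0
  det <- drive_trajectory(init, generations, k = k, s = s)
  mono_dec <- all(diff(det[[mut]]) <= 1e-12)
  mono_inc <- all(diff(det[[mut]]) >= -1e-12)

  wf <- NULL
  if (!is.null(N)) {
    init_wf <- resident * (1 - 1 / (2 * N))
    init_wf[mut] <- init_wf[mut] + 1 / (2 * N)
    finals <- vapply(seq_len(reps), function(r) {
      tr <- wright_fisher_run(init_wf, N, generations,
                              seed = stream_seed(seed, paste0("fate", r)),
                              k = k, s = s)
      tr[[mut]][nrow(tr)]
    }, numeric(1))
    wf <- list(final_freqs = finals,
               lost = mean(finals == 0),
               established = mean(finals > 0.1))
  }
  structure(list(scenario = scenario, mutant = mut,
                 deterministic = det,
                 final_freq = det[[mut]][nrow(det)],
                 monotone_decreasing = mono_dec,
                 monotone_increasing = mono_inc,
                 wright_fisher = wf),
            class = "ta_mutant_fate")
}

#' @export
print.ta_mutant_fate <- function(x, ...) {
  cat("Mutant-haplotype fate:", x$scenario, "\n")
  cat(sprintf("  deterministic final frequency of %s after %d generations: %.4g\n",
              x$mutant, nrow(x$deterministic) - 1L, x$final_freq))
  if (x$monotone_decreasing) cat("  frequency monotonically non-increasing\n")
  if (x$monotone_increasing) cat("  frequency monotonically non-decreasing\n")
  if (!is.null(x$wright_fisher))
    cat(sprintf("  Wright-Fisher: lost in %.0f%%, established (>0.1) in %.0f%% of %d replicates\n",
                100 * x$wright_fisher$lost, 100 * x$wright_fisher$established,
                length(x$wright_fisher$final_freqs)))
  invisible(x)
}
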