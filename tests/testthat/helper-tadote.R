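# Shared fixtures and independent oracles for the test suite.

p1 <- function(k = 1) qhms1_panel(k)
p17 <- function(k1 = 1, k7 = 1) qhms_panel(k1, k7)

het1 <- function(k = 1) ta_genotype("1M1D", p1(k))

# Independent brute-force pollen-fertility oracle: enumerate every gamete
# (allele choice per locus x hemizygous-transgene subset) and apply the
# killing rule from first principles, without going through male_gametes().
oracle_fertility <- function(genotype, panel) {
  L <- length(panel$loci)
  ids <- names(panel$loci)
  tgs <- genotype$transgenes
  is_hemi <- vapply(tgs, function(t) t$zygosity == "hemizygous", logical(1))
  hemi <- tgs[is_hemi]
  homo <- tgs[!is_hemi]
  combos <- expand.grid(rep(list(1:2), L))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(hemi)))
  if (!nrow(subsets)) subsets <- data.frame(row.names = 1)
  total <- 0
  for (ci in seq_len(nrow(combos))) {
    hap <- vapply(seq_len(L), function(i)
      if (combos[ci, i] == 1) genotype$hapA[i] else genotype$hapB[i],
      character(1))
    for (si in seq_len(nrow(subsets))) {
      carried <- c(homo, hemi[unlist(subsets[si, ])])
      w <- 0.5^L * 0.5^length(hemi)
      s <- 1
      for (i in seq_len(L)) {
        exposed <- substr(genotype$hapA[i], 1, 1) == "F" ||
          substr(genotype$hapB[i], 1, 1) == "F" ||
          any(vapply(tgs, function(t)
            t$payload == "toxin" && t$target_locus == ids[i], logical(1)))
        protected <- substr(hap[i], 2, 2) == "A" ||
          any(vapply(carried, function(t)
            t$payload == "antidote" && t$target_locus == ids[i], logical(1)))
        if (exposed && !protected) s <- s * (1 - panel$loci[[i]]$k)
      }
      total <- total + w * s
    }
  }
  total
}

# Random panel / genotype generators for property tests.
rand_panel <- function(L, stages = c("uninucleate", "binucleate")) {
  loci <- lapply(seq_len(L), function(i)
    ta_locus(paste0("L", i), as.character(i), k = runif(1),
             abortion_stage = sample(stages, 1)))
  ta_panel(loci, stages = stages)
}

rand_genotype <- function(panel, n_tg = 0) {
  toks <- c("FA", "fA", "Fa", "fa")
  L <- length(panel$loci)
  tgs <- if (n_tg > 0) lapply(seq_len(n_tg), function(i)
    ta_transgene(sample(c("toxin", "antidote"), 1),
                 sample(names(panel$loci), 1),
                 sample(c("hemizygous", "homozygous"), 1))) else list()
  ta_genotype(sample(toks, L, replace = TRUE), panel,
              hapB = sample(toks, L, replace = TRUE), transgenes = tgs)
}

# Strict increase until numerical fixation (increments vanish once the
# frequency saturates at 1 in double precision).
strictly_rises <- function(x, cap = 1 - 1e-9) {
  all(diff(x) > 0 | x[-1] > cap)
}

prob_of <- function(dist, key) {
  i <- match(key, dist$genotype)
  if (is.na(i)) 0 else dist$probability[i]
}
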