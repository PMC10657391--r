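test_that("toxin exposure is sporophytic: any functional copy or toxin transgene", {
  p <- p1()
  expect_true(toxin_exposure(het1(), p, "qHMS1"))
  dd <- ta_genotype("1D1D", p)
  expect_false(toxin_exposure(dd, p, "qHMS1"))
  dd_tg <- ta_genotype("1D1D", p,
                       transgenes = list(ta_transgene("toxin", "qHMS1")))
  expect_true(toxin_exposure(dd_tg, p, "qHMS1"))
  expect_error(toxin_exposure(dd, p, "nope"), "unknown locus")
})

test_that("antidote protection is strictly gametophytic-cis", {
  p <- p1()
  expect_true(gamete_protected("FA", p, "qHMS1"))
  expect_false(gamete_protected("fa", p, "qHMS1"))
  expect_true(gamete_protected("fa", p, "qHMS1",
                               list(ta_transgene("antidote", "qHMS1"))))
  # the other haplotype's antidote never protects: Fa/fA plant is still
  # semi-sterile because the Fa gamete carries no antidote of its own
  g <- ta_genotype("Fa", p, hapB = "fA")
  expect_equal(pollen_fertility(g, p), 0.5)
})

test_that("male gamete distribution applies the killing rule per class", {
  p <- p1()
  mg <- male_gametes(het1(), p)
  expect_equal(mg$viable_fraction, 0.5)
  surv <- mg$classes[mg$classes$post > 0, ]
  expect_equal(surv$gamete, "1M")
  expect_equal(surv$post, 1)
  expect_equal(surv$stage, NA_character_)

  mg0 <- male_gametes(ta_genotype("1M1D", p1(0)), p1(0))
  expect_equal(mg0$viable_fraction, 1)
  expect_equal(sort(mg0$classes$post), c(0.5, 0.5))

  dh <- double_het(p17())
  mgd <- male_gametes(dh, p17())
  expect_equal(mgd$viable_fraction, 0.25)
  surv <- mgd$classes[mgd$classes$post > 0, ]
  expect_equal(surv$gamete, "1M/7D")
  expect_equal(surv$post, 1)
})

test_that("fully sterile plants yield an empty surviving pool, not an error", {
  p <- p1()
  ko <- edit_genotype(het1(), p, "qHMS1", "antidote")
  mg <- male_gametes(ko, p)
  expect_equal(mg$viable_fraction, 0)
  expect_true(all(mg$classes$post == 0))
})

test_that("the knockout/transgene phenotype table is reproduced", {
  p <- p1()
  atg <- ta_transgene("antidote", "qHMS1")
  ttg <- ta_transgene("toxin", "qHMS1")
  cases <- list(
    list(g = ta_genotype("1D1D", p), fert = 1.0),          # cultivar
    list(g = ta_genotype("1M1M", p), fert = 1.0),          # NIL
    list(g = het1(), fert = 0.5),                          # F1
    list(g = edit_genotype(het1(), p, "qHMS1", "antidote"), fert = 0.0),
    list(g = edit_genotype(ta_genotype("1M1M", p), p, "qHMS1", "antidote"),
         fert = 0.0),
    list(g = ta_genotype("1D1D", p, transgenes = list(ttg)), fert = 0.0),
    # toxin knocked out on the functional haplotype: F1 fully fertile
    list(g = edit_genotype(het1(), p, "qHMS1", "toxin"), fert = 1.0),
    # toxin knocked out only on the already-null haplotype: still semi-sterile
    list(g = ta_genotype("FA", p, hapB = "fa"), fert = 0.5),
    list(g = ta_genotype("1M1D", p, transgenes = list(atg)), fert = 0.75),
    list(g = double_het(p17()), fert = 0.25),
    list(g = edit_genotype(ta_genotype("1D1D", p), p, "qHMS1", "toxin"),
         fert = 1.0))
  for (cs in cases) {
    pan <- if (length(cs$g$loci) == 2) p17() else p
    expect_equal(pollen_fertility(cs$g, pan), cs$fert)
  }
})

test_that("stage-resolved abortion attributes doubly-killed pollen to the earliest stage", {
  pp <- p17()
  ab <- abortion_profile(double_het(pp), pp)
  expect_equal(ab[["uninucleate"]], 0.5)
  expect_equal(ab[["binucleate"]], 0.25)
  expect_equal(attr(ab, "viable_fraction"), 0.25)
  expect_equal(sum(ab) + attr(ab, "viable_fraction"), 1)

  ab1 <- abortion_profile(het1(), p1())
  expect_equal(as.numeric(ab1), 0.5)
  expect_equal(names(ab1), "uninucleate")

  ab0 <- abortion_profile(ta_genotype("1D1D", p1()), p1())
  expect_length(ab0, 0)

  # partial killing at both loci still sums to one with the viable fraction
  pk <- p17(0.7, 0.4)
  abk <- abortion_profile(double_het(pk), pk)
  expect_equal(sum(abk) + attr(abk, "viable_fraction"), 1, tolerance = 1e-12)
})

test_that("distributions normalise and are invariant to haplotype order", {
  set.seed(401)
  for (i in 1:20) {
    pan <- rand_panel(sample(1:3, 1))
    g <- rand_genotype(pan, n_tg = sample(0:2, 1))
    mg <- male_gametes(g, pan)
    expect_equal(sum(mg$classes$prior), 1, tolerance = 1e-12)
    if (mg$viable_fraction > 0)
      expect_equal(sum(mg$classes$post), 1, tolerance = 1e-12)
    expect_equal(mg$viable_fraction,
                 sum(mg$classes$prior * mg$classes$survival), tolerance = 1e-12)
    swapped <- g
    swapped$hapA <- g$hapB; swapped$hapB <- g$hapA
    expect_equal(pollen_fertility(swapped, pan), pollen_fertility(g, pan),
                 tolerance = 1e-12)
    expect_equal(abortion_profile(swapped, pan), abortion_profile(g, pan),
                 tolerance = 1e-12)
  }
})

test_that("Mendelian limit: k = 0 means no selection anywhere", {
  set.seed(402)
  for (i in 1:10) {
    L <- sample(1:3, 1)
    pan <- ta_panel(lapply(seq_len(L), function(j)
      ta_locus(paste0("L", j), as.character(j), k = 0)))
    g <- rand_genotype(pan)
    mg <- male_gametes(g, pan)
    expect_equal(mg$viable_fraction, 1)
    expect_equal(mg$classes$post, mg$classes$prior, tolerance = 1e-12)
  }
})

test_that("antidote states are irrelevant when no toxin is present", {
  set.seed(403)
  pan <- rand_panel(2)
  for (i in 1:10) {
    # toxin-free genotype: antidote alleles drawn at random
    hapA <- sample(c("fA", "fa"), 2, replace = TRUE)
    hapB <- sample(c("fA", "fa"), 2, replace = TRUE)
    g <- ta_genotype(hapA, pan, hapB = hapB)
    expect_equal(pollen_fertility(g, pan), 1)
    expect_length(abortion_profile(g, pan), 0)
  }
})

test_that("brute-force gamete enumeration equals closed-form fertility", {
  set.seed(404)
  for (i in 1:25) {
    pan <- rand_panel(sample(1:3, 1))
    g <- rand_genotype(pan, n_tg = sample(0:2, 1))
    expect_equal(pollen_fertility(g, pan), oracle_fertility(g, pan),
                 tolerance = 1e-12)
  }
})

test_that("edit_genotype performs biallelic or single-haplotype knockouts", {
  p <- p1()
  f1 <- het1()
  tko <- edit_genotype(f1, p, "qHMS1", "toxin")
  expect_equal(tko$hapA, "fA")
  expect_equal(tko$hapB, "fa")
  expect_equal(pollen_fertility(tko, p), 1.0)
  ako <- edit_genotype(f1, p, "qHMS1", "antidote")
  expect_equal(pollen_fertility(ako, p), 0.0)
  one <- edit_genotype(f1, p, "qHMS1", "toxin", mode = "knockout_hap", hap = "A")
  expect_equal(one$hapA, "fA")
  expect_equal(one$hapB, "fa")
  # knockout in the null homozygote changes nothing phenotypically
  dd <- edit_genotype(ta_genotype("1D1D", p), p, "qHMS1", "toxin")
  expect_equal(pollen_fertility(dd, p), 1.0)
})

test_that("genotype strings parse through aliases and explicit state tokens", {
  pp <- p17()
  a <- ta_genotype("1M1D;7D7M", pp)
  b <- ta_genotype(c("FA", "FA"), pp, hapB = c("fa", "fa"))
  expect_equal(genotype_key(a, pp), genotype_key(b, pp))
  expect_equal(genotype_key(a, pp), "1D1M;7D7M")
  c2 <- ta_genotype("FAfa;fa FA", pp)
  expect_equal(genotype_key(c2, pp), "1D1M;7D7M")
  expect_error(ta_genotype("1M1D", pp), "segments")
  expect_error(ta_genotype("1X1D;7D7M", pp), "cannot parse")
})

test_that("panel round-trips through JSON configuration", {
  cfg <- list(stages = c("uninucleate", "binucleate"),
              loci = list(
                list(id = "qHMS1", chromosome = "1", k = 0.97,
                     stage = "uninucleate", functional_origin = "Mer",
                     aliases = list(M = "FA", D = "fa"))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  pan <- read_panel_json(path)
  expect_s3_class(pan, "ta_panel")
  expect_equal(pan$loci$qHMS1$k, 0.97)
  g <- ta_genotype("1M1D", pan)
  expect_equal(pollen_fertility(g, pan), 1 - 0.97 / 2)
})
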