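## Seeded generators for every synthetic input the package consumes.
## One global integer seed drives named substreams (hash of generator name +
## seed), so adding a generator never perturbs existing fixtures.

#' Derive a named substream seed
#'
#' Maps a global integer seed and a stream name to a reproducible integer
#' seed below 2^31, by a polynomial hash of the name combined with the seed.
#'
#' @param seed Global integer seed.
#' @param name Stream name (e.g. `"cross_counts"`).
#' @return A single integer seed.
#' @export
stream_seed <- function(seed, name) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.double(seed)) %% m * 48271 + h * 7919 + 1) %% m)
}

#' Deterministic toy reference sequences for allele typing
#'
#' Builds the toy reference a desk-scale classifier needs: a toxin (HPT) CDS
#' of 902 codons plus a single terminal stop with no internal stop codons, an
#' antidote (HPA) CDS of 361 codons plus stop, a 200-bp promoter, and a
#' 1391-bp transposon template. Diagnostic lesion templates are attached:
#' the G-to-T change at HPT CDS position 2011 (first base of codon 671,
#' engineered as GGA so the change yields a TGA stop and a 670-aa product),
#' the transposon insertion 11 bp upstream of the HPA ATG, and the benign
#' Asn-to-Thr codon change in the HPA CDS.
#'
#' @param seed Integer seed (fixed default so the reference is stable).
#' @return An object of class `ta_reference`: list with `hpt_cds`,
#'   `hpa_cds`, `hpa_promoter`, `te_seq`, `hpt_aa_len` (902), `hpa_aa_len`
#'   (361), `promoter_window` (`c(-200, -1)`), `te_min_len` (50), and
#'   `variants` (list of lesion templates with `gene`, `pos`, `ref`, `alt`).
#' @export
gen_reference_toys <- function(seed = 19241112L) {
  codons <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"), paste0)),
                            c("A", "C", "G", "T"), paste0))
  nonstop <- setdiff(codons, c("TAA", "TAG", "TGA"))
  withr::with_seed(stream_seed(seed, "reference_toys"), {
    hpt <- c("ATG", sample(nonstop, 902L - 2L, replace = TRUE), "GGA")
    # codon 671 fixed to GGA: G>T at its first base (CDS nt 2011) makes TGA
    hpt[671L] <- "GGA"
    # keep the terminal coding codon free of the diagnostic too
    hpt[902L] <- "GCT"
    hpt_cds <- paste(c(hpt, "TAA"), collapse = "")
    hpa <- c("ATG", sample(nonstop, 361L - 1L, replace = TRUE))
    hpa[100L] <- "AAT"   # Asn codon carrying the benign Asn->Thr change
    hpa_cds <- paste(c(hpa, "TAA"), collapse = "")
    promoter <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                      collapse = "")
    te <- sample(c("A", "C", "G", "T"), 1391L, replace = TRUE)
    # first TE base must differ from the reference base at the insertion
    # point so the common-prefix rule recovers the exact position
    at <- substr(promoter, 190L, 190L)
    te[1L] <- sample(setdiff(c("A", "C", "G", "T"), at), 1L)
    te_seq <- paste(te, collapse = "")
    structure(list(
      hpt_cds = hpt_cds, hpa_cds = hpa_cds, hpa_promoter = promoter,
      te_seq = te_seq, hpt_aa_len = 902L, hpa_aa_len = 361L,
      hpt_stop_nt = 2011L,
      promoter_window = c(-200L, -1L), te_min_len = 50L,
      variants = list(
        hpt_premature_stop = list(gene = "HPT", pos = 2011L, ref = "G", alt = "T"),
        hpa_te_insertion = list(gene = "HPA_promoter", pos = -11L,
                                length = 1391L),
        hpa_asn_thr = list(gene = "HPA", pos = 299L, ref = "A", alt = "C"))),
      class = "ta_reference")
  })
}

## Apply a single-base substitution to a sequence string.
.substitute_base <- function(seq, pos, alt) {
  substr(seq, pos, pos) <- alt
  seq
}

## Insert `ins` so that the reference base at 1-based position `at` becomes
## the base immediately 3' of the insertion.
.insert_at <- function(seq, at, ins) {
  paste0(substr(seq, 1L, at - 1L), ins, substr(seq, at, nchar(seq)))
}

#' Mutated toy allele sequences
#'
#' Convenience constructors for the three diagnostic lesions on the toy
#' reference: the truncated HPT CDS, the transposon-silenced HPA promoter,
#' and the benign Asn-to-Thr HPA CDS.
#'
#' @param ref A [gen_reference_toys()] reference.
#' @return A character string.
#' @export
hpt_truncated_cds <- function(ref) {
  v <- ref$variants$hpt_premature_stop
  .substitute_base(ref$hpt_cds, v$pos, v$alt)
}

#' @rdname hpt_truncated_cds
#' @export
hpa_silenced_promoter <- function(ref) {
  v <- ref$variants$hpa_te_insertion
  .insert_at(ref$hpa_promoter, nchar(ref$hpa_promoter) + 1L + v$pos, ref$te_seq)
}

#' @rdname hpt_truncated_cds
#' @export
hpa_benign_cds <- function(ref) {
  v <- ref$variants$hpa_asn_thr
  .substitute_base(ref$hpa_cds, v$pos, v$alt)
}

#' Simulate a genotype count table from a cross design
#'
#' Draws `n` progeny genotypes multinomially from the model-predicted
#' distribution of a named cross design at the true parameters. The class
#' set is the full support at `k = 0` (uniform weights), so classes that the
#' killing model empties still appear with count 0.
#'
#' @param design `"self_het"`, `"testcross"` (null homozygote female x
#'   heterozygote male) or `"f2_double_het"`.
#' @param n Number of progeny.
#' @param seed Global integer seed (substream `"cross_counts"`).
#' @param k True killing efficiency (single-locus designs).
#' @param weights Optional [female_weights()] (f2 design).
#' @return A [ta_counts()] with the design tag set.
#' @examples
#' gen_cross_counts("self_het", n = 400, seed = 7, k = 1)  # no 1D1D class
#' @export
gen_cross_counts <- function(design = c("self_het", "testcross",
                                        "f2_double_het"),
                             n, seed, k = 1, weights = NULL) {
  design <- match.arg(design)
  if (design == "f2_double_het") {
    dist <- f2_double_het(qhms_panel(), weights)
    full <- f2_double_het(qhms_panel(), NULL)
  } else {
    panel <- qhms1_panel(k)
    het <- ta_genotype("1M1D", panel)
    dist <- if (design == "self_het") self_progeny(het, panel) else
      cross(ta_genotype("1D1D", panel), het, panel)
    panel0 <- qhms1_panel(0)
    het0 <- ta_genotype("1M1D", panel0)
    full <- if (design == "self_het") self_progeny(het0, panel0) else
      cross(ta_genotype("1D1D", panel0), het0, panel0)
  }
  classes <- sort(full$genotype)
  probs <- stats::setNames(numeric(length(classes)), classes)
  probs[dist$genotype] <- dist$probability
  draw <- withr::with_seed(stream_seed(seed, "cross_counts"),
                           stats::rmultinom(1, n, probs)[, 1L])
  ta_counts(stats::setNames(draw, classes), design = design)
}

#' Simulate a pollen-scoring tally
#'
#' Multinomial draw of `n_pollen` scored grains over (viable, aborted at
#' each stage) with probabilities from [abortion_profile()]; emulates
#' microscope counts of roughly 200 grains per spikelet.
#'
#' @param genotype A [ta_genotype()].
#' @param panel Its `ta_panel`.
#' @param n_pollen Number of grains scored (default 200).
#' @param seed Global integer seed (substream `"pollen_counts"`).
#' @return Named integer vector: `viable` plus one entry per aborting stage.
#' @export
gen_pollen_counts <- function(genotype, panel, n_pollen = 200L, seed) {
  ab <- abortion_profile(genotype, panel)
  probs <- c(viable = attr(ab, "viable_fraction"), as.numeric(ab))
  names(probs) <- c("viable", names(ab))
  draw <- withr::with_seed(stream_seed(seed, "pollen_counts"),
                           stats::rmultinom(1, n_pollen, probs)[, 1L])
  stats::setNames(draw, names(probs))
}

#' Simulate a variety survey (optionally with toy sequences)
#'
#' Samples accessions over the haplotype classes `FA`, `fA`, `fa` (the class
#' `Fa` violates the toxin-antidote coupling rule and is rejected unless the
#' constraint is disabled). When sequences are requested each accession gets
#' engineered toy records carrying its class-defining lesions: truncated or
#' absent HPT for `f` classes (choice itself seeded), transposon-silenced
#' promoter for `a` classes, and the benign Asn-to-Thr coding change on a
#' seeded subset of expressed antidote alleles.
#'
#' @param n Number of accessions.
#' @param class_freqs Named frequencies over `FA`, `fA`, `fa` (and `Fa` only
#'   if `constraint = FALSE`); needs not be normalised.
#' @param seed Global integer seed (substream `"survey"`).
#' @param species Species label recycled over accessions.
#' @param fasta If `TRUE`, also return a `DNAStringSet` of toy records named
#'   `<acc>|HPT_CDS` / `<acc>|HPA_promoter_cds`.
#' @param ref Reference from [gen_reference_toys()].
#' @param constraint Enforce the coupling rule (default `TRUE`).
#' @return List with `records` (variety-record data frame with columns
#'   `accession`, `species`, `hpt_class`, `hpa_class`, `haplotype_class`)
#'   and `fasta` (`DNAStringSet` or `NULL`).
#' @export
gen_survey <- function(n, class_freqs, seed, species = "O. rufipogon",
                       fasta = FALSE, ref = gen_reference_toys(),
                       constraint = TRUE) {
  if (is.null(names(class_freqs)))
    stop("class_freqs must be named by haplotype class", call. = FALSE)
  if (!all(names(class_freqs) %in% .DRIVE_CLASSES))
    stop("unknown haplotype class in class_freqs", call. = FALSE)
  if (constraint && isTRUE(class_freqs["Fa"] > 0))
    stop("class Fa violates the toxin-antidote coupling constraint", call. = FALSE)
  pf <- class_freqs / sum(class_freqs)

  withr::with_seed(stream_seed(seed, "survey"), {
    cls <- sample(names(pf), n, replace = TRUE, prob = pf)
    # which truncation-bearing accessions lost HPT entirely vs carry the stop
    hpt_lost <- stats::runif(n) < 0.5
    benign <- stats::runif(n) < 0.5
    acc <- sprintf("ACC%04d", seq_len(n))

    hpt_class <- ifelse(substr(cls, 1, 1) == "F", "functional",
                        ifelse(hpt_lost, "absent", "truncated"))
    hpa_class <- ifelse(substr(cls, 2, 2) == "A", "expressed_functional",
                        "te_silenced")
    records <- data.frame(accession = acc, species = species,
                          hpt_class = hpt_class, hpa_class = hpa_class,
                          haplotype_class = cls, stringsAsFactors = FALSE)
    fa_set <- NULL
    if (fasta) {
      seqs <- character(0)
      for (i in seq_len(n)) {
        if (hpt_class[i] == "functional")
          seqs[paste0(acc[i], "|HPT_CDS")] <- ref$hpt_cds
        else if (hpt_class[i] == "truncated")
          seqs[paste0(acc[i], "|HPT_CDS")] <- hpt_truncated_cds(ref)
        prom <- if (hpa_class[i] == "te_silenced") hpa_silenced_promoter(ref)
                else ref$hpa_promoter
        cds <- if (benign[i]) hpa_benign_cds(ref) else ref$hpa_cds
        seqs[paste0(acc[i], "|HPA_promoter_cds")] <- paste0(prom, cds)
      }
      fa_set <- Biostrings::DNAStringSet(seqs)
    }
    list(records = records, fasta = fa_set)
  })
}
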