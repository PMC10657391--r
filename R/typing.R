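## Rule-based classification of toy toxin (HPT) / antidote (HPA) alleles.
## HPT reference: 902-codon CDS; a diagnostic premature stop truncates the
## protein to 670 aa. HPA reference: 361-codon CDS behind a 200-bp promoter;
## the diagnostic lesion is a long transposon insertion 11 bp upstream of the
## ATG which silences transcription. Classification is rule-based on
## engineered toy sequences; no alignment to real genomes.

.check_dna <- function(x, what) {
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside A/C/G/T (ambiguity codes are not supported)",
         call. = FALSE)
  invisible(TRUE)
}

## Translate a CDS up to (and excluding) the first stop codon.
.translate_to_stop <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "error"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1L, stop_at - 1L) else aa
}

#' Classify a toxin (HPT) coding sequence
#'
#' Translates the CDS to its first stop codon and compares the product
#' length with the reference (902 aa): `functional` at full length,
#' `truncated` when shorter (the diagnostic G-to-T change at CDS position
#' 2011 yields a 670-aa product), `absent` when no record exists.
#'
#' @param cds CDS string (in frame, including the terminal stop codon), or
#'   `NULL`/`NA` for a missing gene.
#' @param ref Reference specification from [gen_reference_toys()].
#' @return An object of class `ta_hpt_call`: list with `class`,
#'   `protein_length`, `evidence`.
#' @export
classify_hpt <- function(cds, ref) {
  if (is.null(cds) || (length(cds) == 1L && is.na(cds)))
    return(structure(list(class = "absent", protein_length = NA_integer_,
                          evidence = "no HPT record"),
                     class = "ta_hpt_call"))
  stopifnot(is.character(cds), length(cds) == 1L)
  .check_dna(cds, "HPT CDS")
  if (nchar(cds) %% 3L != 0L)
    stop("HPT CDS length is not a multiple of 3", call. = FALSE)
  aa <- .translate_to_stop(cds)
  len <- nchar(aa)
  if (len < ref$hpt_aa_len) {
    structure(list(class = "truncated", protein_length = len,
                   evidence = sprintf("premature stop after codon %d (reference %d aa)",
                                      len, ref$hpt_aa_len)),
              class = "ta_hpt_call")
  } else {
    structure(list(class = "functional", protein_length = len,
                   evidence = sprintf("full-length product (%d aa)", len)),
              class = "ta_hpt_call")
  }
}

#' Classify an antidote (HPA) allele from promoter (+ CDS)
#'
#' The promoter is compared with the reference promoter (positions -200..-1
#' relative to the ATG, whose A is +1). An insertion at least
#' `ref$te_min_len` bp long (default 50, separating transposon insertions
#' from small indels) whose insertion point lies inside the promoter window
#' silences transcription: class `te_silenced`. Coding variants are reported
#' but never change the class — the known Asn-to-Thr substitution is benign.
#'
#' @param promoter Observed promoter string (`NULL` is an error: silencing
#'   cannot be assessed without the promoter).
#' @param cds Optional observed CDS; compared base-by-base with the
#'   reference when of equal length.
#' @param ref Reference specification from [gen_reference_toys()].
#' @return An object of class `ta_hpa_call`: list with `class`,
#'   `promoter_insertion_length`, `promoter_insertion_pos` (coordinate of the
#'   base immediately 3' of the insertion point, negative upstream of ATG),
#'   `coding_variants` (data frame pos/ref/alt), `evidence`.
#' @export
classify_hpa <- function(promoter, cds = NULL, ref) {
  if (is.null(promoter) || (length(promoter) == 1L && is.na(promoter)))
    stop("cannot assess silencing: promoter region missing", call. = FALSE)
  stopifnot(is.character(promoter), length(promoter) == 1L)
  .check_dna(promoter, "HPA promoter")
  refp <- ref$hpa_promoter
  plen <- nchar(refp)

  ins_len <- nchar(promoter) - plen
  ins_pos <- NA_integer_
  cls <- "expressed_functional"
  evid <- "promoter matches reference"
  if (ins_len > 0) {
    # locate the insertion via the longest common prefix with the reference
    obs <- strsplit(promoter, "")[[1L]]
    rf <- strsplit(refp, "")[[1L]]
    lcp <- 0L
    while (lcp < plen && obs[lcp + 1L] == rf[lcp + 1L]) lcp <- lcp + 1L
    ins_pos <- (lcp + 1L) - plen - 1L   # base immediately 3' of the insertion
    win <- ref$promoter_window
    if (ins_len >= ref$te_min_len && ins_pos >= win[1L] && ins_pos <= win[2L]) {
      cls <- "te_silenced"
      evid <- sprintf("%d-bp insertion at promoter position %d", ins_len, ins_pos)
    } else {
      evid <- sprintf("small or out-of-window insertion (%d bp at %d); expression retained",
                      ins_len, ins_pos)
    }
  }

  variants <- data.frame(pos = integer(0), ref = character(0),
                         alt = character(0), stringsAsFactors = FALSE)
  if (!is.null(cds) && !(length(cds) == 1L && is.na(cds))) {
    .check_dna(cds, "HPA CDS")
    if (nchar(cds) == nchar(ref$hpa_cds)) {
      a <- strsplit(cds, "")[[1L]]
      b <- strsplit(ref$hpa_cds, "")[[1L]]
      d <- which(a != b)
      variants <- data.frame(pos = d, ref = b[d], alt = a[d],
                             stringsAsFactors = FALSE)
    } else {
      variants <- data.frame(pos = NA_integer_, ref = "indel", alt = "indel",
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(class = cls, promoter_insertion_length =
                   if (ins_len > 0) ins_len else NA_integer_,
                 promoter_insertion_pos = ins_pos,
                 coding_variants = variants, evidence = evid),
            class = "ta_hpa_call")
}

#' Haplotype class from an allele call pair
#'
#' Total map: toxin letter `F` iff the HPT call is `functional`; antidote
#' letter `A` iff the HPA call is `expressed_functional`.
#'
#' @param hpt_class,hpa_class Class strings (or call objects) for the two
#'   genes.
#' @return One of `"FA"`, `"fA"`, `"Fa"`, `"fa"`.
#' @export
haplotype_class <- function(hpt_class, hpa_class) {
  if (inherits(hpt_class, "ta_hpt_call")) hpt_class <- hpt_class$class
  if (inherits(hpa_class, "ta_hpa_call")) hpa_class <- hpa_class$class
  stopifnot(hpt_class %in% c("functional", "truncated", "absent"),
            hpa_class %in% c("expressed_functional", "te_silenced", "absent"))
  paste0(if (hpt_class == "functional") "F" else "f",
         if (hpa_class == "expressed_functional") "A" else "a")
}

#' Classify every accession in a FASTA panel
#'
#' FASTA record naming convention: `<accession>|HPT_CDS` carries the toxin
#' CDS, `<accession>|HPA_promoter_cds` the promoter followed by the antidote
#' CDS (the CDS is taken as the trailing `nchar(ref$hpa_cds)` bases; the toy
#' panel has no coding indels). Accessions lacking an HPT record are typed
#' `absent` for the toxin.
#'
#' @param fasta Path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @param ref Reference specification from [gen_reference_toys()].
#' @param species Species label(s) recycled over accessions, or a named
#'   vector keyed by accession.
#' @return A data frame of `VarietyRecord`s: `accession`, `species`,
#'   `hpt_class`, `hpt_protein_length`, `hpa_class`, `haplotype_class`.
#' @export
classify_fasta <- function(fasta, ref, species = NA_character_) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  nm <- names(seqs)
  parts <- strsplit(nm, "|", fixed = TRUE)
  acc <- vapply(parts, `[[`, character(1), 1L)
  what <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", character(1))
  accessions <- unique(acc)
  sp <- if (!is.null(names(species))) species[accessions] else
    rep_len(species, length(accessions))
  rows <- lapply(seq_along(accessions), function(i) {
    a <- accessions[i]
    hpt_seq <- nm[acc == a & what == "HPT_CDS"]
    hpt <- classify_hpt(if (length(hpt_seq)) as.character(seqs[[hpt_seq[1L]]]) else NULL,
                        ref)
    hpa_nm <- nm[acc == a & what == "HPA_promoter_cds"]
    if (!length(hpa_nm))
      stop("accession ", a, " has no HPA_promoter_cds record", call. = FALSE)
    full <- as.character(seqs[[hpa_nm[1L]]])
    cds_len <- nchar(ref$hpa_cds)
    hpa <- classify_hpa(substr(full, 1L, nchar(full) - cds_len),
                        substr(full, nchar(full) - cds_len + 1L, nchar(full)),
                        ref)
    data.frame(accession = a, species = sp[i],
               hpt_class = hpt$class, hpt_protein_length = hpt$protein_length,
               hpa_class = hpa$class,
               haplotype_class = haplotype_class(hpt, hpa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise an allele survey
#'
#' Per-species counts and percentages (one decimal) of each haplotype class
#' and of each per-gene allele class.
#'
#' @param records Data frame of variety records with columns `species`,
#'   `hpt_class`, `hpa_class`, `haplotype_class` (as from [classify_fasta()]
#'   or [gen_survey()]).
#' @param group_by Grouping column (default `"species"`).
#' @return A data frame with columns `group`, `category` (`haplotype`,
#'   `hpt`, `hpa`), `class`, `count`, `total`, `percent`.
#' @export
survey_summarize <- function(records, group_by = "species") {
  stopifnot(group_by %in% names(records))
  groups <- unique(records[[group_by]])
  out <- list()
  for (g in groups) {
    sub <- records[records[[group_by]] == g, , drop = FALSE]
    if (!nrow(sub)) { warning("empty group omitted: ", g); next }
    for (cat_col in c(haplotype = "haplotype_class", hpt = "hpt_class",
                      hpa = "hpa_class")) {
      tb <- table(sub[[cat_col]])
      out[[length(out) + 1L]] <- data.frame(
        group = g,
        category = names(which(c(haplotype = "haplotype_class",
                                 hpt = "hpt_class",
                                 hpa = "hpa_class") == cat_col)),
        class = names(tb), count = as.integer(tb), total = nrow(sub),
        percent = round(100 * as.integer(tb) / nrow(sub), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Audit the toxin-antidote coupling rule
#'
#' A functional toxin must ride with an expressed antidote: a haplotype
#' with a live toxin but silenced antidote (`Fa`) would sterilise its own
#' carriers and is never expected in surveys. Returns every record violating
#' the rule; an empty result is an audit pass.
#'
#' @param records Data frame of variety records with a `haplotype_class`
#'   column.
#' @return The violating rows (possibly zero-row).
#' @export
coupling_audit <- function(records) {
  records[records$haplotype_class == "Fa", , drop = FALSE]
}

#' Predict F1 pollen fertility for a parental combination
#'
#' Builds the F1 genotype at the toxin-antidote locus from two parental
#' haplotype classes and computes its pollen fertility under complete
#' killing. Varieties with a dead toxin but expressed antidote (`fA`) are
#' compatible with every partner (wide compatibility).
#'
#' @param class1,class2 Parental haplotype classes (`"FA"`, `"fA"`, `"Fa"`,
#'   `"fa"`), or variety-record rows carrying a `haplotype_class` column.
#' @return List with `f1_pollen_fertility` (fraction) and `label`
#'   (`"compatible"`, `"semi-sterile"`, `"sterile"`, or the percent string
#'   for intermediate values).
#' @examples
#' predict_cross_sterility("FA", "fa")  # 0.5, semi-sterile
#' predict_cross_sterility("fA", "FA")  # 1.0, compatible
#' @export
predict_cross_sterility <- function(class1, class2) {
  pick <- function(x) {
    if (is.data.frame(x)) x <- x$haplotype_class
    if (is.na(x) || !x %in% .STATE_TOKENS)
      stop("parent is not typed at the locus", call. = FALSE)
    x
  }
  c1 <- pick(class1); c2 <- pick(class2)
  panel <- ta_panel(ta_locus("qHMS1", "1", k = 1, abortion_stage = "uninucleate"))
  fert <- pollen_fertility(ta_genotype(c1, panel, hapB = c2), panel)
  label <- if (abs(fert - 1) < 1e-12) "compatible"
           else if (abs(fert - 0.5) < 1e-12) "semi-sterile"
           else if (fert < 1e-12) "sterile"
           else sprintf("%.1f%% fertile", 100 * fert)
  list(f1_pollen_fertility = fert, label = label)
}
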