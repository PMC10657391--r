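#' @keywords internal
"_PACKAGE"

## Haplotype state tokens: two characters, toxin then antidote.
## Upper case = functional copy. "FA" toxin+ antidote+, "fa" double null, etc.
.STATE_TOKENS <- c("FA", "fA", "Fa", "fa")

.tok_toxin <- function(tok) substr(tok, 1L, 1L) == "F"
.tok_antidote <- function(tok) substr(tok, 2L, 2L) == "A"

#' Describe one toxin-antidote locus
#'
#' A toxin-antidote (TA) locus is a pair of absolutely linked genes: a toxin
#' expressed sporophytically (the diploid plant poisons all of its pollen if
#' either haplotype, or a toxin transgene, carries a functional copy) and an
#' antidote acting gametophytically in cis (only pollen whose own haplotype,
#' or a carried transgene, has a functional antidote is protected).
#'
#' @param locus_id Locus name, e.g. `"qHMS1"`.
#' @param chromosome Chromosome label used as a prefix when printing allele
#'   aliases (e.g. `"1"` so the Mer allele prints as `"1M"`).
#' @param k Killing efficiency: probability in `[0, 1]` that an unprotected
#'   pollen grain exposed to the toxin is eliminated. Default 1 (complete
#'   killing).
#' @param abortion_stage Pollen developmental stage at which killing by this
#'   locus manifests; must belong to the panel's ordered stage vocabulary.
#' @param functional_origin Free-text label for the origin of the functional
#'   haplotype (`"Mer"` for qHMS1, `"DJY1"` for qHMS7).
#' @param aliases Named character vector mapping single-letter allele aliases
#'   to state tokens, e.g. `c(M = "FA", D = "fa")`.
#' @return An object of class `ta_locus`.
#' @examples
#' ta_locus("qHMS1", "1", k = 1, abortion_stage = "uninucleate",
#'          functional_origin = "Mer", aliases = c(M = "FA", D = "fa"))
#' @export
ta_locus <- function(locus_id, chromosome = NA_character_, k = 1.0,
                     abortion_stage = "uninucleate",
                     functional_origin = NA_character_, aliases = NULL) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > 1)
    stop("killing efficiency k must be a single number in [0, 1]", call. = FALSE)
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop("aliases must be a named character vector", call. = FALSE)
    if (!all(aliases %in% .STATE_TOKENS))
      stop("alias values must be state tokens: ", paste(.STATE_TOKENS, collapse = ", "),
           call. = FALSE)
  }
  structure(
    list(locus_id = locus_id, chromosome = chromosome,
         toxin_action = "sporophytic", antidote_action = "gametophytic_cis",
         k = k, abortion_stage = abortion_stage,
         functional_origin = functional_origin,
         aliases = aliases),
    class = "ta_locus")
}

#' Assemble a locus panel
#'
#' @param ... `ta_locus` objects, in map order.
#' @param stages Ordered vocabulary of pollen developmental stages (earliest
#'   first). Every locus `abortion_stage` must be a member.
#' @return An object of class `ta_panel`: a list with elements `loci` (named
#'   list of `ta_locus`) and `stages`.
#' @export
ta_panel <- function(..., stages = c("uninucleate", "binucleate")) {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1L]]) && !inherits(loci[[1L]], "ta_locus"))
    loci <- loci[[1L]]
  if (!length(loci)) stop("panel needs at least one locus", call. = FALSE)
  if (!all(vapply(loci, inherits, logical(1), "ta_locus")))
    stop("all panel members must be ta_locus objects", call. = FALSE)
  ids <- vapply(loci, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) stop("duplicated locus_id in panel", call. = FALSE)
  st <- vapply(loci, `[[`, character(1), "abortion_stage")
  if (!all(st %in% stages))
    stop("abortion_stage must be one of: ", paste(stages, collapse = " < "),
         call. = FALSE)
  names(loci) <- ids
  structure(list(loci = loci, stages = stages), class = "ta_panel")
}

#' @export
print.ta_panel <- function(x, ...) {
  cat("Toxin-antidote locus panel (", length(x$loci), " loci; stages: ",
      paste(x$stages, collapse = " < "), ")\n", sep = "")
  for (lc in x$loci) {
    al <- if (is.null(lc$aliases)) "" else
      paste0("  [", paste(names(lc$aliases), "=", lc$aliases, collapse = ", "), "]")
    cat(sprintf("  %-8s chr %-3s k = %.4g  stage = %s  functional origin = %s%s\n",
                lc$locus_id, lc$chromosome, lc$k, lc$abortion_stage,
                lc$functional_origin, al))
  }
  invisible(x)
}

#' Standard qHMS1 + qHMS7 panel
#'
#' The two-locus panel of the rice hybrid-sterility system: at qHMS1 the
#' functional (toxin+antidote) haplotype comes from the wild species
#' O. meridionalis (allele alias `M`) and the cultivated DJY1 allele (`D`) is
#' a double null; at qHMS7 the polarity is reversed (`D` functional, `M`
#' null). qHMS1 aborts pollen at the uninucleate stage, qHMS7 at the
#' binucleate stage.
#'
#' @param k1,k7 Killing efficiencies of qHMS1 and qHMS7.
#' @return A `ta_panel` with loci `qHMS1` and `qHMS7`.
#' @export
qhms_panel <- function(k1 = 1, k7 = 1) {
  ta_panel(
    ta_locus("qHMS1", "1", k = k1, abortion_stage = "uninucleate",
             functional_origin = "Mer", aliases = c(M = "FA", D = "fa")),
    ta_locus("qHMS7", "7", k = k7, abortion_stage = "binucleate",
             functional_origin = "DJY1", aliases = c(D = "FA", M = "fa")))
}

#' Single-locus qHMS1 panel
#'
#' @param k Killing efficiency.
#' @return A `ta_panel` with the single locus `qHMS1`.
#' @export
qhms1_panel <- function(k = 1) {
  ta_panel(ta_locus("qHMS1", "1", k = k, abortion_stage = "uninucleate",
                    functional_origin = "Mer", aliases = c(M = "FA", D = "fa")))
}

#' Read a locus panel from a JSON configuration file
#'
#' Expected layout:
#' `{"stages": ["uninucleate","binucleate"],
#'   "loci": [{"id": "qHMS1", "chromosome": "1", "k": 1.0,
#'             "stage": "uninucleate", "functional_origin": "Mer",
#'             "aliases": {"M": "FA", "D": "fa"}}, ...]}`
#'
#' @param path Path to the JSON file.
#' @return A `ta_panel`.
#' @export
read_panel_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$loci)) stop("panel config has no 'loci' entry", call. = FALSE)
  stages <- if (is.null(cfg$stages)) c("uninucleate", "binucleate") else
    unlist(cfg$stages)
  loci <- lapply(cfg$loci, function(l) {
    ta_locus(l$id,
             chromosome = if (is.null(l$chromosome)) NA_character_ else l$chromosome,
             k = if (is.null(l$k)) 1.0 else l$k,
             abortion_stage = if (is.null(l$stage)) stages[1L] else l$stage,
             functional_origin = if (is.null(l$functional_origin)) NA_character_
                                 else l$functional_origin,
             aliases = if (is.null(l$aliases)) NULL else unlist(l$aliases))
  })
  ta_panel(loci, stages = stages)
}

.panel_k <- function(panel) vapply(panel$loci, `[[`, numeric(1), "k")

#' Replace killing efficiencies on a panel
#'
#' @param panel A `ta_panel`.
#' @param k Named numeric vector of killing efficiencies (names = locus ids),
#'   or a single unnamed value recycled over all loci.
#' @return The modified panel.
#' @export
set_k <- function(panel, k) {
  stopifnot(inherits(panel, "ta_panel"))
  if (is.null(names(k))) {
    if (length(k) == 1L) k <- stats::setNames(rep(k, length(panel$loci)),
                                              names(panel$loci))
    else stop("k must be named or a single value", call. = FALSE)
  }
  for (id in names(k)) {
    if (!id %in% names(panel$loci)) stop("unknown locus_id: ", id, call. = FALSE)
    panel$loci[[id]] <- ta_locus(id, panel$loci[[id]]$chromosome, k[[id]],
                                 panel$loci[[id]]$abortion_stage,
                                 panel$loci[[id]]$functional_origin,
                                 panel$loci[[id]]$aliases)
  }
  panel
}

## ---- transgenes -----------------------------------------------------------

#' Define an unlinked transgene
#'
#' Transgenes model genomic-fragment constructs carrying a toxin or antidote
#' copy inserted at one unlinked locus. A hemizygous (single-copy) transgene
#' is transmitted to half the gametes; a homozygous one to all.
#'
#' @param payload `"toxin"` or `"antidote"`.
#' @param target_locus Locus id whose toxin/antidote the construct supplies.
#' @param zygosity `"hemizygous"` (default) or `"homozygous"`.
#' @return An object of class `ta_transgene`.
#' @export
ta_transgene <- function(payload = c("antidote", "toxin"), target_locus,
                         zygosity = c("hemizygous", "homozygous")) {
  payload <- match.arg(payload)
  zygosity <- match.arg(zygosity)
  stopifnot(is.character(target_locus), length(target_locus) == 1L)
  structure(list(payload = payload, target_locus = target_locus,
                 zygosity = zygosity), class = "ta_transgene")
}

.tg_token <- function(tg) paste0(tg$payload, "Tg(", tg$target_locus, ")")

## ---- genotype parsing and construction ------------------------------------

.parse_segment <- function(seg, locus) {
  raw <- gsub("[^A-Za-z]", "", seg)   # strip digits / separators (e.g. "1M1D")
  toks <- character(0)
  i <- 1L
  while (i <= nchar(raw)) {
    two <- substr(raw, i, i + 1L)
    if (two %in% .STATE_TOKENS) {
      toks <- c(toks, two); i <- i + 2L
    } else {
      one <- substr(raw, i, i)
      if (!is.null(locus$aliases) && one %in% names(locus$aliases)) {
        toks <- c(toks, unname(locus$aliases[[one]])); i <- i + 1L
      } else {
        stop("cannot parse allele token at '", substr(raw, i, nchar(raw)),
             "' for locus ", locus$locus_id, call. = FALSE)
      }
    }
  }
  if (length(toks) != 2L)
    stop("segment '", seg, "' must contain exactly two alleles for locus ",
         locus$locus_id, call. = FALSE)
  toks
}

#' Construct a diploid genotype
#'
#' Genotypes may be given as a string in the field's shorthand: one segment
#' per panel locus, segments joined by `";"`, each segment two allele tokens.
#' Tokens are either locus aliases (`"1M1D;7D7M"`, digits ignored) or
#' explicit state tokens `FA`, `fA`, `Fa`, `fa` (toxin then antidote; upper
#' case = functional). Alternatively pass two explicit haplotypes as
#' character vectors of state tokens (one per locus).
#'
#' Haplotype order carries no meaning: all model output is invariant under
#' swapping `hapA` and `hapB`.
#'
#' @param x Genotype string, or a character vector of state tokens for the
#'   first haplotype.
#' @param panel A `ta_panel`.
#' @param hapB Second haplotype (state-token vector) when `x` is a haplotype.
#' @param transgenes List of [ta_transgene()] objects carried by the plant.
#' @return An object of class `ta_genotype`.
#' @examples
#' p <- qhms_panel()
#' ta_genotype("1M1D;7D7M", p)                     # double heterozygote
#' ta_genotype(c("FA", "fa"), p, c("fa", "FA"))    # same thing, explicit
#' @export
ta_genotype <- function(x, panel, hapB = NULL, transgenes = list()) {
  stopifnot(inherits(panel, "ta_panel"))
  L <- length(panel$loci)
  if (inherits(transgenes, "ta_transgene")) transgenes <- list(transgenes)
  if (is.null(hapB)) {
    stopifnot(is.character(x), length(x) == 1L)
    segs <- strsplit(x, ";", fixed = TRUE)[[1L]]
    if (length(segs) != L)
      stop("genotype string has ", length(segs), " segments; panel has ",
           L, " loci", call. = FALSE)
    hapA <- hapB <- character(L)
    for (i in seq_len(L)) {
      pr <- .parse_segment(segs[i], panel$loci[[i]])
      hapA[i] <- pr[1L]; hapB[i] <- pr[2L]
    }
  } else {
    hapA <- x
    if (length(hapA) != L || length(hapB) != L)
      stop("haplotypes must have one state token per panel locus", call. = FALSE)
    if (!all(c(hapA, hapB) %in% .STATE_TOKENS))
      stop("haplotype entries must be state tokens ",
           paste(.STATE_TOKENS, collapse = ", "), call. = FALSE)
  }
  for (tg in transgenes) {
    if (!inherits(tg, "ta_transgene")) stop("transgenes must be ta_transgene objects",
                                            call. = FALSE)
    if (!tg$target_locus %in% names(panel$loci))
      stop("transgene targets unknown locus: ", tg$target_locus, call. = FALSE)
  }
  structure(list(hapA = hapA, hapB = hapB, transgenes = transgenes,
                 loci = names(panel$loci)),
            class = "ta_genotype")
}

.check_genotype_panel <- function(genotype, panel) {
  if (!inherits(genotype, "ta_genotype")) stop("not a ta_genotype", call. = FALSE)
  if (!identical(genotype$loci, names(panel$loci)))
    stop("genotype was built on a different locus panel", call. = FALSE)
  invisible(TRUE)
}

## Display token for a state token at a locus: alias + chromosome prefix when
## an alias exists ("1M"), otherwise the raw state token with locus prefix.
.display_token <- function(tok, locus) {
  if (!is.null(locus$aliases)) {
    hit <- names(locus$aliases)[match(tok, locus$aliases)]
    if (!is.na(hit)) {
      pre <- if (is.na(locus$chromosome)) "" else locus$chromosome
      return(paste0(pre, hit))
    }
  }
  paste0(if (is.na(locus$chromosome)) "" else locus$chromosome, tok)
}

.tg_suffix <- function(counts) {
  # counts: named integer vector of transgene copy numbers
  if (!length(counts)) return("")
  nm <- sort(names(counts))
  paste0(" +", paste(vapply(nm, function(x) {
    if (counts[[x]] > 1L) paste0(x, "x", counts[[x]]) else x
  }, character(1)), collapse = " +"))
}

.genotype_tg_counts <- function(genotype) {
  if (!length(genotype$transgenes)) return(integer(0))
  tok <- vapply(genotype$transgenes, .tg_token, character(1))
  cp <- vapply(genotype$transgenes, function(tg)
    if (tg$zygosity == "homozygous") 2L else 1L, integer(1))
  tapply(cp, tok, sum)
}

#' Canonical genotype key
#'
#' With free recombination between loci, a genotype is fully characterised by
#' its unordered allele pair at each locus. The key sorts the two display
#' tokens within each locus, joins loci with `";"`, and appends transgene
#' copies, e.g. `"1D1M;7D7M"` or `"1D1M +antidoteTg(qHMS1)"`.
#'
#' @param genotype A `ta_genotype`.
#' @param panel The panel it was built on.
#' @return A single string.
#' @export
genotype_key <- function(genotype, panel) {
  .check_genotype_panel(genotype, panel)
  segs <- vapply(seq_along(panel$loci), function(i) {
    lc <- panel$loci[[i]]
    paste(sort(c(.display_token(genotype$hapA[i], lc),
                 .display_token(genotype$hapB[i], lc))), collapse = "")
  }, character(1))
  paste0(paste(segs, collapse = ";"), .tg_suffix(.genotype_tg_counts(genotype)))
}

#' @export
print.ta_genotype <- function(x, ...) {
  cat("<ta_genotype> ", paste(x$hapA, collapse = ";"), " / ",
      paste(x$hapB, collapse = ";"), sep = "")
  if (length(x$transgenes))
    cat(" ", .tg_suffix(.genotype_tg_counts(x)), sep = "")
  cat("  (loci: ", paste(x$loci, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Double heterozygote on a two-locus panel
#'
#' Builds the plant heterozygous at every panel locus for the functional and
#' null haplotype (e.g. `1M1D;7D7M` on the standard panel).
#'
#' @param panel A `ta_panel`.
#' @return A `ta_genotype`.
#' @export
double_het <- function(panel) {
  L <- length(panel$loci)
  ta_genotype(rep("FA", L), panel, hapB = rep("fa", L))
}
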