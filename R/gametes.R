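#' Is the pollen population of a plant exposed to a locus toxin?
#'
#' The toxin acts sporophytically: it is produced by the diploid plant and
#' delivered to all of its pollen. Exposure therefore requires only that one
#' of the two haplotypes carries a functional toxin at the locus, or that the
#' plant carries a toxin-payload transgene targeting the locus.
#'
#' @param genotype A [ta_genotype()].
#' @param panel The `ta_panel` the genotype was built on.
#' @param locus_id Locus to interrogate.
#' @return `TRUE` or `FALSE`.
#' @export
toxin_exposure <- function(genotype, panel, locus_id) {
  .check_genotype_panel(genotype, panel)
  i <- match(locus_id, names(panel$loci))
  if (is.na(i)) stop("unknown locus_id: ", locus_id, call. = FALSE)
  if (.tok_toxin(genotype$hapA[i]) || .tok_toxin(genotype$hapB[i])) return(TRUE)
  for (tg in genotype$transgenes)
    if (tg$payload == "toxin" && tg$target_locus == locus_id) return(TRUE)
  FALSE
}

#' Is a single gamete protected at a locus?
#'
#' The antidote acts gametophytically in cis: only the gamete's own haplotype
#' (or a transgene copy the gamete itself carries) protects it. The antidote
#' on the other parental haplotype never does.
#'
#' @param hap Character vector of state tokens: the gamete's haplotype.
#' @param panel The `ta_panel`.
#' @param locus_id Locus to interrogate.
#' @param transgenes_carried Character vector of transgene tokens carried by
#'   the gamete (as produced by [male_gametes()]), or a list of
#'   [ta_transgene()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
gamete_protected <- function(hap, panel, locus_id, transgenes_carried = character(0)) {
  i <- match(locus_id, names(panel$loci))
  if (is.na(i)) stop("unknown locus_id: ", locus_id, call. = FALSE)
  if (length(hap) != length(panel$loci))
    stop("gamete haplotype not defined on this panel", call. = FALSE)
  if (.tok_antidote(hap[i])) return(TRUE)
  if (is.list(transgenes_carried))
    transgenes_carried <- vapply(transgenes_carried, .tg_token, character(1))
  any(transgenes_carried == .tg_token(ta_transgene("antidote", locus_id)))
}

## Internal: enumerate male gamete classes of a genotype.
## Returns a list of classes, each list(hap, tg (character tokens), prior).
.enumerate_gametes <- function(genotype, panel) {
  L <- length(panel$loci)
  choice <- expand.grid(rep(list(c(1L, 2L)), L))  # 1 = hapA allele, 2 = hapB
  haps <- lapply(seq_len(nrow(choice)), function(r) {
    ifelse(unlist(choice[r, ]) == 1L, genotype$hapA, genotype$hapB)
  })
  hap_prior <- rep(0.5^L, length(haps))

  tgs <- genotype$transgenes
  if (length(tgs)) {
    hemi <- which(vapply(tgs, function(t) t$zygosity == "hemizygous", logical(1)))
    homo_tok <- vapply(tgs[setdiff(seq_along(tgs), hemi)], .tg_token, character(1))
    sub <- expand.grid(rep(list(c(FALSE, TRUE)), length(hemi)))
    if (!nrow(sub)) sub <- data.frame(row.names = 1)
    tg_sets <- lapply(seq_len(nrow(sub)), function(r) {
      carried <- hemi[unlist(sub[r, ])]
      c(homo_tok, vapply(tgs[carried], .tg_token, character(1)))
    })
    tg_prior <- rep(0.5^length(hemi), length(tg_sets))
  } else {
    tg_sets <- list(character(0))
    tg_prior <- 1
  }

  out <- vector("list", length(haps) * length(tg_sets))
  m <- 0L
  for (h in seq_along(haps)) for (t in seq_along(tg_sets)) {
    m <- m + 1L
    out[[m]] <- list(hap = haps[[h]], tg = tg_sets[[t]],
                     prior = hap_prior[h] * tg_prior[t])
  }
  out
}

## Internal: per-class survival and kill bookkeeping under the killing rule.
## For each class returns survival prob, the earliest stage at which a kill
## term < 1 applies, and the per-stage hazard schedule used for staged
## abortion attribution.
.class_survival <- function(cls, genotype, panel, exposure) {
  surv <- 1
  kill_stage <- NA_character_
  stage_hazard <- stats::setNames(numeric(length(panel$stages)), panel$stages)
  for (i in seq_along(panel$loci)) {
    lc <- panel$loci[[i]]
    if (!exposure[i]) next
    if (gamete_protected(cls$hap, panel, lc$locus_id, cls$tg)) next
    if (lc$k <= 0) next
    surv <- surv * (1 - lc$k)
    st <- lc$abortion_stage
    # combine hazards of same-stage loci: survive the stage iff surviving all
    stage_hazard[st] <- 1 - (1 - stage_hazard[st]) * (1 - lc$k)
    if (is.na(kill_stage) ||
        match(st, panel$stages) < match(kill_stage, panel$stages))
      kill_stage <- st
  }
  list(survival = surv, stage = kill_stage, stage_hazard = stage_hazard)
}

#' Male gamete distribution of a plant
#'
#' Enumerates every male gamete class (per-locus allele choice times carried
#' transgene subset) with its Mendelian prior frequency, then applies the
#' gamete-killing rule at each locus: a gamete exposed to a locus toxin and
#' not protected in cis survives that locus with probability `1 - k`. Loci
#' act independently; survival is the product over loci. A killed gamete is
#' attributed to the earliest developmental stage at which a kill term
#' applies.
#'
#' @param genotype A [ta_genotype()].
#' @param panel The `ta_panel`.
#' @return An object of class `ta_gametes`: a list with
#'   \describe{
#'     \item{classes}{data frame with columns `gamete` (display key),
#'       `prior`, `survival`, `stage` (earliest kill stage or `NA`), `post`
#'       (frequency among surviving pollen), plus list-columns `hap` and `tg`
#'       used by the crossing layer.}
#'     \item{viable_fraction}{overall fraction of pollen surviving,
#'       \eqn{\sum prior \times survival}.}
#'     \item{aborted_by_stage}{named vector of aborted fractions per stage,
#'       earliest-stage attribution.}
#'   }
#'   A fully sterile plant is returned with `viable_fraction = 0` and an
#'   all-zero `post` column (complete sterility is a model state, not an
#'   error).
#' @examples
#' p <- qhms1_panel()
#' male_gametes(ta_genotype("1M1D", p), p)  # only M pollen survives
#' @export
male_gametes <- function(genotype, panel) {
  .check_genotype_panel(genotype, panel)
  exposure <- vapply(names(panel$loci), function(id)
    toxin_exposure(genotype, panel, id), logical(1))
  classes <- .enumerate_gametes(genotype, panel)

  n <- length(classes)
  prior <- vapply(classes, `[[`, numeric(1), "prior")
  surv <- numeric(n)
  stage <- character(n)
  aborted <- stats::setNames(numeric(length(panel$stages)), panel$stages)
  for (j in seq_len(n)) {
    cs <- .class_survival(classes[[j]], genotype, panel, exposure)
    surv[j] <- cs$survival
    stage[j] <- if (is.na(cs$stage)) NA_character_ else cs$stage
    # sequential hazards in stage order: die at the first stage that kills
    remaining <- prior[j]
    for (st in panel$stages) {
      hz <- cs$stage_hazard[[st]]
      if (hz > 0) {
        aborted[st] <- aborted[st] + remaining * hz
        remaining <- remaining * (1 - hz)
      }
    }
  }
  viable <- sum(prior * surv)
  post <- if (viable > 0) prior * surv / viable else numeric(n)

  keys <- vapply(classes, function(cl) {
    hap_disp <- paste(vapply(seq_along(panel$loci), function(i)
      .display_token(cl$hap[i], panel$loci[[i]]), character(1)), collapse = "/")
    tgc <- if (length(cl$tg)) table(cl$tg) else integer(0)
    paste0(hap_disp, .tg_suffix(as.integer(tgc) |>
                                  stats::setNames(names(tgc))))
  }, character(1))

  cls_df <- data.frame(gamete = keys, prior = prior, survival = surv,
                       stage = stage, post = post, stringsAsFactors = FALSE)
  cls_df$hap <- I(lapply(classes, `[[`, "hap"))
  cls_df$tg <- I(lapply(classes, `[[`, "tg"))

  structure(list(classes = cls_df, viable_fraction = viable,
                 aborted_by_stage = aborted),
            class = "ta_gametes")
}

#' @export
print.ta_gametes <- function(x, digits = 4, ...) {
  cat("Male gamete distribution  (viable fraction ",
      format(round(100 * x$viable_fraction, 1), nsmall = 1), "%)\n", sep = "")
  df <- x$classes[, c("gamete", "prior", "survival", "stage", "post")]
  df$prior <- round(df$prior, digits)
  df$survival <- round(df$survival, digits)
  df$post <- round(df$post, digits)
  print(df, row.names = FALSE)
  ab <- x$aborted_by_stage[x$aborted_by_stage > 0]
  if (length(ab))
    cat("Aborted:", paste(sprintf("%s %.1f%%", names(ab), 100 * ab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Pollen fertility of a genotype
#'
#' The fraction of male gametes that survive all toxin-antidote killing:
#' the `viable_fraction` of [male_gametes()].
#'
#' @inheritParams male_gametes
#' @return A probability in `[0, 1]`.
#' @examples
#' p <- qhms1_panel()
#' pollen_fertility(ta_genotype("1M1M", p), p)  # 1.0, fertile NIL
#' pollen_fertility(ta_genotype("1M1D", p), p)  # 0.5, semi-sterile F1
#' @export
pollen_fertility <- function(genotype, panel) {
  male_gametes(genotype, panel)$viable_fraction
}

#' Stage-resolved pollen abortion profile
#'
#' Fraction of pollen aborted at each developmental stage, with a gamete
#' killed at several loci counted once at the earliest stage. Stages at which
#' nothing aborts are dropped; the retained fractions plus the viable
#' fraction sum to 1.
#'
#' @inheritParams male_gametes
#' @return Named numeric vector of aborted fractions (possibly empty), with
#'   attribute `viable_fraction`.
#' @export
abortion_profile <- function(genotype, panel) {
  g <- male_gametes(genotype, panel)
  out <- g$aborted_by_stage[g$aborted_by_stage > 0]
  attr(out, "viable_fraction") <- g$viable_fraction
  out
}

#' Apply a CRISPR-style knockout to a genotype
#'
#' Sets the named gene's functionality to non-functional at a locus, by
#' default on both haplotypes (biallelic editing, the usual CRISPR outcome),
#' or on one named haplotype. Transgenes are untouched.
#'
#' @param genotype A [ta_genotype()].
#' @param panel The `ta_panel`.
#' @param locus_id Locus to edit.
#' @param gene `"toxin"` or `"antidote"`.
#' @param mode `"knockout_both"` (default) or `"knockout_hap"`.
#' @param hap Which haplotype (`"A"` or `"B"`) when `mode = "knockout_hap"`.
#' @return The edited `ta_genotype`.
#' @export
edit_genotype <- function(genotype, panel, locus_id,
                          gene = c("toxin", "antidote"),
                          mode = c("knockout_both", "knockout_hap"),
                          hap = c("A", "B")) {
  .check_genotype_panel(genotype, panel)
  gene <- match.arg(gene)
  mode <- match.arg(mode)
  i <- match(locus_id, names(panel$loci))
  if (is.na(i)) stop("unknown locus_id: ", locus_id, call. = FALSE)
  pos <- if (gene == "toxin") 1L else 2L
  off <- if (gene == "toxin") "f" else "a"
  ko <- function(tok) { substr(tok, pos, pos) <- off; tok }
  if (mode == "knockout_both") {
    genotype$hapA[i] <- ko(genotype$hapA[i])
    genotype$hapB[i] <- ko(genotype$hapB[i])
  } else {
    hap <- match.arg(hap)
    if (hap == "A") genotype$hapA[i] <- ko(genotype$hapA[i])
    else genotype$hapB[i] <- ko(genotype$hapB[i])
  }
  genotype
}
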