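## Female gametes: same Mendelian enumeration as the male side but with no
## killing (single toxin-antidote loci do not act on ovules), optionally
## reweighted by joint-class transmission weights.
.female_gametes <- function(genotype, panel, weights = NULL) {
  classes <- .enumerate_gametes(genotype, panel)
  prior <- vapply(classes, `[[`, numeric(1), "prior")
  keys <- vapply(classes, function(cl)
    paste(vapply(seq_along(panel$loci), function(i)
      .display_token(cl$hap[i], panel$loci[[i]]), character(1)), collapse = "/"),
    character(1))
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "ta_female_weights"))
    w <- weights$weights[keys]
    if (anyNA(w))
      stop("female transmission weights missing for gamete class(es): ",
           paste(unique(keys[is.na(w)]), collapse = ", "), call. = FALSE)
    prior <- prior * w
    prior <- prior / sum(prior)
  }
  list(classes = classes, prior = prior, keys = keys)
}

#' Female joint-gamete transmission weights
#'
#' Single toxin-antidote loci leave ovules untouched, but stacked loci can
#' bias female transmission jointly. The bias is expressed as nonnegative
#' weights over joint female gamete classes (keyed by the gamete display
#' string, e.g. `"1M/7D"`), normalised to sum to 1. The default (no weights)
#' is uniform Mendelian transmission.
#'
#' @param weights Named nonnegative numeric vector, names = gamete class keys.
#' @return An object of class `ta_female_weights`.
#' @examples
#' female_weights(c("1D/7M" = 0.1, "1M/7M" = 0.2, "1D/7D" = 0.3, "1M/7D" = 0.4))
#' @export
female_weights <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by gamete class key", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  structure(list(weights = weights / sum(weights)), class = "ta_female_weights")
}

## Combine a female and a male gamete into an offspring ta_genotype.
.zygote <- function(fcl, mcl, panel) {
  tg_tok <- c(fcl$tg, mcl$tg)
  tgs <- list()
  if (length(tg_tok)) {
    tb <- table(tg_tok)
    tgs <- lapply(names(tb), function(tok) {
      m <- regmatches(tok, regexec("^(toxin|antidote)Tg\\((.+)\\)$", tok))[[1L]]
      ta_transgene(m[2L], m[3L],
                   zygosity = if (tb[[tok]] >= 2L) "homozygous" else "hemizygous")
    })
  }
  ta_genotype(fcl$hap, panel, hapB = mcl$hap, transgenes = tgs)
}

#' Progeny genotype distribution of a cross
#'
#' Combines the unselected (or weighted) female gamete pool of the seed
#' parent with the post-selection male gamete pool of the pollen parent.
#' Gamete pools combine as an independent product; transgene copies add.
#'
#' @param female,male `ta_genotype` seed and pollen parent.
#' @param panel The shared `ta_panel`.
#' @param weights Optional [female_weights()] applied to the female joint
#'   gamete classes.
#' @return An object of class `ta_progeny`: a data frame with columns
#'   `genotype` (canonical key), `probability` and `percent`, plus a
#'   list-column `g` holding a representative `ta_genotype` per class.
#'   Classes below 1e-15 are pruned after normalisation.
#' @examples
#' p <- qhms1_panel()
#' cross(ta_genotype("1D1D", p), ta_genotype("1M1D", p), p)  # all heterozygous
#' @export
cross <- function(female, male, panel, weights = NULL) {
  .check_genotype_panel(female, panel)
  .check_genotype_panel(male, panel)
  mg <- male_gametes(male, panel)
  if (mg$viable_fraction <= 0)
    stop("male parent fully sterile; cross yields no progeny", call. = FALSE)
  fg <- .female_gametes(female, panel, weights)

  keep <- which(mg$classes$post > 0)
  keys <- character(0); probs <- numeric(0); reps <- list()
  acc <- new.env(parent = emptyenv())
  for (fi in seq_along(fg$classes)) {
    if (fg$prior[fi] <= 0) next
    for (mi in keep) {
      pz <- fg$prior[fi] * mg$classes$post[mi]
      z <- .zygote(fg$classes[[fi]],
                   list(hap = mg$classes$hap[[mi]], tg = mg$classes$tg[[mi]]),
                   panel)
      key <- genotype_key(z, panel)
      if (is.null(acc[[key]])) {
        acc[[key]] <- pz
        reps[[key]] <- z
      } else acc[[key]] <- acc[[key]] + pz
    }
  }
  keys <- ls(acc)
  probs <- vapply(keys, function(k) acc[[k]], numeric(1))
  probs <- probs / sum(probs)
  drop <- probs < 1e-15
  if (any(drop)) {
    keys <- keys[!drop]; probs <- probs[!drop]; probs <- probs / sum(probs)
  }
  ord <- order(probs, keys, decreasing = TRUE)
  out <- data.frame(genotype = keys[ord], probability = probs[ord],
                    percent = round(100 * probs[ord], 1),
                    stringsAsFactors = FALSE)
  out$g <- I(unname(reps[keys[ord]]))
  class(out) <- c("ta_progeny", "data.frame")
  attr(out, "panel") <- panel
  out
}

#' @export
print.ta_progeny <- function(x, ...) {
  cat("Progeny genotype distribution (", nrow(x), " classes)\n", sep = "")
  df <- as.data.frame(x)[, c("genotype", "probability", "percent")]
  df$probability <- signif(df$probability, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Self progeny distribution
#'
#' @param genotype A `ta_genotype` with viable pollen.
#' @inheritParams cross
#' @return A `ta_progeny` distribution; see [cross()].
#' @examples
#' p <- qhms1_panel()
#' self_progeny(ta_genotype("1M1D", p), p)  # 1:1, no 1D1D at k = 1
#' @export
self_progeny <- function(genotype, panel, weights = NULL) {
  cross(genotype, genotype, panel, weights)
}

#' F2 distribution from the stacked double heterozygote
#'
#' With complete killing at both loci only one pollen class (the one carrying
#' both functional haplotypes, `1M/7D` on the standard panel) survives, so
#' each F2 genotype class maps one-to-one to a female gamete class and its
#' probability equals that gamete's transmission weight: four classes at
#' 1:1:1:1 under uniform transmission.
#'
#' @param panel A two-locus `ta_panel`; both killing efficiencies must be 1.
#' @param weights Optional [female_weights()] over the four female joint
#'   gamete classes.
#' @return A `ta_progeny` with four classes.
#' @export
f2_double_het <- function(panel = qhms_panel(), weights = NULL) {
  if (length(panel$loci) != 2L)
    stop("f2_double_het requires a two-locus panel", call. = FALSE)
  if (any(abs(.panel_k(panel) - 1) > 1e-12))
    stop("f2_double_het assumes killing efficiency 1 at both loci", call. = FALSE)
  self_progeny(double_het(panel), panel, weights)
}

#' Run a scripted pedigree
#'
#' Applies a list of named cross/self/edit steps to a pool of named
#' genotypes, tracking full genotype distributions. A step referring to a
#' distribution treats it as a mixture over its classes; classes that are
#' fully male-sterile contribute no selfed offspring (the cross errors only
#' if every class is sterile).
#'
#' Each step is a list with fields:
#' \describe{
#'   \item{`op`}{`"cross"`, `"self"` or `"edit"`.}
#'   \item{`name`}{name under which the result is stored.}
#'   \item{`female`, `male`}{(cross) names of existing entries.}
#'   \item{`genotype`}{(self/edit) name of an existing entry.}
#'   \item{`locus`, `gene`, `mode`}{(edit) arguments passed to
#'     [edit_genotype()].}
#' }
#'
#' @param steps List of step lists (possibly empty).
#' @param start Named list of `ta_genotype` starting material.
#' @param panel The `ta_panel`.
#' @param weights Optional [female_weights()] applied in every cross.
#' @return Named list of `ta_progeny` distributions, one per step, in order.
#' @export
pedigree <- function(steps, start, panel, weights = NULL) {
  stopifnot(is.list(steps), is.list(start), length(start) > 0)
  # pool maps name -> ta_progeny (start genotypes become point distributions)
  as_point <- function(g) {
    out <- data.frame(genotype = genotype_key(g, panel), probability = 1,
                      percent = 100, stringsAsFactors = FALSE)
    out$g <- I(list(g))
    class(out) <- c("ta_progeny", "data.frame")
    out
  }
  pool <- lapply(start, as_point)
  resolve <- function(nm) {
    if (is.null(pool[[nm]]))
      stop("pedigree step refers to undefined genotype: ", nm, call. = FALSE)
    pool[[nm]]
  }
  mix_cross <- function(fd, md) {
    # mixture over all parent class pairs; sterile male classes contribute 0
    acc <- list(); wsum <- 0
    for (i in seq_len(nrow(fd))) for (j in seq_len(nrow(md))) {
      mviab <- pollen_fertility(md$g[[j]], panel)
      if (mviab <= 0) next
      w <- fd$probability[i] * md$probability[j]
      acc[[length(acc) + 1L]] <- list(w = w,
                                      d = cross(fd$g[[i]], md$g[[j]], panel, weights))
      wsum <- wsum + w
    }
    if (!length(acc))
      stop("male parent fully sterile; cross yields no progeny", call. = FALSE)
    tab <- new.env(parent = emptyenv()); reps <- list()
    for (a in acc) for (r in seq_len(nrow(a$d))) {
      key <- a$d$genotype[r]
      p <- a$w / wsum * a$d$probability[r]
      if (is.null(tab[[key]])) { tab[[key]] <- p; reps[[key]] <- a$d$g[[r]] }
      else tab[[key]] <- tab[[key]] + p
    }
    keys <- ls(tab)
    probs <- vapply(keys, function(k) tab[[k]], numeric(1))
    probs <- probs / sum(probs)
    ord <- order(probs, keys, decreasing = TRUE)
    out <- data.frame(genotype = keys[ord], probability = probs[ord],
                      percent = round(100 * probs[ord], 1),
                      stringsAsFactors = FALSE)
    out$g <- I(unname(reps[keys[ord]]))
    class(out) <- c("ta_progeny", "data.frame")
    out
  }
  results <- list()
  for (s in steps) {
    if (is.null(s$op) || is.null(s$name))
      stop("each pedigree step needs 'op' and 'name'", call. = FALSE)
    res <- switch(s$op,
      cross = mix_cross(resolve(s$female), resolve(s$male)),
      self = { d <- resolve(s$genotype); mix_cross(d, d) },
      edit = {
        d <- resolve(s$genotype)
        d$g <- I(lapply(d$g, edit_genotype, panel = panel, locus_id = s$locus,
                        gene = s$gene,
                        mode = if (is.null(s$mode)) "knockout_both" else s$mode))
        d$genotype <- vapply(d$g, genotype_key, character(1), panel = panel)
        d
      },
      stop("unknown pedigree op: ", s$op, call. = FALSE))
    pool[[s$name]] <- res
    results[[s$name]] <- res
  }
  results
}
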