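#' Diversity statistics for one trait
#'
#' From a state frequency vector p: Na (observed states, \eqn{p_i > 0}),
#' effective state number \eqn{Ne = 1/\sum p_i^2}, Nei gene diversity
#' \eqn{h = 1 - \sum p_i^2} and Shannon index \eqn{I = -\sum p_i \log p_i}
#' (with \eqn{0 \log 0 := 0}). The plug-in estimators are the default; with
#' \code{unbiased = TRUE} gene diversity uses the small-sample correction
#' \eqn{n/(n-1) (1 - \sum p_i^2)} (and Ne its reciprocal complement).
#' Nothing is rounded internally.
#'
#' @param p frequency vector (must sum to 1 within 1e-9).
#' @param n denominator (genotypes scored).
#' @param unbiased apply the small-sample correction to h and Ne.
#' @return a one-row data.frame with columns Na, Ne, He, I, n.
#' @examples
#' traitDiversity(c(125, 1) / 126, 126)  # Ne 1.016, He 0.016, I 0.046
#' @export
traitDiversity <- function(p, n = NA_integer_, unbiased = FALSE) {
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies do not sum to 1")
  if (any(p < 0)) stop("negative frequency")
  sp2 <- sum(p^2)
  h <- 1 - sp2
  if (unbiased) {
    if (is.na(n) || n < 2L) stop("unbiased correction needs n >= 2")
    h <- n / (n - 1) * h
  }
  pos <- p[p > 0]
  data.frame(Na = length(pos),
             Ne = 1 / (1 - h),
             He = h,
             I = -sum(pos * log(pos)),
             n = as.integer(n))
}

#' Per-trait diversity table, overall or per group
#'
#' Computes [traitDiversity()] for every trait from the panel's (or each
#' group's) state frequencies, plus the summary statistics reported alongside:
#' arithmetic means and standard deviations of Na/Ne/He/I over traits, percent
#' polymorphism, probability of identity and differentiation capacity.
#'
#' @param tm a [TraitMatrix-class].
#' @param byGroup compute one table per group label instead of one overall.
#' @param unbiased see [traitDiversity()].
#' @param ppDenominator denominator convention for percent polymorphism:
#'   the full catalogue variable count (\code{"catalog"}, default) or the
#'   number of variables observed in the panel (\code{"observed"}).
#' @return with \code{byGroup = FALSE}, a data.frame (one row per trait;
#'   columns trait_key, Na, Ne, He, I, n) with attribute \code{"summary"}
#'   (list: means, sds, percentPolymorphicTraits, percentPolymorphic, PI,
#'   capacity). With \code{byGroup = TRUE}, a data.frame of per-group summary
#'   rows (group, n, Ne, He, I, pctP) with attribute \code{"tables"} holding
#'   the per-group trait tables.
#' @export
diversityTable <- function(tm, byGroup = FALSE, unbiased = FALSE,
                           ppDenominator = c("catalog", "observed")) {
  stopifnot(is(tm, "TraitMatrix"))
  ppDenominator <- match.arg(ppDenominator)
  one <- function(subset) {
    ft <- traitFrequencies(tm, subset)
    tab <- do.call(rbind, lapply(split(ft, factor(ft$trait_key, traitKeys(tm))),
      function(f) {
        td <- traitDiversity(f$p, f$n[1L], unbiased = unbiased)
        cbind(trait_key = f$trait_key[1L], td)
      }))
    rownames(tab) <- NULL
    attr(tab, "summary") <- list(
      means = colMeans(tab[c("Na", "Ne", "He", "I")]),
      sds = vapply(tab[c("Na", "Ne", "He", "I")], sd, 0),
      percentPolymorphicTraits = 100 * mean(tab$Na > 1L),
      percentPolymorphic = percentPolymorphicFreq(ft, nVariables(tm), ppDenominator),
      PI = prod(1 - tab$He),
      capacity = 1 / prod(1 - tab$He))
    tab
  }
  if (!byGroup) return(one(NULL))
  g <- groupLabels(tm)
  if (all(is.na(g))) stop("panel has no group labels")
  groups <- sort(unique(g[!is.na(g)]))
  tables <- lapply(groups, one)
  names(tables) <- groups
  out <- do.call(rbind, lapply(groups, function(gr) {
    s <- attr(tables[[gr]], "summary")
    data.frame(group = gr, n = sum(g == gr, na.rm = TRUE),
               Ne = s$means[["Ne"]], He = s$means[["He"]], I = s$means[["I"]],
               pctP = s$percentPolymorphic)
  }))
  attr(out, "tables") <- tables
  out
}

# %P from a frequency table: share of variables with 0 < p < 1.
percentPolymorphicFreq <- function(ft, V, denominator) {
  poly <- sum(ft$p > 0 & ft$p < 1, na.rm = TRUE)
  denom <- if (denominator == "catalog") V else sum(ft$p > 0, na.rm = TRUE)
  100 * poly / denom
}

#' Percent polymorphism from a one-hot matrix
#'
#' Percentage of variables segregating (column frequency strictly between 0
#' and 1) within a genotype subset.
#'
#' @param bm a matrix from [encodeBinary()].
#' @param subset optional row ids / indices / logical mask; default all rows.
#' @param denominator \code{"catalog"} (all V columns, default) or
#'   \code{"observed"} (variables present in at least one subset genotype).
#' @return a percentage in [0, 100].
#' @export
percentPolymorphic <- function(bm, subset = NULL,
                               denominator = c("catalog", "observed")) {
  denominator <- match.arg(denominator)
  rows <- if (is.null(subset)) seq_len(nrow(bm))
    else if (is.character(subset)) match(subset, rownames(bm))
    else if (is.logical(subset)) which(subset)
    else as.integer(subset)
  if (anyNA(rows)) stop("unknown accession id in subset")
  if (length(rows) == 0L) stop("empty subset")
  cf <- colMeans(bm[rows, , drop = FALSE], na.rm = TRUE)
  poly <- sum(cf > 0 & cf < 1, na.rm = TRUE)
  denom <- if (denominator == "catalog") ncol(bm) else sum(cf > 0, na.rm = TRUE)
  100 * poly / denom
}

#' Probability of identity and differentiation capacity
#'
#' Probability that two independent genotypes drawn from the panel's state
#' frequencies match at every polymorphic trait, assuming independence across
#' traits: \eqn{PI = \prod_t \sum_i p_{ti}^2} over polymorphic traits
#' (monomorphic traits contribute a factor 1). The differentiation capacity
#' is 1/PI, also reported as an order of magnitude.
#'
#' @param ft a frequency table from [traitFrequencies()].
#' @return list(PI, capacity, orderOfMagnitude).
#' @export
probabilityOfIdentity <- function(ft) {
  terms <- vapply(split(ft, ft$trait_key), function(f) {
    p <- f$p
    if (sum(p > 0, na.rm = TRUE) <= 1L) 1 else sum(p^2, na.rm = TRUE)
  }, 0)
  pi_ <- prod(terms)
  list(PI = pi_, capacity = 1 / pi_,
       orderOfMagnitude = floor(log10(1 / pi_)))
}
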