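#' Pairwise genotype distances from the one-hot matrix
#'
#' The default metric is the trait mismatch proportion m: the fraction of
#' co-scored traits at which two genotypes carry different states. For one-hot
#' categorical profiles any Nei-type identity is a monotone function of m, so
#' tree topologies are unaffected by the choice; \code{metric = "neilog"}
#' applies the -log(1 - m) transform (infinite when m = 1).
#'
#' @param bm a matrix from [encodeBinary()].
#' @param metric \code{"mismatch"} (default) or \code{"neilog"}.
#' @return a symmetric numeric matrix with accession ids as dimnames and
#'   attribute \code{metric}; pairs with zero co-scored traits get NA.
#' @export
genotypeDistance <- function(bm, metric = c("mismatch", "neilog")) {
  metric <- match.arg(metric)
  traits <- attr(bm, "traits")
  keys <- unique(traits)
  n <- nrow(bm)
  # state index per genotype/trait (NA = unscored)
  S <- matrix(NA_integer_, n, length(keys))
  for (j in seq_along(keys)) {
    cols <- which(traits == keys[j])
    sub <- bm[, cols, drop = FALSE]
    hit <- sub == 1L
    hit[is.na(hit)] <- FALSE
    idx <- max.col(hit, ties.method = "first")
    idx[rowSums(hit) == 0L] <- NA_integer_
    S[, j] <- idx
  }
  d <- matrix(0, n, n, dimnames = list(rownames(bm), rownames(bm)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    co <- !is.na(S[i, ]) & !is.na(S[j, ])
    d[i, j] <- d[j, i] <- if (!any(co)) NA_real_ else
      mean(S[i, co] != S[j, co])
  }
  if (metric == "neilog") d <- -log(1 - d)
  structure(d, metric = metric)
}

#' Nei genetic distance between groups
#'
#' Nei identity between two groups x and y is \eqn{I = J_{xy} / \sqrt{J_x J_y}}
#' with the J terms averaged across traits (\eqn{J_x} the trait-wise sum of
#' squared state frequencies, \eqn{J_{xy}} the cross product); the distance is
#' \eqn{D = -\log I}. With \code{unbiased = TRUE} the within-group J terms use
#' the haploid small-sample correction \eqn{(n \sum x_i^2 - 1)/(n - 1)} per
#' trait, floored at a small positive value.
#'
#' @param tm a [TraitMatrix-class] with group labels.
#' @param unbiased apply the small-sample correction.
#' @return a symmetric matrix of distances over the group labels, attribute
#'   \code{metric}. Identity <= 0 yields Inf with a warning.
#' @export
groupNeiDistance <- function(tm, unbiased = FALSE) {
  stopifnot(is(tm, "TraitMatrix"))
  g <- groupLabels(tm)
  groups <- sort(unique(g[!is.na(g)]))
  if (length(groups) < 2L) stop("need at least two groups")
  fts <- lapply(groups, function(gr) traitFrequencies(tm, gr))
  names(fts) <- groups
  keys <- traitKeys(tm)
  jwithin <- function(ft) vapply(keys, function(k) {
    f <- ft[ft$trait_key == k, ]
    j <- sum(f$p^2)
    if (unbiased) {
      n <- f$n[1L]
      if (n < 2L) stop("unbiased correction needs n >= 2 in every group")
      j <- max((n * j - 1) / (n - 1), 1e-12)
    }
    j
  }, 0)
  J <- lapply(fts, jwithin)
  d <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) if (a < b) {
    jxy <- mean(vapply(keys, function(k)
      sum(fts[[a]]$p[fts[[a]]$trait_key == k] *
          fts[[b]]$p[fts[[b]]$trait_key == k]), 0))
    I <- jxy / sqrt(mean(J[[a]]) * mean(J[[b]]))
    if (I <= 0) {
      warning("zero identity between ", groups[a], " and ", groups[b],
              "; distance set to Inf")
      d[a, b] <- d[b, a] <- Inf
    } else d[a, b] <- d[b, a] <- -log(I)
  }
  structure(d, metric = if (unbiased) "nei_unbiased" else "nei")
}
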