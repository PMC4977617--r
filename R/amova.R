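#' One-level AMOVA on the one-hot matrix
#'
#' Decomposes squared Euclidean distances among one-hot rows into among- and
#' within-group components: \eqn{SS_{total} = \sum_{i<j} d^2_{ij} / N},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d^2_{ij} / n_g}, SS among by
#' subtraction, with df = (G-1, N-G). Variance components follow the standard
#' expectation: \eqn{\sigma^2_w = MS_w}, \eqn{\sigma^2_a = (MS_a - MS_w)/n_0},
#' \eqn{n_0 = (N - \sum n_g^2 / N)/(G-1)}. PhiST = \eqn{\sigma^2_a /
#' (\sigma^2_a + \sigma^2_w)}; its significance is tested by permuting group
#' labels, with \eqn{p = (\#\{\Phi^* \ge \Phi\} + 1)/(n_{perm} + 1)}.
#' A negative among component is floored at zero for the percentage column
#' (the raw value is kept in \code{components}).
#'
#' @param bm matrix from [encodeBinary()] (missing cells are skipped pairwise).
#' @param groups group label per row; default the matrix's \code{groups}
#'   attribute.
#' @param nPermutations number of label permutations (0 = no test).
#' @param seed RNG seed for the permutations (required when permuting).
#' @return an [AmovaResult-class].
#' @export
amova <- function(bm, groups = attr(bm, "groups"), nPermutations = 10000L,
                  seed = NULL) {
  if (is.null(groups) || all(is.na(groups)))
    stop("group labels are required")
  keep <- !is.na(groups)
  bm <- bm[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  N <- nrow(bm); G <- length(unique(groups))
  if (G < 2L) stop("need at least two groups")
  if (nPermutations > 0L && is.null(seed))
    stop("a seed is required for the permutation test")
  D2 <- squaredDistances(bm)
  decomposed <- amovaSS(D2, groups)
  ng <- table(groups)
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  msA <- decomposed["among"] / (G - 1)
  msW <- decomposed["within"] / (N - G)
  s2w <- unname(msW)
  s2a <- unname((msA - msW) / n0)
  phi <- phiFromSS(decomposed, N, G, n0)
  pval <- NA_real_
  if (nPermutations >= 1L) {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      perm <- sample(groups)
      if (phiFromSS(amovaSS(D2, perm), N, G, n0) >= phi) hits <- hits + 1L
    }
    pval <- (hits + 1) / (nPermutations + 1)
  }
  s2a_rep <- max(s2a, 0)
  pct <- 100 * c(s2a_rep, s2w) / (s2a_rep + s2w)
  tab <- data.frame(
    Source = c("Among groups", "Within groups", "Total"),
    df = c(G - 1L, N - G, N - 1L),
    SS = unname(c(decomposed["among"], decomposed["within"], decomposed["total"])),
    MS = c(unname(msA), unname(msW), NA_real_),
    EstVar = c(s2a_rep, s2w, s2a_rep + s2w),
    Percent = c(pct, 100))
  new("AmovaResult", table = tab,
      components = c(sigma2_among = s2a, sigma2_within = s2w, n0 = n0),
      phiST = phi, pValue = pval,
      nPermutations = as.integer(nPermutations),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Pairwise squared Euclidean distances, skipping columns missing in either row.
squaredDistances <- function(bm) {
  x <- bm
  miss <- is.na(x)
  if (!any(miss)) {
    cp <- tcrossprod(x)
    sq <- diag(cp)
    return(outer(sq, sq, `+`) - 2 * cp)
  }
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    co <- !miss[i, ] & !miss[j, ]
    d2[i, j] <- d2[j, i] <- sum((x[i, co] - x[j, co])^2)
  }
  d2
}

# SS decomposition given squared distances and labels.
amovaSS <- function(D2, groups) {
  N <- nrow(D2)
  tot <- sum(D2[upper.tri(D2)]) / N
  within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx, drop = FALSE]
      within <- within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = tot, within = within, among = tot - within)
}

phiFromSS <- function(ss, N, G, n0) {
  msA <- ss[["among"]] / (G - 1)
  msW <- ss[["within"]] / (N - G)
  s2a <- (msA - msW) / n0
  if (s2a + msW <= 0) return(0)
  s2a / (s2a + msW)
}
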