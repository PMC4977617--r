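#' PCA of the centered one-hot matrix
#'
#' Column-centered (not scaled) principal component analysis of the binary
#' matrix. One-hot columns of a trait are linearly dependent (they sum to 1),
#' so the decomposition is rank-deficient by construction; all columns are
#' retained so that loadings do not depend on an arbitrary reference-state
#' choice. Missing cells are imputed by column means (flagged). The sign of
#' each component is fixed so that its largest-magnitude loading is positive.
#'
#' @param bm a matrix from [encodeBinary()].
#' @return an object of class \code{PcaResult}: eigenvalues, proportion and
#'   cumulative proportion of variance, scores (genotypes), loadings
#'   (variables), per-column trait keys, and \code{imputed}/\code{constant}
#'   flags.
#' @export
traitPca <- function(bm) {
  x <- bm
  storage.mode(x) <- "double"
  imputed <- anyNA(x)
  if (imputed) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 genotypes")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  constant <- sum(ev) == 0
  for (c_ in seq_along(ev)) {                # deterministic sign convention
    jmax <- which.max(abs(pc$rotation[, c_]))
    if (pc$rotation[jmax, c_] < 0) {
      pc$rotation[, c_] <- -pc$rotation[, c_]
      pc$x[, c_] <- -pc$x[, c_]
    }
  }
  prop <- if (constant) rep(0, length(ev)) else ev / sum(ev)
  structure(list(eigenvalues = ev, proportion = prop,
                 cumulative = cumsum(prop), scores = pc$x,
                 loadings = pc$rotation, traits = attr(bm, "traits"),
                 imputed = imputed, constant = constant),
            class = "PcaResult")
}

#' Rank traits by their contribution to the leading components
#'
#' Trait importance is the eigenvalue-weighted sum of squared loadings of the
#' trait's variables over the retained components:
#' \eqn{s_t = \sum_{c \le nc} \lambda_c \sum_{j \in t} L_{jc}^2}. Summed over
#' all traits and all components this equals the total variance. Ties are
#' broken by catalogue order.
#'
#' @param pca a \code{PcaResult} from [traitPca()].
#' @param nComponents number of leading components to retain (truncated with a
#'   warning if it exceeds the available rank).
#' @return data.frame (trait_key, score, rank) in decreasing importance.
#' @export
rankTraits <- function(pca, nComponents = 3L) {
  stopifnot(inherits(pca, "PcaResult"), nComponents >= 1L)
  nc <- length(pca$eigenvalues)
  if (nComponents > nc) {
    warning("nComponents exceeds the number of components; truncated to ", nc)
    nComponents <- nc
  }
  keys <- unique(pca$traits)
  sq <- pca$loadings[, seq_len(nComponents), drop = FALSE]^2
  w <- sweep(sq, 2L, pca$eigenvalues[seq_len(nComponents)], `*`)
  score <- vapply(keys, function(k) sum(w[pca$traits == k, ]), 0)
  ord <- order(-score)                        # stable: ties keep catalogue order
  data.frame(trait_key = keys[ord], score = unname(score[ord]),
             rank = seq_along(keys), row.names = NULL)
}
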