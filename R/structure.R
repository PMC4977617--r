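#' Fit the admixture model by Gibbs sampling
#'
#' Bayesian model-based clustering of genotypes from categorical descriptor
#' states. The model is the haploid admixture model: genotype i has ancestry
#' proportions \eqn{q_i} over K clusters (Dirichlet(alpha) prior), cluster k
#' has its own state frequencies \eqn{p_{k,t}} per trait (uniform Dirichlet
#' prior), and the state observed at trait t arose from a cluster drawn from
#' \eqn{q_i}. A Gibbs sampler alternates latent origin indicators, q, and p;
#' posterior means over the post-burn-in sweeps estimate Q and P. The log
#' probability of the data is estimated by the deviance approximation
#' \eqn{\bar{L} - \mathrm{var}(L)/2} over the log-likelihood draws.
#'
#' @param tm a [TraitMatrix-class].
#' @param K number of clusters (>= 1).
#' @param alpha ancestry Dirichlet concentration (fixed, not sampled).
#' @param burnIn,reps burn-in and retained MCMC sweeps. The defaults are
#'   desk-scale; raise to the classical 1e5/1e5 for production runs.
#' @param seed RNG seed.
#' @return a [StructureRun-class].
#' @export
fitStructure <- function(tm, K, alpha = 1.0, burnIn = 2000L, reps = 5000L,
                         seed) {
  stopifnot(is(tm, "TraitMatrix"), K >= 1L, alpha > 0, burnIn > 0L, reps > 0L)
  keys <- traitKeys(tm)
  X <- vapply(keys, function(k) {
    idx <- match(tm@data[[k]], traitStates(tm@catalog, k))
    idx[is.na(idx)] <- 0L
    idx
  }, integer(length(tm)))
  nStates <- vapply(keys, function(k) length(traitStates(tm@catalog, k)), 0L)
  set.seed(as.integer(seed))
  fit <- gibbsStructure(X, nStates, as.integer(K), alpha,
                        as.integer(burnIn), as.integer(reps))
  Q <- fit$Q
  rownames(Q) <- accessionIds(tm)
  colnames(Q) <- paste0("SP", seq_len(K))
  P <- fit$P
  names(P) <- keys
  for (k in keys) colnames(P[[k]]) <- traitStates(tm@catalog, k)
  ll <- as.numeric(fit$ll)
  new("StructureRun", K = as.integer(K), Q = Q, P = P,
      lnP = mean(ll) - var(ll) / 2, llTrace = ll, alpha = alpha,
      burnIn = as.integer(burnIn), reps = as.integer(reps),
      seed = as.integer(seed))
}

#' Evanno delta-K table from replicate runs
#'
#' Given replicate [fitStructure()] runs over a consecutive range of K,
#' computes per K the mean and between-run sd of lnP(D), the first and second
#' order rates of change L'(K) and |L''(K)|, and
#' \eqn{\Delta K = |L''(K)| / sd(L(K))} for interior K. Degenerate sds give a
#' missing delta-K rather than an error.
#'
#' @param runs a list of [StructureRun-class] objects (>= 2 per K, >= 3
#'   consecutive K values).
#' @return data.frame (K, nRuns, meanLnP, sdLnP, dLdK, d2LdK2, deltaK) with
#'   attribute \code{"bestK"} = argmax delta-K.
#' @export
evanno <- function(runs) {
  ks <- vapply(runs, function(r) r@K, 0L)
  lnp <- vapply(runs, function(r) r@lnP, 0)
  kk <- sort(unique(ks))
  if (length(kk) < 3L || !all(diff(kk) == 1L))
    stop("need at least 3 consecutive K values")
  if (any(table(ks) < 2L)) stop("need at least 2 runs per K")
  m <- vapply(kk, function(k) mean(lnp[ks == k]), 0)
  s <- vapply(kk, function(k) sd(lnp[ks == k]), 0)
  d1 <- c(NA, diff(m))                           # L'(K) = L(K) - L(K-1)
  d2 <- abs(c(NA, diff(m, differences = 2), NA)) # |L(K+1) - 2L(K) + L(K-1)|
  dk <- ifelse(s > 0, d2 / s, NA_real_)
  out <- data.frame(K = kk, nRuns = as.integer(table(ks)[as.character(kk)]),
                    meanLnP = m, sdLnP = s, dLdK = d1, d2LdK2 = d2,
                    deltaK = dk)
  attr(out, "bestK") <- if (all(is.na(dk))) NA_integer_ else
    kk[which.max(dk)]
  out
}

#' Assign genotypes to clusters with the 80 percent rule
#'
#' A genotype is assigned to its maximum-membership cluster when that
#' membership exceeds the threshold, and is flagged admixed otherwise.
#'
#' @param run a [StructureRun-class].
#' @param threshold membership threshold, default 0.80 (inclusive rule:
#'   status is admixed iff max membership <= threshold).
#' @return data.frame (accession_id, cluster, membership, status) with
#'   attribute \code{"shares"} = mean Q per cluster.
#' @export
assignClusters <- function(run, threshold = 0.80) {
  stopifnot(is(run, "StructureRun"), threshold > 0, threshold < 1)
  Q <- run@Q
  top <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), top)]
  out <- data.frame(accession_id = rownames(Q),
                    cluster = colnames(Q)[top],
                    membership = mx,
                    status = ifelse(mx > threshold, "assigned", "admixed"),
                    stringsAsFactors = FALSE)
  attr(out, "shares") <- colMeans(Q)
  out
}

#' Align cluster labels between two Q matrices
#'
#' Resolves label switching by exhaustive search over column permutations
#' (K <= 8), minimizing the mean absolute difference to the reference.
#'
#' @param Qref reference N x K matrix (e.g. the simulator's true Q).
#' @param Q matrix to relabel.
#' @return list(Q = permuted matrix, permutation, mae).
#' @export
alignClusters <- function(Qref, Q) {
  K <- ncol(Q)
  stopifnot(ncol(Qref) == K, nrow(Qref) == nrow(Q), K <= 8L)
  perms <- permutations(K)
  maes <- apply(perms, 1L, function(pm) mean(abs(Qref - Q[, pm, drop = FALSE])))
  best <- perms[which.min(maes), ]
  Qp <- Q[, best, drop = FALSE]
  colnames(Qp) <- colnames(Qref)
  list(Q = Qp, permutation = best, mae = min(maes))
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Per-cluster fixation index on hard assignments
#'
#' For each cluster, the variance-component PhiST of the bipartition
#' "this cluster vs all other genotypes" on hard (argmax) assignments — a
#' descriptive proxy for the model-based per-cluster fixation index.
#'
#' @param tm the [TraitMatrix-class] the run was fitted to.
#' @param assignment result of [assignClusters()].
#' @return named numeric vector of per-cluster indices (NA for clusters with
#'   fewer than 2 members).
#' @export
clusterFst <- function(tm, assignment) {
  stopifnot(is(tm, "TraitMatrix"))
  bm <- encodeBinary(tm)
  cl <- assignment$cluster[match(rownames(bm), assignment$accession_id)]
  ks <- sort(unique(cl))
  if (length(ks) < 2L) stop("need at least two assigned clusters")
  vapply(setNames(ks, ks), function(k) {
    if (sum(cl == k) < 2L || sum(cl != k) < 2L) return(NA_real_)
    res <- amova(bm, groups = ifelse(cl == k, k, "rest"), nPermutations = 0L)
    res@phiST
  }, 0)
}
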