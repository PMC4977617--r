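#' Specify a synthetic landrace panel
#'
#' A panel spec bundles the catalogue, panel size, per-trait state frequency
#' vectors and optional group (district) sizes; [simulatePanel()] realizes it.
#'
#' @param catalog a [TraitCatalog-class].
#' @param n number of genotypes (ignored when \code{groupSizes} is given).
#' @param frequencies named list (by trait key) of frequency vectors in
#'   catalogue state order; traits not listed default to uniform.
#' @param groupSizes optional named integer vector of genotypes per group;
#'   their sum overrides \code{n}.
#' @param groupDivergence 0 for a homogeneous panel; otherwise each group's
#'   trait frequencies are drawn from a Dirichlet centred on the base vector
#'   with concentration \code{base/groupDivergence}, so the expected
#'   among-group fixation is roughly \code{groupDivergence/(1+groupDivergence)}.
#' @return an object of class \code{PanelSpec} (a validated list).
#' @export
panelSpec <- function(catalog, n = 126L, frequencies = list(),
                      groupSizes = NULL, groupDivergence = 0) {
  stopifnot(is(catalog, "TraitCatalog"), groupDivergence >= 0)
  if (!is.null(groupSizes)) {
    stopifnot(!is.null(names(groupSizes)), all(groupSizes >= 1L))
    n <- sum(groupSizes)
  }
  stopifnot(n >= 1L)
  freqs <- lapply(traitKeys(catalog), function(k) {
    states <- traitStates(catalog, k)
    p <- frequencies[[k]]
    if (is.null(p)) p <- rep(1 / length(states), length(states))
    if (length(p) != length(states))
      stop("frequency vector for trait ", k, " has length ", length(p),
           ", catalogue has ", length(states), " states")
    if (abs(sum(p) - 1) > 1e-9) stop("frequencies for trait ", k, " do not sum to 1")
    setNames(p, states)
  })
  structure(list(catalog = catalog, n = as.integer(n),
                 frequencies = setNames(freqs, traitKeys(catalog)),
                 groupSizes = groupSizes, groupDivergence = groupDivergence),
            class = "PanelSpec")
}

#' The Odisha-like panel specification
#'
#' Encodes every printed state frequency of the 126-genotype Odisha aromatic
#' short-grain collection (e.g. lemma-palea colour straw 50\%, purple furrow
#' 14\%, brown 11\%, purple 10\%, brown furrow 10\%, black 2\%, red 2\%, brown
#' spot 1\%; auricles present 99\%; awns absent 91\%; ...), spreads unprinted
#' residual mass uniformly over the remaining catalogue states, fixes the six
#' invariant traits, and uses the 19 reported district sizes (Koraput 17,
#' Cuttack 15, Ganjam 12, ..., Anugul 2).
#'
#' @param catalog the catalogue; defaults to [odishaCatalog()].
#' @param groupDivergence see [panelSpec()]; 0 (homogeneous districts) by default.
#' @return a \code{PanelSpec} for N = 126.
#' @export
odishaPanelSpec <- function(catalog = odishaCatalog(), groupDivergence = 0) {
  mode_freq <- function(k, label, p) {
    states <- traitStates(catalog, k)
    rest <- setdiff(states, label)
    v <- setNames(rep((1 - sum(p)) / length(rest), length(states)), states)
    v[label] <- p
    v
  }
  freqs <- list(
    LPC = mode_freq("LPC",
                    c("Straw", "Purple Furrow", "Brown", "Purple",
                      "Brown Furrow", "Black", "Red", "Brown Spot"),
                    c(.50, .14, .11, .10, .10, .02, .02, .01)),
    LAR = mode_freq("LAR", "Present", .99),
    CA  = mode_freq("CA", "Semi erect", .99),
    LSL = mode_freq("LSL", "Split", .95),
    PA  = mode_freq("PA", "Absent", .91),
    PMA = mode_freq("PMA", "Dropping", .91),
    PAB = mode_freq("PAB", "Semierect", .86),
    PE  = mode_freq("PE", "Well exserted", .76),
    CSTG = mode_freq("CSTG", "White", .74),
    INC = mode_freq("INC", "Light gold", .71),
    PCA = mode_freq("PCA", "Yellowish white", .64),
    PSB = mode_freq("PSB", c("Weak", "Strong"), c(.63, .37)),
    ST  = mode_freq("ST", "Medium", .55),
    BLS = mode_freq("BLS", "Green", .51),
    SCL = mode_freq("SCL", "Purple", .45),
    FLA = mode_freq("FLA", "Erect", .44),
    GT  = mode_freq("GT", c("Short bold", "Medium bold"), c(.47, .51)),
    LI = mode_freq("LI", "Medium", 1), LA = mode_freq("LA", "Absent", 1),
    LPB = mode_freq("LPB", "Medium", 1), LL = mode_freq("LL", "Present", 1),
    CL = mode_freq("CL", "Green", 1), CC = mode_freq("CC", "Pale green", 1)
  )
  groups <- c(Anugul = 2L, Balasore = 4L, Bolangir = 10L, Cuttack = 15L,
              Deogarh = 4L, Dhenkanal = 4L, Ganjam = 12L, Jajpur = 2L,
              Kalahandi = 10L, Kendrapara = 2L, Keonjhar = 5L, Koraput = 17L,
              Malkangiri = 8L, Mayurbhanj = 3L, Nayagarh = 3L, Phulbani = 2L,
              Puri = 13L, Sambalpur = 4L, Sundargarh = 6L)
  panelSpec(catalog, frequencies = freqs, groupSizes = groups,
            groupDivergence = groupDivergence)
}

# Largest-remainder apportionment of n among probabilities p (deterministic;
# ties broken by position).
largestRemainder <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

# One trait column for n genotypes from frequency vector p (named by state).
sampleTrait <- function(p, n, exactCounts) {
  states <- names(p)
  if (exactCounts) {
    counts <- largestRemainder(p, n)
    sample(rep(states, counts))
  } else {
    states[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
}

#' Simulate a landrace panel
#'
#' Draws each genotype's state for each trait independently from the trait's
#' frequency vector. With \code{exactCounts = TRUE} the per-trait state counts
#' are fixed by largest-remainder rounding of p*N (only the within-trait
#' assignment to genotypes is random), which makes all frequency-based
#' statistics deterministic for a given spec.
#'
#' @param spec a [panelSpec()].
#' @param seed RNG seed (mandatory: simulations are always reproducible).
#' @param exactCounts realize frequencies as exact counts (default FALSE:
#'   i.i.d. sampling).
#' @return a [TraitMatrix-class] with accession ids \code{SIM001, ...} and the
#'   spec's group labels (if any).
#' @export
simulatePanel <- function(spec, seed, exactCounts = FALSE) {
  stopifnot(inherits(spec, "PanelSpec"))
  set.seed(as.integer(seed))
  n <- spec$n
  groups <- if (is.null(spec$groupSizes)) rep(NA_character_, n) else
    rep(names(spec$groupSizes), spec$groupSizes)
  d <- data.frame(accession_id = sprintf("SIM%03d", seq_len(n)),
                  name = sprintf("SIM%03d", seq_len(n)),
                  group = groups, stringsAsFactors = FALSE)
  diverged <- spec$groupDivergence > 0 && !is.null(spec$groupSizes)
  for (k in traitKeys(spec$catalog)) {
    p <- spec$frequencies[[k]]
    if (!diverged) {
      d[[k]] <- sampleTrait(p, n, exactCounts)
    } else {
      col <- character(n)
      for (g in names(spec$groupSizes)) {
        rows <- which(groups == g)
        pg <- rdirichlet1(p / spec$groupDivergence)
        names(pg) <- names(p)
        col[rows] <- sampleTrait(pg, length(rows), exactCounts)
      }
      d[[k]] <- col
    }
  }
  traitMatrix(d, spec$catalog)
}

# One Dirichlet draw with concentration vector a (zeros stay zero).
rdirichlet1 <- function(a) {
  g <- ifelse(a > 0, rgamma(length(a), shape = a), 0)
  if (sum(g) == 0) g[which.max(a)] <- 1
  g / sum(g)
}

#' Simulate an admixed panel with known ancestry
#'
#' Each of K subpopulations gets its own per-trait state frequencies, drawn
#' from a Dirichlet centred on the spec's base vector with concentration
#' \code{base/divergence} (larger divergence = more differentiated clusters;
#' expected fixation roughly \code{divergence/(1+divergence)}). Each genotype
#' draws an ancestry vector q from Dirichlet(alpha), and each trait state from
#' the q-mixture of subpopulation frequencies. The true Q and P are returned
#' for parameter-recovery testing.
#'
#' @param spec a [panelSpec()] supplying the base frequencies and N.
#' @param K number of subpopulations.
#' @param alpha symmetric Dirichlet concentration of individual ancestry
#'   (small alpha = near-pure individuals).
#' @param divergence subpopulation divergence (see above).
#' @param seed RNG seed.
#' @return a list with \code{tm} ([TraitMatrix-class]), \code{Q} (N x K true
#'   ancestries) and \code{P} (per-trait K x states frequency matrices).
#' @export
simulateAdmixed <- function(spec, K, alpha = 0.2, divergence = 1, seed) {
  stopifnot(inherits(spec, "PanelSpec"), K >= 1L, alpha > 0, divergence > 0)
  if (K > nVariables(spec$catalog))
    warning("K exceeds the number of catalogue variables")
  set.seed(as.integer(seed))
  n <- spec$n
  keys <- traitKeys(spec$catalog)
  P <- lapply(spec$frequencies, function(p) {
    m <- matrix(0, K, length(p), dimnames = list(NULL, names(p)))
    for (k in seq_len(K)) m[k, ] <- rdirichlet1(p / divergence)
    m
  })
  Q <- matrix(0, n, K)
  for (i in seq_len(n)) Q[i, ] <- rdirichlet1(rep(alpha, K))
  groups <- if (is.null(spec$groupSizes)) rep(NA_character_, n) else
    rep(names(spec$groupSizes), spec$groupSizes)
  d <- data.frame(accession_id = sprintf("SIM%03d", seq_len(n)),
                  name = sprintf("SIM%03d", seq_len(n)),
                  group = groups, stringsAsFactors = FALSE)
  for (k in keys) {
    mix <- Q %*% P[[k]]                      # n x states mixture weights
    d[[k]] <- vapply(seq_len(n), function(i) {
      s <- colnames(mix)[sample.int(ncol(mix), 1L, prob = mix[i, ])]
      s
    }, character(1L))
  }
  list(tm = traitMatrix(d, spec$catalog), Q = Q, P = P)
}
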