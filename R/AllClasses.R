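#' @import methods
#' @importFrom stats cor prcomp rgamma runif sd setNames var
#' @importFrom utils combn read.delim write.table
#' @useDynLib phenoprint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TraitCatalog: the descriptor/state universe
#'
#' An ordered catalogue of qualitative descriptors (traits) and their allowed
#' states ("variables"). Each variable carries a global integer code; when the
#' catalogue is complete the codes form a contiguous 1..V sequence that fixes
#' the phenoprint column order.
#'
#' @slot variables a data.frame with columns \code{trait_key}, \code{trait_name},
#'   \code{variable_code} (integer) and \code{variable_label}, one row per
#'   variable, in catalogue order.
#' @slot version free-text version tag.
#' @seealso [readTraitCatalog()], [catalogSummary()]
#' @export
setClass("TraitCatalog",
  representation(variables = "data.frame", version = "character"),
  prototype(version = "1")
)

setValidity("TraitCatalog", function(object) {
  v <- object@variables
  need <- c("trait_key", "trait_name", "variable_code", "variable_label")
  if (!all(need %in% names(v)))
    return(paste("variables must have columns", paste(need, collapse = ", ")))
  if (nrow(v) < 1L) return("catalogue must define at least one variable")
  if (anyDuplicated(v$variable_code)) {
    dup <- v$variable_code[duplicated(v$variable_code)]
    return(paste("duplicate variable code(s):", paste(unique(dup), collapse = ", ")))
  }
  if (any(v$variable_code < 1L)) return("variable codes must be positive integers")
  lab_dup <- vapply(split(v$variable_label, v$trait_key), anyDuplicated, 0L)
  if (any(lab_dup > 0L))
    return(paste("duplicate variable label within trait(s):",
                 paste(names(lab_dup)[lab_dup > 0L], collapse = ", ")))
  TRUE
})

#' TraitMatrix: genotypes scored for categorical descriptors
#'
#' N genotypes by T traits of categorical states, validated against a
#' [TraitCatalog-class], with optional group (e.g. collection district) labels.
#' Missing states are \code{NA} and are masked from all statistics through
#' per-trait denominators.
#'
#' @slot catalog the [TraitCatalog-class] the states are validated against.
#' @slot data data.frame with columns \code{accession_id} (unique), \code{name},
#'   \code{group}, then one column per trait key holding state labels (or NA).
#' @seealso [readTraitMatrix()], [encodeBinary()], [simulatePanel()]
#' @export
setClass("TraitMatrix",
  representation(catalog = "TraitCatalog", data = "data.frame")
)

setValidity("TraitMatrix", function(object) {
  d <- object@data
  meta <- c("accession_id", "name", "group")
  if (!all(meta %in% names(d)))
    return(paste("data must have columns", paste(meta, collapse = ", ")))
  if (nrow(d) < 1L) return("at least one genotype is required")
  if (anyDuplicated(d$accession_id))
    return(paste("duplicate accession_id:",
                 paste(unique(d$accession_id[duplicated(d$accession_id)]), collapse = ", ")))
  keys <- traitKeys(object@catalog)
  tcols <- setdiff(names(d), meta)
  if (!setequal(tcols, keys))
    return("trait columns must match the catalogue trait keys exactly")
  for (k in keys) {
    states <- d[[k]]
    legal <- object@catalog@variables$variable_label[object@catalog@variables$trait_key == k]
    bad <- !is.na(states) & !(states %in% legal)
    if (any(bad))
      return(sprintf("illegal state '%s' for trait %s (row %d)",
                     states[which(bad)[1L]], k, which(bad)[1L]))
  }
  TRUE
})

#' AmovaResult: one-level analysis of molecular variance
#'
#' @slot table data.frame with the Source/df/SS/MS decomposition.
#' @slot components named numeric: sigma2_among (raw), sigma2_within, n0.
#' @slot phiST among-group fixation index.
#' @slot pValue permutation p-value (NA if no permutations were run).
#' @slot nPermutations number of label permutations.
#' @slot seed seed used for the permutations (NA if none supplied).
#' @export
setClass("AmovaResult",
  representation(table = "data.frame", components = "numeric", phiST = "numeric",
                 pValue = "numeric", nPermutations = "integer", seed = "integer")
)

#' StructureRun: one admixture-model Gibbs run
#'
#' @slot K number of clusters.
#' @slot Q N x K posterior-mean ancestry proportions (rows sum to 1).
#' @slot P per-trait K x (number of states) posterior-mean cluster state
#'   frequencies, a named list over trait keys.
#' @slot lnP estimated log probability of the data (deviance approximation).
#' @slot llTrace complete-data log-likelihood draws (post burn-in).
#' @slot alpha Dirichlet concentration of the ancestry prior.
#' @slot burnIn,reps MCMC sweep counts.
#' @slot seed RNG seed of the run.
#' @export
setClass("StructureRun",
  representation(K = "integer", Q = "matrix", P = "list", lnP = "numeric",
                 llTrace = "numeric", alpha = "numeric", burnIn = "integer",
                 reps = "integer", seed = "integer")
)

setValidity("StructureRun", function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (ncol(object@Q) != object@K) return("Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9)) return("Q rows must sum to 1")
  TRUE
})
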