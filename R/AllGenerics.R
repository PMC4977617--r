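#' Number of traits in a catalogue or matrix
#' @param x a TraitCatalog or TraitMatrix
#' @return integer count
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))

#' Total number of variables (descriptor states)
#' @param x a TraitCatalog or TraitMatrix
#' @return integer V
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' Trait keys, in catalogue order
#' @param x a TraitCatalog or TraitMatrix
#' @return character vector
#' @export
setGeneric("traitKeys", function(x) standardGeneric("traitKeys"))

#' Accession identifiers of a panel
#' @param x a TraitMatrix
#' @return character vector, in record order
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' Group (district) labels of a panel
#' @param x a TraitMatrix
#' @return character vector parallel to [accessionIds()], NA where unset
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

setMethod("nTraits", "TraitCatalog", function(x) length(unique(x@variables$trait_key)))
setMethod("nVariables", "TraitCatalog", function(x) nrow(x@variables))
setMethod("traitKeys", "TraitCatalog", function(x) unique(x@variables$trait_key))
setMethod("nTraits", "TraitMatrix", function(x) nTraits(x@catalog))
setMethod("nVariables", "TraitMatrix", function(x) nVariables(x@catalog))
setMethod("traitKeys", "TraitMatrix", function(x) traitKeys(x@catalog))
setMethod("accessionIds", "TraitMatrix", function(x) x@data$accession_id)
setMethod("groupLabels", "TraitMatrix", function(x) x@data$group)

#' @describeIn nTraits number of genotypes in a panel
#' @export
setMethod("length", "TraitMatrix", function(x) nrow(x@data))

setMethod("show", "TraitCatalog", function(object) {
  cs <- catalogSummary(object)
  cat(sprintf("TraitCatalog: %d traits, %d variables (mean %.2f per trait)\n",
              nTraits(object), nVariables(object), cs$mean_variables))
  cat(sprintf("  most states: %s (%d); version: %s\n",
              cs$max_trait, cs$max_count, object@version))
})

setMethod("show", "TraitMatrix", function(object) {
  g <- groupLabels(object)
  cat(sprintf("TraitMatrix: %d genotypes x %d traits (%d variables)\n",
              length(object), nTraits(object), nVariables(object)))
  if (!all(is.na(g)))
    cat(sprintf("  groups: %d (%s...)\n", length(unique(g[!is.na(g)])),
                paste(utils::head(sort(unique(g[!is.na(g)])), 3L), collapse = ", ")))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (one level: among / within groups)\n")
  print(object@table, row.names = FALSE)
  cat(sprintf("PhiST = %.4f", object@phiST))
  if (!is.na(object@pValue))
    cat(sprintf(", permutation P = %.4g (%d randomizations)", object@pValue,
                object@nPermutations))
  cat("\n")
})

setMethod("show", "StructureRun", function(object) {
  cat(sprintf("StructureRun: K = %d, N = %d, lnP(D) ~ %.2f\n",
              object@K, nrow(object@Q), object@lnP))
  cat(sprintf("  alpha = %g, burn-in %d + %d sweeps, seed %d\n",
              object@alpha, object@burnIn, object@reps, object@seed))
})
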