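#' Read a trait catalogue
#'
#' Parses a tab-separated catalogue file (UTF-8; one record per variable with
#' columns \code{trait_key}, \code{trait_name}, \code{variable_code},
#' \code{variable_label}; \code{#} lines are comments) and validates it:
#' variable codes must be unique positive integers and variable labels unique
#' within each trait. Non-contiguous codes are legal but draw a warning, since
#' a complete catalogue numbers its variables 1..V.
#'
#' @param path path to the catalogue file.
#' @param version version tag to attach (defaults to the file name).
#' @return a [TraitCatalog-class].
#' @examples
#' cat24 <- odishaCatalog()
#' nTraits(cat24)    # 24
#' nVariables(cat24) # 70
#' @export
readTraitCatalog <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  v <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("trait_key", "trait_name", "variable_code", "variable_label")
  if (!all(need %in% names(v)))
    stop("catalogue header must contain: ", paste(need, collapse = ", "))
  v$variable_code <- as.integer(v$variable_code)
  if (anyNA(v$variable_code)) stop("non-integer variable_code in catalogue")
  obj <- new("TraitCatalog", variables = v[need], version = version)
  validObject(obj)
  codes <- sort(v$variable_code)
  if (!identical(codes, seq_len(nrow(v))))
    warning("variable codes are not a contiguous 1..V sequence")
  obj
}

#' The bundled Odisha aromatic short-grain rice descriptor catalogue
#'
#' The 24-trait, 70-variable catalogue used to characterize the Odisha
#' aromatic short-grain landrace collection (e.g. lemma-palea colour with 8
#' states, codes 59-66; tip colour of lemma with 6).
#'
#' @return a [TraitCatalog-class] with 24 traits and 70 variables.
#' @export
odishaCatalog <- function() {
  readTraitCatalog(system.file("extdata", "odisha_asg_catalog.tsv",
                               package = "phenoprint", mustWork = TRUE),
                   version = "odisha_asg_catalog")
}

#' Write a trait catalogue
#'
#' Serializes a catalogue in the same tab-separated format [readTraitCatalog()]
#' reads, preserving order, so that a read/write round trip is lossless.
#'
#' @param catalog a [TraitCatalog-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTraitCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "TraitCatalog"))
  write.table(catalog@variables, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a trait catalogue
#'
#' @param catalog a [TraitCatalog-class].
#' @return a list with \code{counts} (named integer vector of variables per
#'   trait, catalogue order), \code{V} (total variables), \code{mean_variables}
#'   (rounded to 2 decimals), and the traits carrying the most / fewest states.
#' @examples
#' s <- catalogSummary(odishaCatalog())
#' s$counts[["LPC"]]  # 8
#' s$mean_variables   # 2.92
#' @export
catalogSummary <- function(catalog) {
  stopifnot(is(catalog, "TraitCatalog"))
  keys <- traitKeys(catalog)
  counts <- vapply(keys, function(k)
    sum(catalog@variables$trait_key == k), 0L)
  list(counts = counts,
       V = nVariables(catalog),
       mean_variables = round(nVariables(catalog) / length(keys), 2L),
       max_trait = names(which.max(counts)), max_count = max(counts),
       min_trait = names(which.min(counts)), min_count = min(counts))
}

# Legal state labels of one trait, in catalogue (code) order.
traitStates <- function(catalog, key) {
  v <- catalog@variables
  v$variable_label[v$trait_key == key]
}
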