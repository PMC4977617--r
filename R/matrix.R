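#' Construct a TraitMatrix from a data.frame
#'
#' @param data data.frame with columns \code{accession_id}, \code{name},
#'   \code{group}, then one column per catalogue trait key holding state labels
#'   (empty string or NA = missing).
#' @param catalog a [TraitCatalog-class] the states are validated against.
#' @return a validated [TraitMatrix-class].
#' @export
traitMatrix <- function(data, catalog) {
  stopifnot(is(catalog, "TraitCatalog"), is.data.frame(data))
  for (m in c("name", "group"))
    if (is.null(data[[m]])) data[[m]] <- NA_character_
  keys <- traitKeys(catalog)
  data <- data[c("accession_id", "name", "group", keys)]
  for (k in keys) {
    s <- as.character(data[[k]])
    s[!is.na(s) & s == ""] <- NA_character_
    data[[k]] <- s
  }
  data$group <- as.character(data$group)
  data$group[!is.na(data$group) & data$group == ""] <- NA_character_
  rownames(data) <- NULL
  obj <- new("TraitMatrix", catalog = catalog, data = data)
  validObject(obj)
  obj
}

#' Read a genotype x trait state matrix
#'
#' Reads a delimited text panel (default TSV; \code{#} lines are comments) with
#' leading columns \code{accession_id}, \code{name}, \code{group} and one
#' column per trait key. Every state is validated against the catalogue; an
#' unknown state is an error naming the trait and row. Empty cells are missing
#' and stay masked downstream.
#'
#' @param path input file.
#' @param catalog a [TraitCatalog-class].
#' @param sep field separator, tab by default.
#' @return a [TraitMatrix-class].
#' @export
readTraitMatrix <- function(path, catalog, sep = "\t") {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  d <- read.delim(path, sep = sep, comment.char = "#",
                  stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  if (!"accession_id" %in% names(d)) stop("missing accession_id column")
  unknown <- setdiff(names(d), c("accession_id", "name", "group", traitKeys(catalog)))
  if (length(unknown))
    stop("unknown trait column(s): ", paste(unknown, collapse = ", "))
  missing_tr <- setdiff(traitKeys(catalog), names(d))
  if (length(missing_tr))
    stop("matrix lacks trait column(s): ", paste(missing_tr, collapse = ", "))
  traitMatrix(d, catalog)
}

#' Write a genotype x trait state matrix
#'
#' @param tm a [TraitMatrix-class].
#' @param path output file.
#' @param sep field separator.
#' @param header optional character vector of provenance lines written as
#'   \code{#} comments before the table.
#' @return invisibly, \code{path}.
#' @export
writeTraitMatrix <- function(tm, path, sep = "\t", header = NULL) {
  stopifnot(is(tm, "TraitMatrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(tm@data, con, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' One-hot (phenoprint) encoding of a trait matrix
#'
#' Expands each trait into its catalogue variables: cell (i, j) is 1 if
#' genotype i carries the state with global code j, 0 if it carries another
#' state of that trait, and NA if the trait is unscored for that genotype.
#' Columns are in catalogue code order, which fixes the phenoprint bar order.
#'
#' @param tm a [TraitMatrix-class].
#' @return an integer matrix (genotypes x V) with accession ids as row names
#'   and \code{trait_key.variable_label} column names; attributes
#'   \code{codes}, \code{traits} (per-column trait key), \code{labels},
#'   \code{groups} and \code{catalog} carry the bookkeeping.
#' @export
encodeBinary <- function(tm) {
  stopifnot(is(tm, "TraitMatrix"))
  v <- tm@catalog@variables[order(tm@catalog@variables$variable_code), ]
  n <- length(tm)
  bm <- matrix(NA_integer_, n, nrow(v),
               dimnames = list(accessionIds(tm),
                               paste(v$trait_key, v$variable_label, sep = ".")))
  for (k in traitKeys(tm)) {
    cols <- which(v$trait_key == k)
    states <- tm@data[[k]]
    scored <- !is.na(states)
    bm[scored, cols] <- 0L
    hit <- match(states[scored], v$variable_label[cols])
    bm[cbind(which(scored), cols[hit])] <- 1L
  }
  structure(bm, codes = v$variable_code, traits = v$trait_key,
            labels = v$variable_label, groups = groupLabels(tm),
            catalog = tm@catalog)
}

#' Decode a one-hot matrix back to a TraitMatrix
#'
#' Inverse of [encodeBinary()]; exact round trip including missing cells.
#'
#' @param bm a matrix produced by [encodeBinary()].
#' @param name,group optional annotation vectors (defaults taken from \code{bm}).
#' @return a [TraitMatrix-class].
#' @export
decodeBinary <- function(bm, name = NULL, group = attr(bm, "groups")) {
  catalog <- attr(bm, "catalog")
  stopifnot(is(catalog, "TraitCatalog"))
  traits <- attr(bm, "traits"); labels <- attr(bm, "labels")
  d <- data.frame(accession_id = rownames(bm),
                  name = if (is.null(name)) NA_character_ else name,
                  group = if (is.null(group)) NA_character_ else group,
                  stringsAsFactors = FALSE)
  for (k in traitKeys(catalog)) {
    cols <- which(traits == k)
    d[[k]] <- apply(bm[, cols, drop = FALSE], 1L, function(row) {
      if (anyNA(row)) NA_character_ else labels[cols][row == 1L]
    })
  }
  traitMatrix(d, catalog)
}

#' Per-trait state frequencies
#'
#' Sample proportions of every catalogue state per trait, over the whole panel
#' or a subset. States never observed keep p = 0 and stay listed; denominators
#' are per trait (genotypes scored for that trait).
#'
#' @param tm a [TraitMatrix-class].
#' @param subset optional accession ids, logical mask, or a group label
#'   (matched against [groupLabels()]); default all genotypes.
#' @return a data.frame with columns \code{trait_key}, \code{variable_code},
#'   \code{variable_label}, \code{count}, \code{n} (trait denominator), \code{p}.
#' @examples
#' tm <- simulatePanel(odishaPanelSpec(), seed = 1)
#' f <- traitFrequencies(tm)
#' subset(f, trait_key == "LPC" & variable_label == "Straw")$p  # ~0.50
#' @export
traitFrequencies <- function(tm, subset = NULL) {
  stopifnot(is(tm, "TraitMatrix"))
  d <- tm@data[selectRows(tm, subset), , drop = FALSE]
  if (nrow(d) == 0L) stop("empty genotype subset")
  v <- tm@catalog@variables[order(tm@catalog@variables$variable_code), ]
  out <- v
  names(out) <- c("trait_key", "trait_name", "variable_code", "variable_label")
  out$trait_name <- NULL
  out$count <- 0L; out$n <- 0L
  for (k in unique(v$trait_key)) {
    rows <- which(out$trait_key == k)
    states <- d[[k]][!is.na(d[[k]])]
    out$n[rows] <- length(states)
    out$count[rows] <- vapply(out$variable_label[rows],
                              function(s) sum(states == s), 0L)
  }
  out$p <- ifelse(out$n > 0L, out$count / out$n, NA_real_)
  rownames(out) <- NULL
  out
}

# Resolve a subset argument to row indices of tm@data.
selectRows <- function(tm, subset) {
  if (is.null(subset)) return(seq_len(length(tm)))
  if (is.logical(subset)) {
    stopifnot(length(subset) == length(tm))
    return(which(subset))
  }
  ids <- accessionIds(tm)
  if (all(subset %in% ids)) return(match(subset, ids))
  g <- groupLabels(tm)
  if (length(subset) >= 1L && all(subset %in% g)) return(which(g %in% subset))
  stop("subset matches neither accession ids nor group labels: ",
       paste(utils::head(setdiff(subset, c(ids, g)), 3L), collapse = ", "))
}

#' Traits on which two genotypes differ
#'
#' @param tm a [TraitMatrix-class].
#' @param idA,idB accession ids.
#' @return a list: \code{differing} (trait keys with unequal scored states),
#'   \code{count}, and \code{unscored} (traits missing in either genotype,
#'   excluded from the comparison).
#' @export
pairwiseTraitDiff <- function(tm, idA, idB) {
  stopifnot(is(tm, "TraitMatrix"))
  ids <- accessionIds(tm)
  for (id in c(idA, idB))
    if (!id %in% ids) stop("unknown accession id: ", id)
  a <- tm@data[match(idA, ids), traitKeys(tm)]
  b <- tm@data[match(idB, ids), traitKeys(tm)]
  unscored <- traitKeys(tm)[is.na(unlist(a)) | is.na(unlist(b))]
  comp <- setdiff(traitKeys(tm), unscored)
  diff <- comp[unlist(a[comp]) != unlist(b[comp])]
  list(differing = diff, count = length(diff), unscored = unscored)
}
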