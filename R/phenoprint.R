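#' Render phenoprint barcodes as SVG
#'
#' One row per genotype and one bar per catalogue variable, in global code
#' order: black for presence, grey for absence, white for a missing trait.
#' The geometry and number formatting are fixed, so identical inputs produce
#' byte-identical SVG files.
#'
#' @param bm a matrix from [encodeBinary()].
#' @param ids accessions to render (default: all rows, in panel order).
#' @param path output file (".svg").
#' @param barWidth,barHeight bar geometry in user units.
#' @param labelWidth left margin reserved for accession labels (0 = none).
#' @return invisibly, \code{path}.
#' @export
renderPhenoprint <- function(bm, ids = rownames(bm), path,
                             barWidth = 6, barHeight = 16, labelWidth = 90) {
  rows <- match(ids, rownames(bm))
  if (anyNA(rows)) stop("unknown accession id: ",
                        paste(ids[is.na(rows)], collapse = ", "))
  V <- ncol(bm)
  w <- labelWidth + V * barWidth
  h <- length(rows) * (barHeight + 2)
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h))
  for (r in seq_along(rows)) {
    y <- (r - 1L) * (barHeight + 2)
    if (labelWidth > 0)
      out <- c(out, sprintf(
        '<text x="0" y="%d" font-family="monospace" font-size="10">%s</text>',
        y + barHeight - 4, xmlEscape(ids[r])))
    cells <- bm[rows[r], ]
    fill <- ifelse(is.na(cells), "#ffffff",
                   ifelse(cells == 1L, "#000000", "#bfbfbf"))
    out <- c(out, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
      labelWidth + (seq_len(V) - 1L) * barWidth, y, barWidth, barHeight, fill))
  }
  out <- c(out, "</svg>")
  con <- file(path, "wb")                      # fixed newline on all platforms
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Groups of genotypes with identical phenoprints
#'
#' @param bm a matrix from [encodeBinary()].
#' @return a list of character vectors (accession ids), one per group of two
#'   or more genotypes with identical bit vectors (including the missingness
#'   pattern); empty list when all genotypes are distinct.
#' @export
findDuplicates <- function(bm) {
  key <- apply(bm, 1L, paste, collapse = ",")
  grp <- split(rownames(bm), key)
  unname(grp[lengths(grp) > 1L])
}

#' Greedy core subset covering the observed variables
#'
#' Greedy set cover over the variables observed in the panel: repeatedly add
#' the genotype contributing the most not-yet-covered variables (ties broken
#' by panel order) until the covered fraction reaches the threshold. Greedy
#' set cover carries the classical (ln V + 1) approximation guarantee. The
#' subset's mean Nei gene diversity is reported alongside.
#'
#' @param bm a matrix from [encodeBinary()].
#' @param threshold target fraction of observed variables to cover, in [0, 1];
#'   default 0.98.
#' @return list(ids, covered (variable codes), coverage, threshold, meanHe).
#' @export
coreSubset <- function(bm, threshold = 0.98) {
  stopifnot(threshold >= 0, threshold <= 1)
  x <- bm
  x[is.na(x)] <- 0L
  universe <- which(colSums(x) > 0L)
  chosen <- integer(0)
  covered <- logical(ncol(bm))
  while (length(universe) > 0 &&
         sum(covered[universe]) / length(universe) < threshold) {
    gain <- x[, universe, drop = FALSE] %*% (!covered[universe])
    gain[chosen] <- -1
    best <- which.max(gain)                    # ties: first genotype wins
    if (gain[best] <= 0) break
    chosen <- c(chosen, best)
    covered <- covered | (x[best, ] == 1L)
  }
  ids <- rownames(bm)[chosen]
  meanHe <- if (length(chosen)) {
    traits <- attr(bm, "traits")
    p <- colMeans(bm[chosen, , drop = FALSE], na.rm = TRUE)
    mean(vapply(unique(traits), function(k) {
      pk <- p[traits == k]
      pk <- pk[!is.nan(pk)]
      if (!length(pk) || sum(pk) == 0) 0 else 1 - sum((pk / sum(pk))^2)
    }, 0))
  } else NA_real_
  list(ids = ids,
       covered = attr(bm, "codes")[covered],
       coverage = if (length(universe)) sum(covered[universe]) / length(universe) else 1,
       threshold = threshold, meanHe = meanHe)
}
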