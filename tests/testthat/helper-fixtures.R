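# In-code fixtures shared across test files.

# A small catalogue: 3 traits, 6 variables, codes 1..6.
tinyCatalog <- function() {
  d <- data.frame(
    trait_key = c("COL", "COL", "COL", "SHP", "SHP", "AWN"),
    trait_name = c(rep("Colour", 3), rep("Shape", 2), "Awn"),
    variable_code = 1:6,
    variable_label = c("Red", "Green", "Blue", "Round", "Oval", "Present"),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  readTraitCatalog(f, version = "tiny")
}

# A panel over tinyCatalog with the given state rows.
tinyPanel <- function(states, groups = NA_character_) {
  d <- data.frame(accession_id = sprintf("G%02d", seq_len(nrow(states))),
                  name = "toy", group = groups, stringsAsFactors = FALSE)
  cbind(d, states)
}

tinyStates <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(COL = r[1], SHP = r[2], AWN = r[3], stringsAsFactors = FALSE)))
}

# Random additive distance matrix from a random binary tree with positive
# branch lengths; returns list(d, tree).
randomAdditiveMatrix <- function(ntaxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(ntaxa, rooted = FALSE,
                     br = function(n) runif(n, 0.1, 2))
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tree)
}

# Round-half-up to k decimals, the convention of the printed tables.
halfUp <- function(x, k = 3) floor(x * 10^k + 0.5) / 10^k

# Legal state labels of one trait, in catalogue order (test-side mirror).
traitStates_test <- function(catalog, key) {
  v <- catalog@variables
  v$variable_label[v$trait_key == key]
}
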