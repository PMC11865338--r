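#' Supported taxonomic ranks
#'
#' The six ranks handled by the pipeline, ordered from lowest (most
#' specific) to highest: species, genus, family, order, class, phylum.
#' Evidence reported at one rank is propagated to every strictly higher
#' rank reachable through its lineage, never downward.
#'
#' @return Character vector of the six rank names, lowest first.
#' @export
#' @examples
#' taxonomic_ranks()
taxonomic_ranks <- function() {
  c("species", "genus", "family", "order", "class", "phylum")
}

# ranks strictly above `rank`, in ascending order
ranks_above <- function(rank) {
  r <- taxonomic_ranks()
  i <- match(rank, r)
  if (is.na(i)) stop("unknown rank: ", rank)
  if (i == length(r)) character(0) else r[(i + 1L):length(r)]
}

# canonical matching key: trim, collapse internal whitespace, lowercase
norm_key <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# display form: trimmed, internal whitespace collapsed, case preserved
norm_display <- function(x) {
  gsub("\\s+", " ", trimws(as.character(x)))
}
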