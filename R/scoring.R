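#' Partition evidence by body site
#'
#' Splits disease evidence by the anatomical site the microbiota
#' samples came from, drops rows without a site label (logged), and
#' removes sites documented for only a single disease. Within each
#' retained partition the evidence is propagated up the taxonomy so
#' that disturbance strengths can be quantified site-locally: the
#' entity count \code{N} of the IDF term is the number of diseases at
#' the site, and \code{n} counts diseases at the site associated with
#' the taxon.
#'
#' @param evidence A \code{bhwa_evidence} data frame with
#'   \code{body_site} labels.
#' @param taxonomy A \code{bhwa_taxonomy} table or \code{NULL}.
#' @param min_diseases Minimum diseases per retained site (default 2).
#' @return Named list of partitions, one per retained site, each a
#'   list with \code{site}, \code{counts} (a
#'   \code{multi_rank_evidence}), and \code{n_diseases}; the number of
#'   unsited rows is attached as \code{attr(x, "n_unsited")}.
#' @export
partition_by_body_site <- function(evidence, taxonomy = NULL,
                                   min_diseases = 2L) {
  ev <- as.data.frame(evidence)
  unsited <- is.na(ev$body_site) | ev$body_site == ""
  if (any(unsited))
    message(sum(unsited), " evidence row(s) without a body site excluded")
  ev <- ev[!unsited, , drop = FALSE]
  if (nrow(ev) == 0) stop("no evidence rows carry a body site label")
  parts <- split(ev, ev$body_site)
  out <- list()
  for (site in names(parts)) {
    p <- parts[[site]]
    n_dis <- length(unique(p$entity_name))
    if (n_dis < min_diseases) next
    class(p) <- c("bhwa_evidence", "data.frame")
    out[[site]] <- list(site = site,
                        counts = propagate_up(p, taxonomy),
                        n_diseases = n_dis)
  }
  if (length(out) == 0)
    stop("no body site retains at least ", min_diseases, " diseases")
  attr(out, "n_unsited") <- sum(unsited)
  out
}

#' Sigmoid normalization of disturbance strength
#'
#' Maps a raw disturbance strength to the open interval (-1, 1) via
#' \code{2 / (1 + exp(-D)) - 1}, identically \code{tanh(D / 2)}: an
#' odd, strictly increasing squashing so that values near +1 indicate
#' a strong increase and values near -1 a strong decrease in relative
#' abundance.
#'
#' @param D Numeric vector of disturbance strengths.
#' @return Normalized strengths in (-1, 1).
#' @export
#' @examples
#' sigmoid_normalize(c(-2, 0, 2))
sigmoid_normalize <- function(D) {
  2 / (1 + exp(-D)) - 1
}

# site-local normalized strengths per rank for every disease in a
# partition: list rank -> disease x taxon matrix of D-hat
.site_dhat <- function(partition) {
  cts <- partition$counts
  diseases <- cts$entities
  out <- list()
  for (r in taxonomic_ranks()) {
    cr <- cts$counts[[r]]
    if (nrow(cr) == 0) next
    dm <- quantify_disturbance(cts, r, entities = diseases)
    out[[r]] <- sigmoid_normalize(dm$D)
  }
  out
}

#' Body-site-specific disturbance score
#'
#' The disturbance score of a disease at a body site is the Euclidean
#' norm of its sigmoid-normalized site-local disturbance strengths
#' across all six taxonomic ranks:
#' \deqn{DS_i = \sqrt{\sum_{rank} \sum_m \hat D_{m,i}^2}.}
#' A larger score indicates a greater capacity of the disease to
#' disturb the site's microbiota. Because evidence is propagated
#' upward, one documented disturbance contributes at every rank its
#' lineage reaches; direction is lost in the norm but retained in the
#' signed per-cell table (see \code{\link{site_dhat_table}}).
#'
#' @param partition One element of
#'   \code{\link{partition_by_body_site}}'s result.
#' @param disease Disease name present in the partition.
#' @return List with \code{ds}, per-rank squared contributions
#'   \code{contributions}, and \code{n_cells} (evidence-bearing
#'   (rank, taxon) cells).
#' @export
disturbance_score <- function(partition, disease) {
  if (!disease %in% partition$counts$entities)
    stop("disease '", disease, "' absent from site '",
         partition$site, "'")
  dh <- .site_dhat(partition)
  contrib <- stats::setNames(rep(0, length(taxonomic_ranks())),
                             taxonomic_ranks())
  n_cells <- 0L
  for (r in names(dh)) {
    v <- dh[[r]][disease, ]
    contrib[r] <- sum(v^2)
    n_cells <- n_cells + sum(v != 0)
  }
  list(ds = sqrt(sum(contrib)), contributions = contrib,
       n_cells = n_cells)
}

#' Disturbance score table for all diseases and sites
#'
#' @param partitions Result of \code{\link{partition_by_body_site}}.
#' @return Data frame with one row per (disease, body site):
#'   \code{disease}, \code{body_site}, \code{ds}, \code{n_cells}, and
#'   per-rank squared-contribution columns \code{contrib_<rank>}.
#' @export
disturbance_score_table <- function(partitions) {
  rows <- list()
  for (p in partitions) {
    for (d in p$counts$entities) {
      s <- disturbance_score(p, d)
      row <- data.frame(disease = d, body_site = p$site, ds = s$ds,
                        n_cells = s$n_cells, stringsAsFactors = FALSE)
      for (r in taxonomic_ranks())
        row[[paste0("contrib_", r)]] <- s$contributions[[r]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed normalized strengths per cell
#'
#' Long table of the sigmoid-normalized site-local strengths, so the
#' direction of each disturbance (lost in the Euclidean norm of
#' \code{\link{disturbance_score}}) can be recovered.
#'
#' @param partition One element of
#'   \code{\link{partition_by_body_site}}'s result.
#' @return Data frame \code{disease}, \code{body_site}, \code{rank},
#'   \code{taxon}, \code{d_hat} (nonzero cells only).
#' @export
site_dhat_table <- function(partition) {
  dh <- .site_dhat(partition)
  rows <- list()
  for (r in names(dh)) {
    M <- dh[[r]]
    nz <- which(M != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      disease = rownames(M)[nz[, 1]], body_site = partition$site,
      rank = r, taxon = colnames(M)[nz[, 2]], d_hat = M[nz],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(disease = character(0), body_site = character(0),
                      rank = character(0), taxon = character(0),
                      d_hat = numeric(0))
  rownames(out) <- NULL
  out
}
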