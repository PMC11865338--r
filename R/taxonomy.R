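#' Propagate evidence up the taxonomy
#'
#' Each evidence record contributes one signed event at its reported
#' rank and at every strictly higher rank reachable through the
#' microbe's lineage (species to phylum order). Propagation is
#' upward-only: a phylum-level report says nothing about member
#' genera. Microbes absent from the taxonomy are kept as rank-labeled
#' taxa contributing only at their own reported rank; a microbe listed
#' in the taxonomy at a rank different from its reported rank is an
#' error. Exact duplicate evidence rows are removed once; beyond that
#' every row counts as one piece of evidence.
#'
#' @param evidence A \code{bhwa_evidence} data frame (see
#'   \code{\link{read_evidence}}).
#' @param taxonomy A \code{bhwa_taxonomy} data frame (see
#'   \code{\link{read_taxonomy}}), or \code{NULL} for no lineage
#'   information.
#' @return A \code{multi_rank_evidence} object: per rank a data frame
#'   of direction counts (\code{entity}, \code{taxon}, \code{c_inc},
#'   \code{c_dec}), the entity universe, and the per-rank taxon
#'   universes. The number of unresolved microbe names is attached as
#'   \code{attr(x, "n_unresolved")}.
#' @export
propagate_up <- function(evidence, taxonomy = NULL) {
  stopifnot(is.data.frame(evidence))
  ranks <- taxonomic_ranks()
  ev <- as.data.frame(evidence)
  dup <- duplicated(ev[, c("source_id", "entity_type", "entity_name",
                           "microbe_name", "rank", "direction",
                           "body_site")])
  if (any(dup)) {
    message(sum(dup), " exact duplicate evidence row(s) removed")
    ev <- ev[!dup, , drop = FALSE]
  }

  tax_key <- character(0)
  if (!is.null(taxonomy) && nrow(taxonomy) > 0) {
    tax <- as.data.frame(taxonomy)
    tax_key <- norm_key(tax$taxon_name)
  }

  idx <- if (length(tax_key)) match(norm_key(ev$microbe_name), tax_key)
         else rep(NA_integer_, nrow(ev))
  matched <- !is.na(idx)
  if (any(matched)) {
    mism <- matched & tax$rank[idx] != ev$rank
    if (any(mism)) {
      i <- which(mism)[1]
      stop("microbe '", ev$microbe_name[i], "' reported at rank ",
           ev$rank[i], " but present in taxonomy at rank ",
           tax$rank[idx[i]])
    }
  }
  n_unresolved <- length(unique(norm_key(ev$microbe_name[!matched])))
  canonical <- ev$microbe_name
  canonical[matched] <- tax$taxon_name[idx[matched]]

  # one event at the reported rank, one at each resolvable higher rank
  rank_pos <- match(ev$rank, ranks)
  chunks <- list(data.frame(entity = ev$entity_name, taxon = canonical,
                            rank = ev$rank, direction = ev$direction,
                            stringsAsFactors = FALSE))
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    sel <- matched & rank_pos < ri
    if (!any(sel)) next
    anc <- tax[[r]][idx[sel]]
    ok <- !is.na(anc)
    if (!any(ok)) next
    chunks[[length(chunks) + 1L]] <- data.frame(
      entity = ev$entity_name[sel][ok], taxon = anc[ok], rank = r,
      direction = ev$direction[sel][ok], stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, chunks)
  if (n_unresolved > 0)
    message(n_unresolved, " microbe name(s) not in taxonomy; ",
            "kept at reported rank only")
  out <- aggregate_direction_counts(events,
                                    entities = unique(ev$entity_name))
  attr(out, "n_unresolved") <- n_unresolved
  out
}

#' Tally signed events into per-rank direction counts
#'
#' @param events Data frame of events (\code{entity}, \code{taxon},
#'   \code{rank}, \code{direction}) as produced internally by
#'   \code{\link{propagate_up}}.
#' @param entities Entity universe; defaults to the entities seen in
#'   \code{events}.
#' @return A \code{multi_rank_evidence} object: a list with
#'   \code{counts} (per rank a data frame \code{entity}, \code{taxon},
#'   \code{c_inc}, \code{c_dec}), \code{entities}, and \code{taxa}
#'   (per-rank taxon universes).
#' @export
aggregate_direction_counts <- function(events,
                                       entities = unique(events$entity)) {
  ranks <- taxonomic_ranks()
  counts <- stats::setNames(vector("list", length(ranks)), ranks)
  taxa <- stats::setNames(vector("list", length(ranks)), ranks)
  for (r in ranks) {
    er <- events[events$rank == r, , drop = FALSE]
    if (nrow(er) == 0) {
      counts[[r]] <- data.frame(entity = character(0), taxon = character(0),
                                c_inc = integer(0), c_dec = integer(0),
                                stringsAsFactors = FALSE)
      taxa[[r]] <- character(0)
      next
    }
    key <- paste(er$entity, er$taxon, sep = "\r")
    inc <- rowsum(as.integer(er$direction > 0), key)
    dec <- rowsum(as.integer(er$direction < 0), key)
    parts <- strsplit(rownames(inc), "\r", fixed = TRUE)
    counts[[r]] <- data.frame(
      entity = vapply(parts, `[[`, character(1), 1L),
      taxon = vapply(parts, `[[`, character(1), 2L),
      c_inc = as.integer(inc[, 1]),
      c_dec = as.integer(dec[, 1]),
      stringsAsFactors = FALSE
    )
    taxa[[r]] <- sort(unique(counts[[r]]$taxon))
  }
  structure(list(counts = counts, entities = sort(unique(entities)),
                 taxa = taxa),
            class = "multi_rank_evidence")
}

#' @export
print.multi_rank_evidence <- function(x, ...) {
  cat("multi-rank evidence:", length(x$entities), "entities\n")
  for (r in taxonomic_ranks())
    cat(sprintf("  %-8s %4d taxa, %5d (entity, taxon) records\n",
                r, length(x$taxa[[r]]), nrow(x$counts[[r]])))
  invisible(x)
}

#' Remove sparsely documented entities
#'
#' Entities documented with fewer than \code{threshold} distinct
#' disturbed microbes (counted at the reported-rank layer, before
#' propagation) are removed together with all their evidence. A single
#' pass; taxa referenced only by removed entities disappear from the
#' propagated universes because propagation is re-run downstream.
#'
#' @param evidence A \code{bhwa_evidence} data frame.
#' @param threshold Minimum number of distinct disturbed microbes
#'   (default 3).
#' @return The filtered evidence table; removed entities are recorded
#'   in \code{attr(x, "removed_entities")}.
#' @export
filter_min_disturbance <- function(evidence, threshold = 3L) {
  stopifnot(threshold >= 1)
  ev <- as.data.frame(evidence)
  n_microbes <- tapply(norm_key(ev$microbe_name), ev$entity_name,
                       function(x) length(unique(x)))
  keep_entities <- names(n_microbes)[n_microbes >= threshold]
  out <- ev[ev$entity_name %in% keep_entities, , drop = FALSE]
  if (nrow(out) == 0)
    stop("min-disturbance filter (threshold = ", threshold,
         ") removed every entity")
  rownames(out) <- NULL
  attr(out, "removed_entities") <-
    setdiff(names(n_microbes), keep_entities)
  class(out) <- c("bhwa_evidence", "data.frame")
  out
}
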