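#' Configuration for the synthetic evidence generator
#'
#' Defines the conditions under which synthetic disturbance databases
#' are generated: entity counts, a six-rank taxonomy profile, planted
#' block structure and its agreement rates, evidence depth, direction
#' conflicts, and optional body-site labeling. The defaults emulate a
#' fiber-database-sized study: 32 entities in set A grouped into six
#' blocks over 40 genera, with high within-block direction agreement
#' and occasional per-row direction conflicts.
#'
#' @param n_entities_a Entities in set A (default 32).
#' @param n_entities_b Entities in set B for cross-set runs (default
#'   0, no second set).
#' @param n_genera Number of genera carrying planted profiles
#'   (default 40).
#' @param n_families,n_orders,n_classes,n_phyla Higher-rank universe
#'   sizes (defaults 12, 8, 5, 3).
#' @param n_blocks Planted blocks (default 6).
#' @param within_block_agreement Probability an entity follows its
#'   block's planted direction at a genus (default 0.9).
#' @param between_block_agreement Probability a block's planted
#'   direction at a genus equals block 1's (default 0.5; 0 plants
#'   fully opposed blocks).
#' @param evidence_per_pair Integer range (length-2 vector) of
#'   evidence rows per (entity, genus) pair (default c(1, 3)).
#' @param taxa_per_entity Number of genera each entity has evidence
#'   for (default 15 of the 40 genera). Sparsity matters: a taxon
#'   associated with every entity carries zero IDF weight, so a dense
#'   table is degenerate under the disturbance-strength model.
#' @param conflict_rate Probability an individual evidence row flips
#'   its entity's direction (default 0.1).
#' @param n_body_sites Number of body sites to label evidence with
#'   (default 0, no labels).
#' @param entity_type \code{"fiber"} or \code{"disease"} for set A.
#' @param seed Integer seed; a fixed seed yields identical tables.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_entities_a = 32L, n_entities_b = 0L,
                         n_genera = 40L, n_families = 12L, n_orders = 8L,
                         n_classes = 5L, n_phyla = 3L, n_blocks = 6L,
                         within_block_agreement = 0.9,
                         between_block_agreement = 0.5,
                         evidence_per_pair = c(1L, 3L),
                         taxa_per_entity = max(3L, round(n_genera * 0.375)),
                         conflict_rate = 0.1, n_body_sites = 0L,
                         entity_type = c("fiber", "disease"),
                         seed = 1L) {
  entity_type <- match.arg(entity_type)
  if (any(c(within_block_agreement, between_block_agreement,
            conflict_rate) < 0) ||
      any(c(within_block_agreement, between_block_agreement,
            conflict_rate) > 1))
    stop("probabilities must be in [0, 1]")
  if (n_blocks > n_entities_a)
    stop("more blocks than entities in set A")
  if (length(evidence_per_pair) != 2 || evidence_per_pair[1] < 1 ||
      evidence_per_pair[1] > evidence_per_pair[2])
    stop("evidence_per_pair must be a valid integer range")
  structure(as.list(environment()), class = "synth_config")
}

# random but consistent parent assignment for a six-rank tree;
# genera names carry planted profiles, higher ranks aggregate them
.synth_taxonomy <- function(cfg) {
  nm <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  genera <- nm("Genus", cfg$n_genera)
  families <- nm("Family", cfg$n_families)
  orders <- nm("Order", cfg$n_orders)
  classes <- nm("Class", cfg$n_classes)
  phyla <- nm("Phylum", cfg$n_phyla)
  fam_of <- sample(families, cfg$n_genera, replace = TRUE)
  ord_of_fam <- stats::setNames(sample(orders, cfg$n_families,
                                       replace = TRUE), families)
  cls_of_ord <- stats::setNames(sample(classes, cfg$n_orders,
                                       replace = TRUE), orders)
  phy_of_cls <- stats::setNames(sample(phyla, cfg$n_classes,
                                       replace = TRUE), classes)
  tab <- data.frame(taxon_name = genera, rank = "genus",
                    species = NA_character_, genus = genera,
                    family = fam_of,
                    order = unname(ord_of_fam[fam_of]),
                    class = unname(cls_of_ord[ord_of_fam[fam_of]]),
                    phylum = unname(
                      phy_of_cls[cls_of_ord[ord_of_fam[fam_of]]]),
                    stringsAsFactors = FALSE)
  class(tab) <- c("bhwa_taxonomy", "data.frame")
  tab
}

.synth_entities <- function(cfg, set = c("a", "b")) {
  set <- match.arg(set)
  n <- if (set == "a") cfg$n_entities_a else cfg$n_entities_b
  prefix <- if (set == "a") {
    if (cfg$entity_type == "fiber") "Fiber" else "DiseaseA"
  } else "Disease"
  sprintf("%s%02d", prefix, seq_len(n))
}

.synth_evidence_set <- function(cfg, entities, taxonomy, profiles,
                                blocks, etype, sites) {
  rows <- list()
  genera <- taxonomy$taxon_name
  for (e in seq_along(entities)) {
    active <- sort(sample.int(cfg$n_genera,
                              min(cfg$taxa_per_entity, cfg$n_genera)))
    site_e <- if (length(sites)) sample(sites, 1) else NA_character_
    for (g in active) {
      planted <- profiles[blocks[e], g]
      dir_e <- if (stats::runif(1) < cfg$within_block_agreement)
        planted else -planted
      n_rows <- sample(seq(cfg$evidence_per_pair[1],
                           cfg$evidence_per_pair[2]), 1)
      for (rep_i in seq_len(n_rows)) {
        dir_row <- if (stats::runif(1) < cfg$conflict_rate)
          -dir_e else dir_e
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = sprintf("src_%s_%02d_%d", entities[e], g, rep_i),
          entity_type = etype, entity_name = entities[e],
          microbe_name = genera[g], rank = "genus",
          direction = ifelse(dir_row > 0, "increase", "decrease"),
          body_site = site_e, notes = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic evidence database with planted structure
#'
#' Builds a random six-rank taxonomy, plants a signed direction
#' profile over genera for each block, and samples genus-level
#' evidence rows per entity with the configured agreement and
#' conflict rates. Profiles are planted at genus rank so downstream
#' analyses exercise the same upward-propagation path as real data.
#' With \code{between_block_agreement = 0} and two blocks, block
#' profiles are exactly opposed and block recovery by clustering is
#' expected.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return List with \code{evidence} (set A, and set B rows appended
#'   when \code{n_entities_b > 0}), \code{taxonomy}, and
#'   \code{truth}: a data frame (\code{entity}, \code{set},
#'   \code{block}) plus the planted profile matrix as
#'   \code{attr(truth, "profiles")}.
#' @export
generate_synthetic_data <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  taxonomy <- .synth_taxonomy(cfg)

  # block 1 profile random; other blocks agree with it per genus with
  # probability between_block_agreement
  profiles <- matrix(0L, cfg$n_blocks, cfg$n_genera)
  profiles[1, ] <- sample(c(-1L, 1L), cfg$n_genera, replace = TRUE)
  if (cfg$n_blocks > 1) {
    for (b in 2:cfg$n_blocks) {
      agree <- stats::runif(cfg$n_genera) < cfg$between_block_agreement
      profiles[b, ] <- ifelse(agree, profiles[1, ], -profiles[1, ])
    }
  }

  ents_a <- .synth_entities(cfg, "a")
  blocks_a <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_entities_a)
  sites <- if (cfg$n_body_sites > 0)
    sprintf("Site%02d", seq_len(cfg$n_body_sites)) else character(0)
  ev <- .synth_evidence_set(cfg, ents_a, taxonomy, profiles, blocks_a,
                            cfg$entity_type, sites)
  truth <- data.frame(entity = ents_a, set = "a",
                      block = blocks_a, stringsAsFactors = FALSE)

  if (cfg$n_entities_b > 0) {
    ents_b <- .synth_entities(cfg, "b")
    blocks_b <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_entities_b)
    ev_b <- .synth_evidence_set(cfg, ents_b, taxonomy, profiles,
                                blocks_b, "disease", sites)
    ev <- rbind(ev, ev_b)
    truth <- rbind(truth,
                   data.frame(entity = ents_b, set = "b",
                              block = blocks_b, stringsAsFactors = FALSE))
  }
  evidence <- as_evidence(ev)
  attr(truth, "profiles") <- profiles
  list(evidence = evidence, taxonomy = taxonomy, truth = truth)
}
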