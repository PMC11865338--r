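# In-code fixtures and independent oracles shared across test files.

# small taxonomy table (rank_columns layout, already validated shape)
make_taxonomy <- function(df) {
  ranks <- taxonomic_ranks()
  for (r in ranks) if (!r %in% names(df)) df[[r]] <- NA_character_
  for (i in seq_len(nrow(df))) df[i, df$rank[i]] <- df$taxon_name[i]
  class(df) <- c("bhwa_taxonomy", "data.frame")
  df
}

demo_taxonomy <- function() {
  make_taxonomy(data.frame(
    taxon_name = c("Lactobacillus", "Bacteroides", "Prevotella",
                   "Faecalibacterium prausnitzii"),
    rank = c("genus", "genus", "genus", "species"),
    genus = c(NA, NA, NA, "Faecalibacterium"),
    family = c("Lactobacillaceae", "Bacteroidaceae", "Prevotellaceae",
               "Ruminococcaceae"),
    order = c("Lactobacillales", "Bacteroidales", "Bacteroidales",
              "Oscillospirales"),
    class = c("Bacilli", "Bacteroidia", "Bacteroidia", "Clostridia"),
    phylum = c("Firmicutes", "Bacteroidetes", "Bacteroidetes",
               "Firmicutes"),
    stringsAsFactors = FALSE))
}

# evidence row builder
ev_row <- function(entity, microbe, rank, direction,
                   source = "src1", type = "fiber", site = NA_character_) {
  data.frame(source_id = source, entity_type = type, entity_name = entity,
             microbe_name = microbe, rank = rank,
             direction = direction, body_site = site,
             notes = NA_character_, stringsAsFactors = FALSE)
}

make_evidence <- function(...) as_evidence(do.call(rbind, list(...)))

# build a multi_rank_evidence object directly from per-rank count
# tables (entity, taxon, c_inc, c_dec), bypassing propagation
make_mre <- function(counts_by_rank, entities = NULL) {
  ranks <- taxonomic_ranks()
  counts <- stats::setNames(vector("list", length(ranks)), ranks)
  taxa <- stats::setNames(vector("list", length(ranks)), ranks)
  empty <- data.frame(entity = character(0), taxon = character(0),
                      c_inc = integer(0), c_dec = integer(0),
                      stringsAsFactors = FALSE)
  for (r in ranks) {
    counts[[r]] <- if (r %in% names(counts_by_rank))
      counts_by_rank[[r]] else empty
    taxa[[r]] <- sort(unique(counts[[r]]$taxon))
  }
  if (is.null(entities))
    entities <- sort(unique(unlist(lapply(counts, `[[`, "entity"))))
  structure(list(counts = counts, entities = entities, taxa = taxa),
            class = "multi_rank_evidence")
}

# random per-rank count tables for oracle-equivalence checks
random_counts <- function(n_entities, n_taxa, ranks_used, p_present = 0.6) {
  entities <- sprintf("E%d", seq_len(n_entities))
  out <- list()
  for (r in ranks_used) {
    taxa <- sprintf("%s_T%d", r, seq_len(n_taxa))
    rows <- expand.grid(entity = entities, taxon = taxa,
                        stringsAsFactors = FALSE)
    rows <- rows[stats::runif(nrow(rows)) < p_present, , drop = FALSE]
    if (nrow(rows) == 0) next
    rows$c_inc <- sample(0:3, nrow(rows), replace = TRUE)
    rows$c_dec <- sample(0:3, nrow(rows), replace = TRUE)
    rows <- rows[rows$c_inc + rows$c_dec >= 1, , drop = FALSE]
    if (nrow(rows) > 0) out[[r]] <- rows
  }
  out
}

# ---- independent brute-force oracle for the weighted similarity ----
# Scalar re-derivation of the whole chain (strength quantification,
# per-rank cosine / t / sigma / weight, weighted aggregation), written
# with explicit loops and no shared code with the package internals.
oracle_pair <- function(counts_by_rank, ei, ej) {
  clamp <- 1 - 1e-12
  sum_w <- 0; sum_ws <- 0; sum_m <- 0; any_rank <- FALSE
  for (r in names(counts_by_rank)) {
    tab <- counts_by_rank[[r]]
    ents <- sort(unique(tab$entity))
    if (length(ents) < 2 || !all(c(ei, ej) %in% ents)) next
    taxa <- sort(unique(tab$taxon))
    N <- length(ents)
    Di <- numeric(length(taxa)); Dj <- numeric(length(taxa))
    for (t in seq_along(taxa)) {
      n_m <- 0
      for (e in ents) {
        sel <- tab$entity == e & tab$taxon == taxa[t]
        if (any(sel) && sum(tab$c_inc[sel] + tab$c_dec[sel]) >= 1)
          n_m <- n_m + 1
      }
      idf <- log(N / n_m)
      for (who in 1:2) {
        e <- c(ei, ej)[who]
        sel <- tab$entity == e & tab$taxon == taxa[t]
        net <- if (any(sel)) sum(tab$c_inc[sel]) - sum(tab$c_dec[sel]) else 0
        val <- sign(net) * abs(net) * idf
        if (who == 1) Di[t] <- val else Dj[t] <- val
      }
    }
    m_shared <- 0
    for (t in seq_along(taxa))
      if (Di[t] != 0 || Dj[t] != 0) m_shared <- m_shared + 1
    df <- m_shared - 2
    ni <- sqrt(sum(Di^2)); nj <- sqrt(sum(Dj^2))
    if (ni == 0 || nj == 0 || df < 1) next
    sim <- sum(Di * Dj) / (ni * nj)
    s <- max(-clamp, min(clamp, sim))
    sigma <- sqrt((1 - s^2) / df)
    w <- 1 / sigma
    sum_w <- sum_w + w
    sum_ws <- sum_ws + w * sim
    sum_m <- sum_m + m_shared
    any_rank <- TRUE
  }
  if (!any_rank)
    return(list(sim_weighted = NA_real_, p = NA_real_))
  sw <- sum_ws / sum_w
  sb <- sqrt(1 / sum_w)
  df <- sum_m - 2
  list(sim_weighted = sw, sigma_bar = sb, t_score = sw / sb, df = df,
       p = 2 * stats::pt(-abs(sw / sb), df = df))
}

# ---- independent brute-force triangle census on a signed graph ----
# edges: data.frame(node_i, node_j, sign)
oracle_census <- function(nodes, edges) {
  sgn <- new.env()
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  for (i in seq_len(nrow(edges)))
    assign(key(edges$node_i[i], edges$node_j[i]), edges$sign[i],
           envir = sgn)
  coherent <- 0; incoherent <- 0
  n <- length(nodes)
  if (n >= 3) {
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (c in (b + 1):n) {
      k1 <- key(nodes[a], nodes[b]); k2 <- key(nodes[b], nodes[c])
      k3 <- key(nodes[a], nodes[c])
      if (exists(k1, envir = sgn) && exists(k2, envir = sgn) &&
          exists(k3, envir = sgn)) {
        pr <- get(k1, envir = sgn) * get(k2, envir = sgn) *
          get(k3, envir = sgn)
        if (pr > 0) coherent <- coherent + 1 else incoherent <- incoherent + 1
      }
    }
  }
  list(total = coherent + incoherent, coherent = coherent,
       incoherent = incoherent)
}

# small planted two-block similarity run used by several files
planted_run <- function(seed, n_entities = 8, within = 1, between = 0,
                        conflict = 0) {
  cfg <- synth_config(n_entities_a = n_entities, n_genera = 16,
                      taxa_per_entity = 8, n_blocks = 2,
                      within_block_agreement = within,
                      between_block_agreement = between,
                      conflict_rate = conflict, seed = seed)
  syn <- generate_synthetic_data(cfg)
  cts <- propagate_up(filter_min_disturbance(syn$evidence), syn$taxonomy)
  list(syn = syn, counts = cts, sims = pairwise_similarity(cts))
}
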