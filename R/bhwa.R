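#' Quantify disturbance strength at one rank
#'
#' For each (entity i, taxon m) at the given rank, the net signed
#' evidence count is \code{net = c_inc - c_dec}; the direction is
#' \code{alpha = sign(net)} and the count \code{C = |net|} (ties in
#' direction cancel to zero). The disturbance strength is the
#' IDF-weighted signed count
#' \deqn{D_{m,i} = \alpha_{m,i} \, C_{m,i} \, \ln(N / n_m),}
#' where \code{N} is the number of entities at this rank and
#' \code{n_m} the number of entities with any evidence for taxon
#' \code{m}. The log factor down-weights taxa associated with many
#' entities and vanishes for taxa associated with every entity.
#'
#' @param counts A \code{multi_rank_evidence} object.
#' @param rank One of the six taxonomic ranks.
#' @param entities Optional entity universe fixing \code{N} (used for
#'   body-site-local scoring, where \code{N} is the number of diseases
#'   at the site); defaults to entities with evidence at this rank.
#' @return A \code{disturbance_matrix}: list with \code{rank},
#'   \code{entities}, \code{taxa}, matrices \code{D}, \code{alpha},
#'   \code{C} (entity x taxon), scalar \code{N} and per-taxon vector
#'   \code{n}.
#' @export
quantify_disturbance <- function(counts, rank, entities = NULL) {
  stopifnot(inherits(counts, "multi_rank_evidence"),
            rank %in% taxonomic_ranks())
  cr <- counts$counts[[rank]]
  if (is.null(entities)) entities <- sort(unique(cr$entity))
  if (length(entities) < 2)
    stop("rank '", rank, "' has fewer than 2 entities; ln(N/n) degenerate")
  cr <- cr[cr$entity %in% entities, , drop = FALSE]
  taxa <- sort(unique(cr$taxon))
  N <- length(entities)
  M <- length(taxa)
  alpha <- C <- D <- matrix(0, N, M, dimnames = list(entities, taxa))
  if (M > 0) {
    i <- match(cr$entity, entities)
    j <- match(cr$taxon, taxa)
    net <- cr$c_inc - cr$c_dec
    alpha[cbind(i, j)] <- sign(net)
    C[cbind(i, j)] <- abs(net)
    # n_m counts any evidence (c_inc + c_dec >= 1), even if net = 0
    has <- matrix(0, N, M, dimnames = list(entities, taxa))
    has[cbind(i, j)] <- as.numeric(cr$c_inc + cr$c_dec >= 1)
    n <- colSums(has)
    idf <- log(N / n)
    D <- alpha * C * rep(idf, each = N)
  } else {
    n <- numeric(0)
  }
  structure(list(rank = rank, entities = entities, taxa = taxa,
                 D = D, alpha = alpha, C = C, N = N, n = n),
            class = "disturbance_matrix")
}

# clamp for the t construction so identical vectors get a finite weight
.sim_clamp <- 1 - 1e-12

#' Per-rank cosine similarity with deviation and weight
#'
#' The similarity of two entities at one rank is the cosine of their
#' disturbance-strength vectors. Significance is assessed by treating
#' the cosine as a correlation-like statistic:
#' \code{t = SIM * sqrt(df / (1 - SIM^2))} with
#' \code{df = m_shared - 2}, where \code{m_shared} is the number of
#' taxa at which either entity has nonzero strength. The deviation is
#' \code{sigma = SIM / t = sqrt((1 - SIM^2) / df)} (well defined at
#' \code{SIM = 0}) and the rank's weight is \code{W = 1 / sigma}.
#' A rank does not contribute when either vector is all zero or
#' \code{df < 1}. \code{|SIM|} is clamped at \code{1 - 1e-12} before
#' the t construction so identical vectors keep a finite weight.
#'
#' @param Di,Dj Numeric disturbance vectors over the same taxon
#'   universe.
#' @param rank Rank label carried through to the result.
#' @return List with \code{rank}, \code{sim}, \code{m_shared},
#'   \code{t}, \code{sigma}, \code{weight}, \code{contributing}.
#' @export
rank_similarity <- function(Di, Dj, rank = NA_character_) {
  stopifnot(length(Di) == length(Dj))
  support <- which(Di != 0 | Dj != 0)
  m_shared <- length(support)
  df <- m_shared - 2
  ni <- sqrt(sum(Di^2)); nj <- sqrt(sum(Dj^2))
  if (ni == 0 || nj == 0 || df < 1) {
    return(list(rank = rank, sim = NA_real_, m_shared = m_shared,
                t = NA_real_, sigma = NA_real_, weight = NA_real_,
                contributing = FALSE))
  }
  sim <- sum(Di * Dj) / (ni * nj)
  sim <- max(-1, min(1, sim))
  s <- max(-.sim_clamp, min(.sim_clamp, sim))
  tval <- s * sqrt(df / (1 - s^2))
  sigma <- sqrt((1 - s^2) / df)
  list(rank = rank, sim = sim, m_shared = m_shared, t = tval,
       sigma = sigma, weight = 1 / sigma, contributing = TRUE)
}

#' Aggregate per-rank similarities into a weighted similarity
#'
#' The weighted similarity is the weight-normalized convex combination
#' of the contributing ranks' cosines,
#' \deqn{SIM = \sum_l W_l SIM_l / \sum_l W_l,}
#' the weighted deviation is
#' \code{sigma_bar = sqrt(1 / sum(W_l))}, the t-score is
#' \code{SIM / sigma_bar}, and the two-tailed p-value uses a Student-t
#' reference with \code{df = sum(m_shared) - 2} over contributing
#' ranks.
#'
#' @param ranks A list of per-rank results from
#'   \code{\link{rank_similarity}}.
#' @return List with \code{sim_weighted}, \code{sigma_bar},
#'   \code{t_score}, \code{df}, \code{p}; all \code{NA} when no rank
#'   contributes.
#' @export
aggregate_weighted <- function(ranks) {
  keep <- vapply(ranks, function(r) isTRUE(r$contributing), logical(1))
  if (!any(keep))
    return(list(sim_weighted = NA_real_, sigma_bar = NA_real_,
                t_score = NA_real_, df = NA_real_, p = NA_real_))
  W <- vapply(ranks[keep], `[[`, numeric(1), "weight")
  S <- vapply(ranks[keep], `[[`, numeric(1), "sim")
  m <- vapply(ranks[keep], `[[`, numeric(1), "m_shared")
  sw <- sum(W * S) / sum(W)
  sb <- sqrt(1 / sum(W))
  tt <- sw / sb
  df <- sum(m) - 2
  p <- if (df >= 1) 2 * stats::pt(-abs(tt), df = df) else NA_real_
  list(sim_weighted = sw, sigma_bar = sb, t_score = tt, df = df, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (wraps \code{stats::p.adjust}).
#'
#' @param p Numeric vector of p-values in [0, 1]; \code{NA}s pass
#'   through.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Vectorized per-rank pair statistics from one or two entity x taxon
# matrices (cross mode aligns the two taxon universes first).
# Returns matrices sim, W, m_shared, contributing of dim nA x nB.
.rank_pair_stats <- function(DA, DB = NULL) {
  cross <- !is.null(DB)
  if (!cross) DB <- DA
  nrmA <- sqrt(rowSums(DA^2)); nrmB <- sqrt(rowSums(DB^2))
  num <- DA %*% t(DB)
  den <- outer(nrmA, nrmB)
  sim <- ifelse(den > 0, num / den, NA_real_)
  sim[] <- pmax(-1, pmin(1, sim))
  ZA <- (DA != 0) + 0; ZB <- (DB != 0) + 0
  inter <- ZA %*% t(ZB)
  m_shared <- outer(rowSums(ZA), rowSums(ZB), "+") - inter
  df <- m_shared - 2
  contributing <- den > 0 & df >= 1
  s <- pmax(-.sim_clamp, pmin(.sim_clamp, sim))
  W <- array(NA_real_, dim = dim(sim))
  ok <- which(contributing)
  W[ok] <- 1 / sqrt((1 - s[ok]^2) / df[ok])
  list(sim = sim, W = W, m_shared = m_shared, contributing = contributing)
}

# align a list of per-rank matrices from two sets on union or
# intersection of taxon universes (zero fill for union)
.align_columns <- function(DA, DB, align = c("union", "intersection")) {
  align <- match.arg(align)
  ta <- colnames(DA); tb <- colnames(DB)
  taxa <- if (align == "union") sort(union(ta, tb)) else sort(intersect(ta, tb))
  pad <- function(D, taxa) {
    out <- matrix(0, nrow(D), length(taxa),
                  dimnames = list(rownames(D), taxa))
    common <- intersect(colnames(D), taxa)
    out[, common] <- D[, common, drop = FALSE]
    out
  }
  list(A = pad(DA, taxa), B = pad(DB, taxa))
}

# quantify every rank of a multi_rank_evidence into a list of matrices
# over a fixed entity universe (rows = all entities; entities without
# evidence at a rank get all-zero rows and never contribute there)
.rank_matrices <- function(counts, entities = counts$entities) {
  out <- list()
  for (r in taxonomic_ranks()) {
    cr <- counts$counts[[r]]
    ents_r <- sort(unique(cr$entity[cr$entity %in% entities]))
    if (length(ents_r) < 2) next
    dm <- quantify_disturbance(counts, r, entities = ents_r)
    D <- matrix(0, length(entities), length(dm$taxa),
                dimnames = list(entities, dm$taxa))
    D[dm$entities, ] <- dm$D
    out[[r]] <- D
  }
  out
}

#' Pairwise multi-rank weighted similarities
#'
#' Computes the weighted disturbance similarity for every entity pair.
#' In the within-set modes (\code{fiber-fiber}, \code{disease-disease})
#' all unordered pairs of one evidence set are compared; self pairs are
#' reported with similarity 1 but excluded from the FDR family. In the
#' cross-set mode (\code{fiber-disease}) each set is quantified with
#' its own entity count \code{N} and taxon document frequencies
#' \code{n} (IDF within its own database), per-rank vectors are aligned
#' on the union (default) or intersection of the two taxon universes,
#' and all |A| x |B| pairs are compared. FDR is adjusted over all
#' non-self pairs of the run.
#'
#' @param counts_a A \code{multi_rank_evidence} object (from
#'   \code{\link{propagate_up}}).
#' @param counts_b Second \code{multi_rank_evidence} for cross-set
#'   mode; \code{NULL} (default) for within-set mode.
#' @param align Taxon alignment for cross-set mode: \code{"union"}
#'   (zero fill, default) or \code{"intersection"}.
#' @return Data frame of class \code{bhwa_similarity}: one row per
#'   pair with \code{entity_i}, \code{entity_j}, per-rank
#'   \code{sim_<rank>} and \code{w_<rank>} columns, and aggregated
#'   \code{sim_weighted}, \code{sigma_bar}, \code{t_score}, \code{df},
#'   \code{p}, \code{fdr}. Pairs with no contributing rank have
#'   \code{NA} similarity and take part in no network.
#' @export
pairwise_similarity <- function(counts_a, counts_b = NULL,
                                align = c("union", "intersection")) {
  align <- match.arg(align)
  cross <- !is.null(counts_b)
  ranks <- taxonomic_ranks()

  if (!cross) {
    ents <- counts_a$entities
    if (length(ents) < 2) stop("fewer than 2 entities")
    Dl <- .rank_matrices(counts_a)
    stats_l <- lapply(Dl, .rank_pair_stats)
    ii <- which(upper.tri(diag(length(ents))), arr.ind = TRUE)
    pairs <- data.frame(entity_i = ents[ii[, 1]], entity_j = ents[ii[, 2]],
                        stringsAsFactors = FALSE)
    self <- data.frame(entity_i = ents, entity_j = ents,
                       stringsAsFactors = FALSE)
    idx <- ii
    ents_b <- ents
  } else {
    ents <- counts_a$entities
    ents_b <- counts_b$entities
    if (length(ents) < 2 || length(ents_b) < 2)
      stop("fewer than 2 entities in a set")
    Da <- .rank_matrices(counts_a)
    Db <- .rank_matrices(counts_b)
    common <- intersect(names(Da), names(Db))
    stats_l <- stats::setNames(lapply(common, function(r) {
      al <- .align_columns(Da[[r]], Db[[r]], align)
      .rank_pair_stats(al$A, al$B)
    }), common)
    idx <- as.matrix(expand.grid(seq_along(ents), seq_along(ents_b)))
    pairs <- data.frame(entity_i = ents[idx[, 1]],
                        entity_j = ents_b[idx[, 2]],
                        stringsAsFactors = FALSE)
    self <- NULL
  }

  n_pairs <- nrow(pairs)
  sumW <- sumWS <- summ <- numeric(n_pairs)
  any_contrib <- rep(FALSE, n_pairs)
  for (r in names(stats_l)) {
    st <- stats_l[[r]]
    sim_r <- st$sim[idx]; W_r <- st$W[idx]
    contrib <- st$contributing[idx]
    pairs[[paste0("sim_", r)]] <- ifelse(contrib, sim_r, NA_real_)
    pairs[[paste0("w_", r)]] <- W_r
    pairs[[paste0("m_", r)]] <- ifelse(contrib, st$m_shared[idx], NA_real_)
    sumW <- sumW + ifelse(contrib, W_r, 0)
    sumWS <- sumWS + ifelse(contrib, W_r * sim_r, 0)
    summ <- summ + ifelse(contrib, st$m_shared[idx], 0)
    any_contrib <- any_contrib | contrib
  }
  # ranks absent from the run still get their columns, for a stable schema
  for (r in setdiff(ranks, names(stats_l))) {
    pairs[[paste0("sim_", r)]] <- NA_real_
    pairs[[paste0("w_", r)]] <- NA_real_
    pairs[[paste0("m_", r)]] <- NA_real_
  }

  pairs$sim_weighted <- ifelse(any_contrib, sumWS / sumW, NA_real_)
  pairs$sigma_bar <- ifelse(any_contrib, sqrt(1 / sumW), NA_real_)
  pairs$t_score <- pairs$sim_weighted / pairs$sigma_bar
  pairs$df <- ifelse(any_contrib, summ - 2, NA_real_)
  pairs$p <- ifelse(any_contrib & pairs$df >= 1,
                    2 * stats::pt(-abs(pairs$t_score), df = pairs$df),
                    NA_real_)
  # FDR family: all defined non-self pairs of this run
  pairs$fdr <- NA_real_
  ok <- !is.na(pairs$p)
  pairs$fdr[ok] <- bh_fdr(pairs$p[ok])

  if (!cross) {
    # self similarity is 1 by definition; reported, never in the FDR family
    self$sim_weighted <- 1
    for (nm in setdiff(names(pairs), names(self))) self[[nm]] <- NA_real_
    self <- self[, names(pairs)]
    pairs <- rbind(pairs, self)
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("bhwa_similarity", "data.frame")
  pairs
}

#' Similarity matrix from a pairwise similarity table
#'
#' @param sim A \code{bhwa_similarity} table from a within-set run.
#' @return Symmetric matrix of weighted similarities with unit
#'   diagonal; \code{NA} for undefined pairs.
#' @export
similarity_matrix <- function(sim) {
  ents <- sort(unique(c(sim$entity_i, sim$entity_j)))
  M <- matrix(NA_real_, length(ents), length(ents),
              dimnames = list(ents, ents))
  diag(M) <- 1
  off <- sim$entity_i != sim$entity_j
  i <- match(sim$entity_i[off], ents)
  j <- match(sim$entity_j[off], ents)
  M[cbind(i, j)] <- sim$sim_weighted[off]
  M[cbind(j, i)] <- sim$sim_weighted[off]
  M
}
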