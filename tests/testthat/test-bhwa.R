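test_that("disturbance strength follows the signed IDF-count formula", {
  # 4 entities; taxon T1 held by 2 of them; E1 has c_inc = 3:
  # D = 3 * ln(4 / 2)
  cts <- make_mre(list(genus = data.frame(
    entity = c("E1", "E2", "E3", "E4"),
    taxon = c("T1", "T1", "T2", "T2"),
    c_inc = c(3L, 1L, 1L, 1L), c_dec = 0L,
    stringsAsFactors = FALSE)))
  dm <- quantify_disturbance(cts, "genus")
  expect_equal(dm$N, 4)
  expect_equal(unname(dm$n["T1"]), 2)
  expect_equal(dm$D["E1", "T1"], 3 * log(2), tolerance = 1e-12)
  expect_equal(dm$D["E1", "T1"], 2.0794, tolerance = 1e-4)
})

test_that("taxa associated with every entity carry zero strength", {
  cts <- make_mre(list(genus = data.frame(
    entity = c("E1", "E2"), taxon = "T1", c_inc = c(2L, 5L), c_dec = 0L,
    stringsAsFactors = FALSE)))
  dm <- quantify_disturbance(cts, "genus")
  expect_true(all(dm$D == 0))  # ln(N/n) = ln(1) = 0
})

test_that("tied increase/decrease evidence cancels to zero strength", {
  cts <- make_mre(list(genus = data.frame(
    entity = c("E1", "E2"), taxon = c("T1", "T2"),
    c_inc = c(2L, 1L), c_dec = c(2L, 0L), stringsAsFactors = FALSE)))
  dm <- quantify_disturbance(cts, "genus")
  expect_equal(dm$alpha["E1", "T1"], 0)
  expect_equal(dm$D["E1", "T1"], 0)
  # but the tied record still counts toward the taxon's entity count n
  expect_equal(unname(dm$n["T1"]), 1)
  expect_error(quantify_disturbance(make_mre(list(genus = data.frame(
    entity = "E1", taxon = "T1", c_inc = 1L, c_dec = 0L,
    stringsAsFactors = FALSE))), "genus"), "fewer than 2")
})

test_that("per-rank similarity has the stated closed forms", {
  D <- c(1, -2, 0.5, 0, 0, 0)
  id <- rank_similarity(D, D, "genus")
  expect_equal(id$sim, 1)
  expect_true(is.finite(id$weight))  # clamp keeps the weight finite
  anti <- rank_similarity(D, -D, "genus")
  expect_equal(anti$sim, -1)
  # orthogonal vectors over support of 6: sigma = sqrt(1/4), W = 2
  Di <- c(1, 1, 1, 0, 0, 0); Dj <- c(0, 0, 0, 1, 1, 1)
  ort <- rank_similarity(Di, Dj, "genus")
  expect_equal(ort$sim, 0)
  expect_equal(ort$m_shared, 6)
  expect_equal(ort$sigma, 0.5)
  expect_equal(ort$weight, 2)
  # sigma = SIM / t wherever SIM != 0
  gen <- rank_similarity(c(1, 2, 0, 1), c(2, 1, 1, 0), "genus")
  expect_equal(gen$sigma, gen$sim / gen$t, tolerance = 1e-12)
  # all-zero vector or df < 1 means the rank does not contribute
  expect_false(rank_similarity(c(0, 0), c(1, 1), "genus")$contributing)
  expect_false(rank_similarity(c(1, 0), c(1, 1), "genus")$contributing)
})

test_that("weighted aggregation is the weight-normalized convex mean", {
  mk <- function(sim, w, m) list(sim = sim, weight = w, m_shared = m,
                                 contributing = TRUE)
  one <- aggregate_weighted(list(mk(0.42, 3, 8)))
  expect_equal(one$sim_weighted, 0.42)
  eq <- aggregate_weighted(list(mk(0.2, 2, 5), mk(0.4, 2, 5)))
  expect_equal(eq$sim_weighted, 0.3)
  # weights (1, 3), sims (0, 0.4): mean 0.3, sigma_bar = sqrt(1/4)
  uneq <- aggregate_weighted(list(mk(0, 1, 5), mk(0.4, 3, 6)))
  expect_equal(uneq$sim_weighted, 0.3)
  expect_equal(uneq$sigma_bar, 0.5)
  expect_equal(uneq$t_score, 0.6)
  expect_equal(uneq$df, 5 + 6 - 2)
  expect_equal(uneq$p, 2 * pt(-0.6, df = 9), tolerance = 1e-12)
  none <- aggregate_weighted(list(list(contributing = FALSE)))
  expect_true(is.na(none$sim_weighted))
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(order(adj) == order(p)))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("pairwise similarities are symmetric with unit self-similarity", {
  run <- planted_run(seed = 3, n_entities = 6)
  M <- similarity_matrix(run$sims)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, nrow(M)))
  self <- run$sims[run$sims$entity_i == run$sims$entity_j, ]
  expect_equal(self$sim_weighted, rep(1, nrow(self)))
  expect_true(all(is.na(self$fdr)))  # self pairs outside the FDR family
  off <- run$sims[run$sims$entity_i != run$sims$entity_j, ]
  expect_true(all(abs(off$sim_weighted) <= 1, na.rm = TRUE))
  expect_true(all(off$fdr >= off$p, na.rm = TRUE))
})

test_that("weighted similarity stays in the hull of contributing ranks", {
  run <- planted_run(seed = 9, n_entities = 6)
  off <- run$sims[run$sims$entity_i != run$sims$entity_j, ]
  sim_cols <- paste0("sim_", taxonomic_ranks())
  for (i in seq_len(nrow(off))) {
    sims <- unlist(off[i, sim_cols])
    sims <- sims[!is.na(sims)]
    if (length(sims) == 0) next
    expect_gte(off$sim_weighted[i], min(sims) - 1e-12)
    expect_lte(off$sim_weighted[i], max(sims) + 1e-12)
  }
})

test_that("per-rank cosines are invariant to scaling all evidence counts", {
  counts <- random_counts(5, 8, c("genus", "family"))
  k <- 3L
  scaled <- lapply(counts, function(tab) {
    tab$c_inc <- tab$c_inc * k; tab$c_dec <- tab$c_dec * k; tab
  })
  s1 <- pairwise_similarity(make_mre(counts))
  s2 <- pairwise_similarity(make_mre(scaled))
  for (r in c("genus", "family"))
    expect_equal(s2[[paste0("sim_", r)]], s1[[paste0("sim_", r)]],
                 tolerance = 1e-12)
})

test_that("relabeling entities permutes the similarity matrix identically", {
  set.seed(77)
  counts <- random_counts(5, 8, c("genus", "family", "phylum"))
  M1 <- similarity_matrix(pairwise_similarity(make_mre(counts)))
  relabel <- c(E1 = "Z9", E2 = "Q1", E3 = "M5", E4 = "A2", E5 = "K7")
  counts2 <- lapply(counts, function(tab) {
    tab$entity <- unname(relabel[tab$entity]); tab
  })
  M2 <- similarity_matrix(pairwise_similarity(make_mre(counts2)))
  perm <- unname(relabel[rownames(M1)])
  expect_equal(M2[perm, perm], M1, ignore_attr = TRUE)
})

test_that("cross-set mode compares every A-B pair with its own IDF", {
  cfg <- synth_config(n_entities_a = 5, n_entities_b = 4, n_genera = 12,
                      taxa_per_entity = 6, n_blocks = 2,
                      within_block_agreement = 1,
                      between_block_agreement = 0, conflict_rate = 0,
                      seed = 21)
  syn <- generate_synthetic_data(cfg)
  ev <- as.data.frame(syn$evidence)
  split_ev <- function(set) {
    ents <- syn$truth$entity[syn$truth$set == set]
    out <- ev[ev$entity_name %in% ents, ]
    class(out) <- c("bhwa_evidence", "data.frame")
    propagate_up(out, syn$taxonomy)
  }
  cts_a <- split_ev("a"); cts_b <- split_ev("b")
  sims <- pairwise_similarity(cts_a, cts_b)
  expect_equal(nrow(sims), 5 * 4)
  expect_setequal(unique(sims$entity_i), cts_a$entities)
  expect_setequal(unique(sims$entity_j), cts_b$entities)
  # union vs intersection alignment are both defined; union default
  sims_int <- pairwise_similarity(cts_a, cts_b, align = "intersection")
  expect_equal(nrow(sims_int), 20)
})

test_that("pipeline weighted similarity matches the brute-force oracle", {
  set.seed(1234)
  ranks3 <- c("genus", "family", "phylum")
  n_checked <- 0
  for (trial in 1:60) {
    counts <- random_counts(sample(3:6, 1), sample(4:10, 1), ranks3)
    if (length(counts) == 0) next
    sims <- pairwise_similarity(make_mre(counts))
    off <- sims[sims$entity_i != sims$entity_j, ]
    for (i in seq_len(nrow(off))) {
      o <- oracle_pair(counts, off$entity_i[i], off$entity_j[i])
      if (is.na(o$sim_weighted)) {
        expect_true(is.na(off$sim_weighted[i]))
      } else {
        expect_equal(off$sim_weighted[i], o$sim_weighted,
                     tolerance = 1e-10)
        expect_equal(off$p[i], o$p, tolerance = 1e-10)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})
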