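test_that("propagation is upward-only through the lineage", {
  ev <- make_evidence(ev_row("Inulin", "Lactobacillus", "genus", "increase"))
  cts <- propagate_up(ev, demo_taxonomy())
  # genus evidence reaches genus, family, order, class, phylum; not species
  expect_equal(nrow(cts$counts$species), 0)
  expect_equal(cts$counts$genus$taxon, "Lactobacillus")
  expect_equal(cts$counts$family$taxon, "Lactobacillaceae")
  expect_equal(cts$counts$order$taxon, "Lactobacillales")
  expect_equal(cts$counts$class$taxon, "Bacilli")
  expect_equal(cts$counts$phylum$taxon, "Firmicutes")
  expect_true(all(vapply(cts$counts, function(x)
    all(x$c_inc == 1 & x$c_dec == 0), logical(1))[c("genus", "family",
                                                    "order", "class",
                                                    "phylum")]))
})

test_that("phylum-level reports contribute only at phylum", {
  tax <- make_taxonomy(data.frame(taxon_name = "Firmicutes",
                                  rank = "phylum",
                                  stringsAsFactors = FALSE))
  ev <- make_evidence(ev_row("Inulin", "Firmicutes", "phylum", "decrease"))
  cts <- propagate_up(ev, tax)
  expect_equal(nrow(cts$counts$phylum), 1)
  for (r in setdiff(taxonomic_ranks(), "phylum"))
    expect_equal(nrow(cts$counts[[r]]), 0)
})

test_that("shared lineages merge signed events at the common ancestor", {
  # genus Bacteroides (+) and genus Prevotella (-) share phylum
  # Bacteroidetes: hand propagation gives c_inc = 1, c_dec = 1 there
  ev <- make_evidence(
    ev_row("Pectin", "Bacteroides", "genus", "increase", source = "s1"),
    ev_row("Pectin", "Prevotella", "genus", "decrease", source = "s2"))
  cts <- propagate_up(ev, demo_taxonomy())
  phy <- cts$counts$phylum
  expect_equal(phy$taxon, "Bacteroidetes")
  expect_equal(phy$c_inc, 1L)
  expect_equal(phy$c_dec, 1L)
  # both genera also meet at order Bacteroidales
  expect_equal(cts$counts$order$taxon, "Bacteroidales")
  expect_equal(cts$counts$order$c_inc + cts$counts$order$c_dec, 2L)
})

test_that("species evidence with a partial lineage skips only missing ranks", {
  tax <- make_taxonomy(data.frame(
    taxon_name = "Faecalibacterium prausnitzii", rank = "species",
    genus = "Faecalibacterium", family = NA_character_,
    order = NA_character_, class = "Clostridia", phylum = "Firmicutes",
    stringsAsFactors = FALSE))
  ev <- make_evidence(ev_row("Inulin", "Faecalibacterium prausnitzii",
                             "species", "increase"))
  cts <- propagate_up(ev, tax)
  expect_equal(nrow(cts$counts$species), 1)
  expect_equal(nrow(cts$counts$genus), 1)
  expect_equal(nrow(cts$counts$family), 0)  # missing entry: no event
  expect_equal(nrow(cts$counts$order), 0)
  expect_equal(nrow(cts$counts$class), 1)
  expect_equal(nrow(cts$counts$phylum), 1)
})

test_that("microbe at wrong rank errors; unknown microbe stays at own rank", {
  ev_wrong <- make_evidence(ev_row("Inulin", "Lactobacillus", "family",
                                   "increase"))
  expect_error(propagate_up(ev_wrong, demo_taxonomy()), "rank")
  ev_unknown <- make_evidence(ev_row("Inulin", "Mysterybug", "genus",
                                     "increase"))
  cts <- suppressMessages(propagate_up(ev_unknown, demo_taxonomy()))
  expect_equal(cts$counts$genus$taxon, "Mysterybug")
  expect_equal(nrow(cts$counts$phylum), 0)
})

test_that("event conservation and monotone growth hold on random fixtures", {
  set.seed(42)
  tax <- demo_taxonomy()
  genera <- tax$taxon_name[tax$rank == "genus"]
  rows <- lapply(1:30, function(i)
    ev_row(sample(c("A", "B", "C"), 1), sample(genera, 1), "genus",
           sample(c("increase", "decrease"), 1),
           source = paste0("s", i)))
  ev <- do.call(make_evidence, rows)
  cts <- propagate_up(ev, tax)
  # conservation: each genus row has a full 5-rank lineage, so events
  # at every propagated rank must equal the number of evidence rows
  for (r in c("genus", "family", "order", "class", "phylum"))
    expect_equal(sum(cts$counts[[r]]$c_inc + cts$counts[[r]]$c_dec),
                 nrow(ev))
  # monotonicity: adding one record never decreases any tally
  extra <- do.call(make_evidence,
                   c(rows, list(ev_row("A", genera[1], "genus",
                                       "increase", source = "s31"))))
  cts2 <- propagate_up(extra, tax)
  for (r in taxonomic_ranks()) {
    a <- cts$counts[[r]]; b <- cts2$counts[[r]]
    if (nrow(a) == 0) next
    key_a <- paste(a$entity, a$taxon)
    key_b <- paste(b$entity, b$taxon)
    idx <- match(key_a, key_b)
    expect_true(all(b$c_inc[idx] >= a$c_inc))
    expect_true(all(b$c_dec[idx] >= a$c_dec))
  }
})

test_that("direction counts tally exactly and duplicates collapse once", {
  events <- data.frame(
    entity = rep("A", 4), taxon = rep("Gx", 4), rank = "genus",
    direction = c(1, 1, 1, -1), stringsAsFactors = FALSE)
  out <- aggregate_direction_counts(events)
  expect_equal(out$counts$genus$c_inc, 3L)
  expect_equal(out$counts$genus$c_dec, 1L)
  empty <- aggregate_direction_counts(events[0, ], entities = character(0))
  expect_equal(nrow(empty$counts$genus), 0)
  # exact duplicate evidence rows are removed once before counting
  ev <- as_evidence(rbind(ev_row("A", "Bacteroides", "genus", "increase"),
                          ev_row("A", "Bacteroides", "genus", "increase")))
  cts <- suppressMessages(propagate_up(ev, demo_taxonomy()))
  expect_equal(cts$counts$genus$c_inc, 1L)
})

test_that("min-disturbance filter keeps >= 3 distinct microbes, drops fewer", {
  rows <- list(
    ev_row("Keep3", "Bacteroides", "genus", "increase", source = "k1"),
    ev_row("Keep3", "Prevotella", "genus", "increase", source = "k2"),
    ev_row("Keep3", "Lactobacillus", "genus", "decrease", source = "k3"),
    ev_row("Drop2", "Bacteroides", "genus", "increase", source = "d1"),
    ev_row("Drop2", "OrphanBug", "genus", "increase", source = "d2"),
    ev_row("Drop2", "Bacteroides", "genus", "decrease", source = "d3"))
  ev <- do.call(make_evidence, rows)
  out <- filter_min_disturbance(ev, threshold = 3)
  expect_setequal(unique(out$entity_name), "Keep3")
  expect_equal(attr(out, "removed_entities"), "Drop2")
  # taxa referenced only by removed entities vanish from the universes
  cts <- suppressMessages(propagate_up(out, demo_taxonomy()))
  expect_false("OrphanBug" %in% cts$taxa$genus)
  expect_error(filter_min_disturbance(ev, threshold = 10), "every entity")
})
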