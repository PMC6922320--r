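test_that("capability tables load with dedup, first-appearance order and direction checks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\tmetabolite\tdirection",
    "A\tm1\tconsumption",
    "A\tm2\tproduction",
    "B\tm1\tconsumption",
    "B\tm3\tproduction",
    "B\tm3\tproduction"   # duplicate row
  ), path)
  expect_warning(net <- load_interactions(path), "duplicate")
  expect_s3_class(net, "cross_feeding_network")
  expect_identical(net$species, c("A", "B"))
  expect_identical(net$metabolites, c("m1", "m2", "m3"))
  expect_equal(nrow(net$consumption) + nrow(net$production), 4L)

  # empty table with headers
  writeLines("species\tmetabolite\tdirection", path)
  empty <- load_interactions(path)
  expect_length(empty$species, 0L)
  expect_length(empty$metabolites, 0L)
  expect_equal(nrow(empty$consumption) + nrow(empty$production), 0L)

  # unknown direction token names the offending row
  writeLines(c("species\tmetabolite\tdirection", "A\tm1\teats"), path)
  expect_error(load_interactions(path), "direction")

  # missing required column is a format error
  writeLines(c("species\tmetabolite", "A\tm1"), path)
  expect_error(load_interactions(path), "column")
})

test_that("custom column names and direction tokens are honored", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,compound,type", "A,m1,uptake", "A,m2,secretion"), path)
  net <- load_interactions(
    path,
    col_map = c(species = "taxon", metabolite = "compound", direction = "type"),
    direction_tokens = c(consumption = "uptake", production = "secretion")
  )
  expect_equal(nrow(net$consumption), 1L)
  expect_equal(nrow(net$production), 1L)
})

test_that("load -> write -> load round trip preserves edge sets", {
  net <- random_instance(11)$net
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(net, path)
  net2 <- load_interactions(path)
  key <- function(e) sort(paste(e$species, e$metabolite))
  expect_identical(key(net2$consumption), key(net$consumption))
  expect_identical(key(net2$production), key(net$production))
})

test_that("xlsx dialect reads the same table as the delimited one", {
  skip_if_not_installed("readxl")
  # readxl cannot write xlsx; use its bundled example only to confirm the
  # dialect plumbing errors cleanly on a non-capability sheet
  path <- readxl::readxl_example("datasets.xlsx")
  expect_error(load_interactions(path, dialect = "xlsx"), "column")
})

test_that("filtering removes excluded ids, their edges, and optionally isolated nodes", {
  ia <- data.frame(
    species    = c("A", "A", "B", "B", "C"),
    metabolite = c("ion1", "m1", "ion1", "m2", "ion1"),
    direction  = c("consumption", "production", "consumption",
                   "production", "consumption")
  )
  net <- cross_feeding_network(ia)
  filt <- filter_network(net, exclude_metabolites = "ion1")
  expect_false("ion1" %in% filt$metabolites)
  expect_equal(attr(filt, "filter_report")$edges_removed, 3L)
  # C only interacted with the ion -> isolated and dropped
  expect_identical(filt$species, c("A", "B"))

  keep_iso <- filter_network(net, exclude_metabolites = "ion1",
                             drop_isolated = FALSE)
  expect_true("C" %in% keep_iso$species)

  # empty exclusion is the identity; filtering is idempotent
  same <- filter_network(net, character(), character(), drop_isolated = FALSE)
  expect_identical(same$consumption, net$consumption)
  expect_identical(same$production, net$production)
  twice <- filter_network(filt, "ion1")
  expect_identical(twice$species, filt$species)
  expect_identical(twice$consumption, filt$consumption)

  # excluding an absent id is a no-op, counted in the report
  noop <- filter_network(net, exclude_metabolites = "not-there",
                         drop_isolated = FALSE)
  expect_equal(attr(noop, "filter_report")$absent_ids_ignored, 1L)
  expect_identical(noop$consumption, net$consumption)
})

test_that("synthetic database-scale table reproduces curated counts after filtering", {
  tab <- synthetic_capability_table(seed = 5)
  net <- cross_feeding_network(tab$interactions)
  expect_length(net$species, 570L)     # 567 microbes + 3 host cell types
  expect_length(net$metabolites, 244L) # 235 nutrients + 9 ions
  filt <- filter_network(net, exclude_metabolites = tab$ion_metabolites,
                         exclude_species = tab$host_species)
  expect_length(filt$species, 567L)
  expect_length(filt$metabolites, 235L)
  s <- network_summary(filt)
  expect_equal(s$n_interactions, 4248L)
})

test_that("network_summary counts match stored collections", {
  net <- chain_net()
  s <- network_summary(net)
  expect_equal(s$n_species, 2L)
  expect_equal(s$n_metabolites, 3L)
  expect_equal(s$n_consumption_edges, 2L)
  expect_equal(s$n_production_edges, 2L)
  expect_equal(unname(s$species_in_degree), c(1L, 1L))
  expect_equal(unname(s$metabolite_consumer_degree["m1"]), 1L)

  empty <- cross_feeding_network(
    data.frame(species = character(), metabolite = character(),
               direction = character()))
  se <- network_summary(empty)
  expect_equal(se$n_interactions, 0L)
  expect_equal(se$n_species, 0L)
})

test_that("name normalization unifies case, whitespace and underscores", {
  expect_equal(normalize_name(" Bacteroides_fragilis "),
               "bacteroides fragilis")
  expect_equal(normalize_name("Bacteroides   FRAGILIS"),
               "bacteroides fragilis")
})

test_that("taxon mapping: exact stage, genus fallback, and core-capability rule", {
  ia <- data.frame(
    species    = c("Bacteroides fragilis", "Bacteroides fragilis",
                   "Bacteroides ovatus", "Bacteroides ovatus",
                   "Clostridium a", "Clostridium b", "Clostridium b"),
    metabolite = c("m1", "m2", "m1", "m2", "m1", "m1", "m3"),
    direction  = c("consumption", "production", "consumption", "production",
                   "consumption", "consumption", "consumption")
  )
  net <- cross_feeding_network(ia)

  # exact match (MetaPhlAn-style name)
  res <- map_taxa("Bacteroides_fragilis", net)
  expect_equal(res$report$stage, "exact")
  expect_equal(res$report$mapped_id, "Bacteroides fragilis")

  # congeners share identical capabilities -> new species inherits them
  res2 <- map_taxa("Bacteroides vulgatus", net)
  expect_equal(res2$report$stage, "genus_identical")
  expect_setequal(consumables(res2$network, "Bacteroides vulgatus"), "m1")
  expect_setequal(byproducts(res2$network, "Bacteroides vulgatus"), "m2")

  # congeners differ and genus not flagged -> unmapped
  res3 <- map_taxa("Clostridium c", net)
  expect_equal(res3$report$stage, "unmapped")

  # flagged genus gets the intersection ("core") of capabilities
  res4 <- map_taxa("Clostridium c", net, core_genera = "Clostridium")
  expect_equal(res4$report$stage, "genus_core")
  expect_setequal(consumables(res4$network, "Clostridium c"), "m1")

  # fallback disabled
  res5 <- map_taxa("Bacteroides vulgatus", net, genus_fallback = FALSE)
  expect_equal(res5$report$stage, "unmapped")
})

test_that("mapping coverage is the abundance-weighted mapped fraction in [0, 1]", {
  net <- chain_net()
  obs <- c("A", "B", "unknown sp")
  ab <- c(0.5, 0.3, 0.2)
  res <- map_taxa(obs, net, abundances = ab)
  expect_equal(res$coverage, 0.8)
  expect_gte(res$coverage, 0)
  expect_lte(res$coverage, 1)
  # report is writable
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_report(res, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 3L)
})
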