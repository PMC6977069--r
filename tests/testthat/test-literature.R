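write_lit_csv <- function(rows, envir = parent.frame()) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  hdr <- paste("interaction_raw_label", "diatom_genus", "diatom_species",
               "partner_class", "partner_genus", "partner_species",
               "habitat", "source_ref", sep = ",")
  writeLines(c(hdr, rows), p)
  p
}

test_that("read_litdb normalizes labels and habitats", {
  p <- write_lit_csv(c(
    "eatenBy,Chaetoceros,,Insecta,Baetis,,freshwater,ref1",
    "parasiteOf,Thalassiosira,,Syndiniales,Amoebophrya,,Marine,ref2",
    "symbiontOf,,,Cyanobacteria,Richelia,,,ref3"))
  lit <- read_litdb(p)
  expect_equal(lit$interaction_type,
               c("predation", "parasitism", "symbiosis"))
  expect_equal(lit$habitat, c("freshwater", "marine", "unknown"))
  expect_equal(lit$genus_unresolved, c(FALSE, FALSE, TRUE))
})

test_that("read_litdb rejects unknown labels and malformed rows", {
  p <- write_lit_csv("livesNear,Chaetoceros,,X,Y,,marine,r")
  expect_error(read_litdb(p), "unknown interaction label.*livesNear")
  p2 <- write_lit_csv(",Chaetoceros,,X,Y,,marine,r")
  expect_error(read_litdb(p2), "malformed literature row at line 2")
  p3 <- write_lit_csv("eatenBy,Chaetoceros,,X,Y,,underground,r")
  expect_error(read_litdb(p3), "unknown habitat")
  # empty file -> empty database
  pe <- withr::local_tempfile(fileext = ".csv")
  file.create(pe)
  expect_equal(nrow(read_litdb(pe)), 0)
})

test_that("nonliving-surface records are dropped with a warning", {
  p <- write_lit_csv(c(
    "eatenBy,Chaetoceros,,Insecta,Baetis,,marine,r1",
    "epipsammic,Navicula,,substrate,Sand,,marine,r2",
    "epipelic,Navicula,,substrate,Mud,,marine,r3"))
  expect_warning(lit <- read_litdb(p), "nonliving")
  expect_equal(nrow(lit), 1)
  expect_equal(lit$interaction_type, "predation")
})

test_that("litdb round-trips through the interchange CSV", {
  spec <- small_spec(seed = 2)
  net <- generate_network(spec)$network
  lit <- generate_litdb(spec, net)$records
  p <- withr::local_tempfile(fileext = ".csv")
  write_litdb(lit, p)
  back <- read_litdb(p)
  expect_equal(back$raw_label, lit$raw_label)
  expect_equal(back$diatom_genus, lit$diatom_genus)
  expect_equal(back$partner_genus, lit$partner_genus)
})

test_that("aggregate_hierarchy conserves totals and computes shares", {
  p <- write_lit_csv(c(
    "eatenBy,A,,Insecta,X1,,marine,r",
    "eatenBy,A,,Insecta,X2,,marine,r",
    "eatenBy,B,,Crustacea,X3,,marine,r",
    "parasiteOf,A,,Syndiniales,X4,,marine,r",
    "symbiontOf,C,,Cyanobacteria,X5,,marine,r"))
  lit <- read_litdb(p)
  h <- aggregate_hierarchy(lit, c("interaction_type", "partner_class"))
  top <- h$tables[[1]]
  expect_equal(sum(top$n), 5)
  expect_equal(top$share[top$interaction_type == "predation"], 60)
  leaf <- h$tables[[2]]
  expect_equal(sum(leaf$n), 5)
  # share within parent: insects are 2 of 3 predation records
  ins <- leaf[leaf$partner_class == "Insecta", ]
  expect_equal(ins$share, 200 / 3)
  # single record -> every level count 1
  p1 <- write_lit_csv("eatenBy,A,,Insecta,X,,marine,r")
  h1 <- aggregate_hierarchy(read_litdb(p1),
                            c("interaction_type", "partner_class",
                              "diatom_genus"))
  expect_true(all(vapply(h1$tables, function(t) all(t$n == 1),
                         logical(1))))
  expect_error(aggregate_hierarchy(lit, "no_such_field"), "unknown field")
})

test_that("habitat_summary counts records and deduplicated genera", {
  p <- write_lit_csv(c(
    "eatenBy,A,,I,X1,,freshwater,r",
    "eatenBy,A,,I,X2,,freshwater,r",
    "eatenBy,B,,I,X3,,freshwater,r",
    "parasiteOf,A,,S,X4,,marine,r",
    "symbiontOf,C,,C,X5,,marine,r"))
  lit <- read_litdb(p)
  hs <- habitat_summary(lit)
  expect_equal(hs$n_records[hs$habitat == "freshwater"], 3)
  expect_equal(hs$n_genera[hs$habitat == "freshwater"], 2)
  expect_equal(hs$n_records[hs$habitat == "marine"], 2)
  expect_equal(sum(hs$n_records), nrow(lit))
})

litnet <- function() {
  # diatoms of genera Da, Db, Dc; partners Pa (edged), Pb (edged),
  # Pc (present, no diatom edge)
  ann <- rbind(
    make_annotations(c("d1", "d2", "d3"), "Bacillariophyta",
                     genus = c("Da", "Db", "Dc")),
    make_annotations(c("p1", "p2", "p3"), "Copepoda",
                     genus = c("Pa", "Pb", "Pc")))
  ed <- make_edges(c("d1", "d1", "d2"), c("p1", "p2", "p1"),
                   c(0.5, -0.5, 0.6))
  interaction_network(ann, ed)
}

test_that("compare_litdb_network classifies potential and recovered", {
  net <- litnet()
  p <- write_lit_csv(c(
    "eatenBy,Da,,C,Pa,,marine,r1",     # recovered (edge d1-p1)
    "eatenBy,Db,,C,Pa,,marine,r2",     # recovered (edge d2-p1)
    "eatenBy,Dc,,C,Pc,,marine,r3",     # potential only (no edge)
    "eatenBy,Da,,C,Zz,,marine,r4"))    # partner absent
  lit <- read_litdb(p)
  ov <- compare_litdb_network(lit, net, "Bacillariophyta")
  expect_equal(ov$n_literature, 4)
  expect_equal(ov$n_potential, 3)
  expect_equal(ov$n_recovered, 2)
  expect_equal(ov$pct_recovered_of_potential, 200 / 3)
  expect_equal(ov$n_network_edges_matched, 2)
  expect_equal(ov$pct_of_group_network_edges, 200 / 3)
  expect_equal(nrow(ov$matched_pairs), 2)
  # a recovered record is always potential
  expect_lte(ov$n_recovered, ov$n_potential)
  expect_lte(ov$n_potential, ov$n_literature)
})

test_that("overlap matching is case-insensitive and synonym-aware", {
  net <- litnet()
  net$annotations$genus[net$annotations$genus == "Da"] <- "Proboscia"
  p <- write_lit_csv("eatenBy,rhizosolenia,,C,pa,,marine,r1")
  lit <- read_litdb(p)
  ov <- compare_litdb_network(lit, net, "Bacillariophyta",
                              synonym_map = default_synonym_map())
  expect_equal(ov$n_recovered, 1)
  # without the synonym map the genus never matches
  ov2 <- compare_litdb_network(lit, net, "Bacillariophyta")
  expect_equal(ov2$n_potential, 0)
})

test_that("an empty literature set yields the all-zero report", {
  pe <- withr::local_tempfile(fileext = ".csv")
  file.create(pe)
  ov <- compare_litdb_network(read_litdb(pe), litnet(), "Bacillariophyta")
  expect_equal(ov$n_literature, 0)
  expect_equal(ov$n_potential, 0)
  expect_equal(ov$n_recovered, 0)
  expect_equal(ov$n_network_edges_matched, 0)
})

test_that("genus_disparity merges both sources and flags absences", {
  net <- litnet()
  p <- write_lit_csv(c("eatenBy,Da,,C,Pa,,marine,r1",
                       "eatenBy,Da,,C,Zz,,marine,r2",
                       "eatenBy,Dx,,C,Pa,,marine,r3"))
  lit <- read_litdb(p)
  d <- genus_disparity(lit, net, "Bacillariophyta")
  expect_setequal(d$genus, c("Da", "Db", "Dc", "Dx"))
  expect_equal(d$n_literature[d$genus == "Da"], 2)
  expect_equal(d$n_network_edges[d$genus == "Da"], 2)
  expect_false(d$absent_from_literature[d$genus == "Da"])
  # in the network only -> flagged
  expect_true(d$absent_from_literature[d$genus == "Db"])
  # in the literature only -> zero network edges
  expect_equal(d$n_network_edges[d$genus == "Dx"], 0)
  expect_false(d$absent_from_literature[d$genus == "Dc"])
})
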