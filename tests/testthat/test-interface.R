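test_that("constructed hydrogen-bond geometries are detected per criteria", {
  hb <- make_geometry_fixture("hbond", distance = 2.9, angle = 165)
  bonds <- find_hydrogen_bonds(hb, "A", "B")
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$distance, 2.9, tolerance = 1e-6)
  expect_equal(bonds$angle, 165, tolerance = 1e-6)
  expect_equal(bonds$donor_atom, "N")
  expect_equal(bonds$acceptor_atom, "O")

  far <- make_geometry_fixture("hbond", distance = 4.2, angle = 165)
  expect_equal(nrow(find_hydrogen_bonds(far, "A", "B")), 0L)

  bent <- make_geometry_fixture("hbond", distance = 2.9, angle = 70)
  expect_equal(nrow(find_hydrogen_bonds(bent, "A", "B")), 0L)
})

test_that("hydrophobic contacts respect the distance cutoff", {
  near <- make_geometry_fixture("hydrophobic", distance = 4.0)
  cp <- find_hydrophobic_contacts(near, "A", "B")
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$min_dist, 4.0, tolerance = 1e-6)
  expect_equal(nrow(find_hydrogen_bonds(near, "A", "B")), 0L)

  far <- make_geometry_fixture("hydrophobic", distance = 8.0)
  expect_equal(nrow(find_hydrophobic_contacts(far, "A", "B")), 0L)
})

test_that("distant components bury no area; contact fixtures bury some", {
  none <- make_geometry_fixture("none", distance = 12)
  rep0 <- buried_surface_area(none, "A", "B", n_points = 240)
  expect_equal(rep0$bsa_total, 0, tolerance = 1e-9)

  touching <- make_geometry_fixture("hydrophobic", distance = 4.0)
  rep1 <- buried_surface_area(touching, "A", "B", n_points = 960)
  expect_gt(rep1$bsa_total, 0)
  ## recomposition oracle: BSA from independent compute_sasa calls
  s_ab <- compute_sasa(touching, 1.4, 960)
  s_a <- compute_sasa(select_chains(touching, "A"), 1.4, 960)
  s_b <- compute_sasa(select_chains(touching, "B"), 1.4, 960)
  in_a <- touching$atoms$chain == "A"
  expect_equal(rep1$bsa_total,
               (s_a$total - sum(s_ab$per_atom[in_a])) +
                 (s_b$total - sum(s_ab$per_atom[!in_a])),
               tolerance = 1e-9)
  expect_equal(rep1$interface_area, rep1$bsa_total / 2, tolerance = 1e-12)
})

test_that("BSA is symmetric under component swap and non-negative", {
  for (seed in 1:3) {
    x <- random_toy_structure(n_res_per_chain = 3, spread = 5, seed = seed)
    f <- buried_surface_area(x, "A", "B", n_points = 240)
    g <- buried_surface_area(x, "B", "A", n_points = 240)
    expect_equal(f$bsa_component_a, g$bsa_component_b, tolerance = 1e-9)
    expect_equal(f$bsa_component_b, g$bsa_component_a, tolerance = 1e-9)
    expect_equal(f$bsa_total, g$bsa_total, tolerance = 1e-9)
    expect_gte(f$bsa_component_a, -1e-9)
    expect_gte(f$bsa_component_b, -1e-9)
  }
})

test_that("component validation rejects overlap and unknown chains", {
  x <- make_geometry_fixture("none")
  expect_error(buried_surface_area(x, "A", "A"), "overlap")
  expect_error(buried_surface_area(x, "A", character()), "non-empty")
  expect_error(find_hydrogen_bonds(x, "A", "Z"), "not in structure")
})

test_that("detector agrees with an exhaustive brute-force scan", {
  for (seed in c(2, 5, 11, 17)) {
    x <- random_toy_structure(n_res_per_chain = 4, spread = 5, seed = seed)
    got <- find_hydrogen_bonds(x, "A", "B", max_da_distance = 3.5)
    want <- brute_force_hbonds(x, "A", "B", max_dist = 3.5, min_angle = 90)
    key <- function(d) sort(paste(d$donor_resno, d$donor_atom,
                                  d$acceptor_resno, d$acceptor_atom))
    expect_equal(key(got), key(want), label = paste("seed", seed))
  }
})

test_that("interface_report bundles areas, bonds and contacts; writers work", {
  x <- make_geometry_fixture("hydrophobic", distance = 4.0)
  rep <- interface_report(x, "A", "B", n_points = 240)
  expect_s3_class(rep, "interface_report")
  expect_equal(nrow(rep$hydrophobic_contacts), 1L)
  json <- withr::local_tempfile(fileext = ".json")
  write_interface_report(rep, json, tsv_prefix = sub("\\.json$", "", json))
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$bsa_total, rep$areas$bsa_total, tolerance = 1e-9)
  expect_true(file.exists(paste0(sub("\\.json$", "", json), "_hbonds.tsv")))
})
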