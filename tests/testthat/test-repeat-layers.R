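test_that("layer offsets derive from the printed residue series", {
  sch <- derive_layer_offsets(ankg_layer_lists())
  expect_equal(sch$period, 33L)
  expect_equal(sch$offsets,
               c(phi1 = 0L, phi2 = 5L, rho2 = 8L, rho1 = 31L))
  ## anchoring: phi1 alone fixes the period
  sch1 <- derive_layer_offsets(list(phi1 = c(277, 310, 343, 376, 409, 442)))
  expect_equal(sch1$period, 33L)
  expect_equal(sch1$offsets[["phi1"]], 0L)
})

test_that("inconsistent spacings are rejected with offending layers named", {
  bad <- ankg_layer_lists()
  bad$phi2 <- c(282L, 316L, 348L)   # 316 breaks the arithmetic progression
  expect_error(derive_layer_offsets(bad), "inconsistent spacing")
  expect_error(derive_layer_offsets(list(phi2 = c(1, 34))), "phi1")
})

test_that("explicit frame assignment and labeling", {
  seq99 <- strrep("A", 99)
  fr <- assign_frames(seq99, starts = c(1, 34, 67), period = 33)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$label, c("R1", "R2", "R3"))

  ## paper indexing: fragment numbered from 275, first frame origin 277 = R8
  frag <- strrep("A", 300)
  fr8 <- assign_frames(frag, starts = seq(277, by = 33, length.out = 6),
                       first_index = 8, numbering_start = 275)
  expect_equal(fr8$label[1], "R8")
  expect_equal(fr8$start[1], 277L)

  expect_error(assign_frames(seq99, starts = c(34, 1)), "increasing")
  expect_error(assign_frames(seq99, starts = c(1, 200)), "outside")
})

test_that("motif scan recovers the tiling an exact-string oracle finds", {
  unit <- "LQRAKVDTSGHWLKEYAANMPCFILDVRSTEGQK"  # 34 chars; trim to 33
  unit <- substr(unit, 1, 33)
  s <- strrep(unit, 5)
  fr <- assign_frames(s, period = 33, motif_scan = TRUE)
  ## oracle: exact string-match positions of the unit
  oracle <- as.integer(gregexpr(unit, s, fixed = TRUE)[[1]])
  expect_equal(fr$start, oracle)
  expect_equal(nrow(fr), 5L)
})

test_that("layer extraction returns printed identities and marks absences", {
  fx <- ankg_layer_sequence_synthetic()
  frames <- ankg_r8_frames()
  got <- extract_layers(frames, layer_scheme(), fx$sequence,
                        numbering_start = fx$numbering_start)
  expect_equal(got$aa[got$layer == "phi1"], c("I", "L", "L", "L", "F", "L"))
  expect_equal(got$aa[got$layer == "phi2"], c("V", "C", "M", "V", "I", "V"))
  expect_equal(got$resno[got$layer == "rho1"][1:3], c(308L, 341L, 374L))
  expect_equal(got$aa[got$layer == "rho1"][1:3], c("D", "N", "D"))
  ## printed rho2 residues 318/351/384 sit in frames R9-R11 (offset +8 from
  ## the NEXT frame origin relative to the R8 anchor series)
  expect_equal(got$resno[got$layer == "rho2"][2:4], c(318L, 351L, 384L))
  expect_equal(got$aa[got$layer == "rho2"][2:4], c("R", "Q", "H"))
  ## the sequence ends at 478: frames whose rho1 lies beyond are absent
  short <- substr(fx$sequence, 1, 33 * 2)   # only R8-R9 fully covered
  got2 <- extract_layers(frames, layer_scheme(), short,
                         numbering_start = fx$numbering_start)
  expect_true(any(is.na(got2$aa)))
  expect_false(any(is.na(got2$resno)))
})

test_that("shifting all frames by one period relabels but keeps interior residues", {
  syn <- make_repeat_sequences(n_repeats = 6, seed = 5)
  s <- syn$sequences[[1]]
  f0 <- assign_frames(s, starts = seq(1, by = 33, length.out = 6))
  f1 <- assign_frames(s, starts = seq(34, by = 33, length.out = 5))
  e0 <- extract_layers(f0, layer_scheme(), s)
  e1 <- extract_layers(f1, layer_scheme(), s)
  ## interior repeats: same residue numbers appear with shifted labels
  merged <- merge(e0, e1, by = c("layer", "resno"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$aa.x, merged$aa.y)
})

test_that("frames round-trip through JSON and TSV", {
  fr <- ankg_r8_frames()
  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(protein = "AnkG",
                            frames = as.data.frame(fr)), j,
                       auto_unbox = TRUE)
  back <- read_frames(j)
  expect_equal(back$start, fr$start)
  expect_equal(attr(back, "protein"), "AnkG")
  t <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(fr), t, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_equal(read_frames(t)$start, fr$start)
})
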