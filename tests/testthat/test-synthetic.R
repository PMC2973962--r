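test_that("plant specs validate shift feasibility under nearest rounding", {
  expect_error(plant_spec(4), "at least 5")
  expect_error(plant_spec(5, 150), "\\[0, 100\\]")
  # 3% of a 5-residue helix rounds to zero non-helical positions
  expect_error(plant_spec(5, 3), "infeasible")
  # 97% of a 12-residue helix rounds to all positions
  expect_error(plant_spec(12, 97), "infeasible")
  p <- plant_spec(12, 75)
  expect_equal(p$n_nonhelical, 9L)
  expect_equal(p$realized_shifts, 75)
})

test_that("a planted 75% shift yields 9 non-helical positions out of 12", {
  g <- generate_databases(synthetic_config(list(plant_spec(12, 75))), 5)
  occ_ss <- substring(g$target$chains[[1]]$ss,
                      g$truth$occurrences$target_start,
                      g$truth$occurrences$target_end)
  expect_equal(sum(!is_helical(str2vec(occ_ss))), 9L)
  expect_equal(percent_shift(occ_ss), 75)
})

test_that("identical seeds give byte-identical databases", {
  cfg <- basic_synth_config(n_decoy_query = 2, n_decoy_target = 2)
  g1 <- generate_databases(cfg, 123)
  g2 <- generate_databases(cfg, 123)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_chain_table(g1$query, p1); write_chain_table(g2$query, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  write_chain_table(g1$target, p1); write_chain_table(g2$target, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- generate_databases(cfg, 124)
  expect_false(identical(g1$query$chains[[1]]$sequence,
                         g3$query$chains[[1]]$sequence))
})

test_that("the pipeline recovers every planted shift, bin and class", {
  plants <- lapply(seq(0, 100, by = 10), function(s)
    plant_spec(10, s, group_label = paste0("s", s)))
  plants <- c(plants, list(plant_spec(20, c(5, 35, 85)),
                           plant_spec(8, numeric(0)),
                           plant_spec(10, c(50, 60, 70),
                                      shift_mode = "scattered")))
  g <- generate_databases(synthetic_config(plants, n_decoy_query = 2,
                                           n_decoy_target = 3), 99)
  h <- extract_all_helices(g$query)
  occ <- map_all(h, g$target)
  rec <- ambivalency_records(h, occ)
  truth <- g$truth$helices
  rec <- rec[match(truth$helix_id, rec$helix_id), ]
  expect_equal(rec$n_occurrences, truth$n_occurrences)
  expect_equal(rec$max_shift, truth$max_shift)
  expect_equal(rec$bin, truth$bin)
  expect_equal(rec$klass, truth$klass)
  # per-occurrence shifts match the plant exactly
  occ$shift <- percent_shift(occ$target_ss)
  key <- paste(g$truth$occurrences$target_structure_id,
               g$truth$occurrences$target_start)
  okey <- paste(occ$target_structure_id, occ$target_start)
  expect_setequal(okey, key)
  expect_equal(occ$shift[match(key, okey)],
               g$truth$occurrences$planted_shift)
})

test_that("zero-occurrence plants stay unmapped downstream", {
  g <- generate_databases(synthetic_config(list(
    plant_spec(8, numeric(0)), plant_spec(10, 0))), 17)
  h <- extract_all_helices(g$query)
  occ <- map_all(h, g$target)
  rec <- ambivalency_records(h, occ)
  expect_equal(sort(rec$klass), c("CONSERVED", "UNMAPPED"))
  expect_equal(rec$n_occurrences[rec$klass == "UNMAPPED"], 0L)
})

test_that("the collision scan confirms planted occurrence counts", {
  g <- generate_databases(basic_synth_config(n_decoy_target = 3), 55)
  report <- verify_no_collisions(g$query, g$target, g$truth$helices)
  expect_true(all(report$ok))
  expect_equal(report$found_target[order(report$sequence)],
               report$expected_target[order(report$sequence)])
  empty <- verify_no_collisions(g$query, g$target,
                                g$truth$helices[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("adversarial homopolymer plants exhaust the retry budget", {
  cfg <- synthetic_config(list(
    plant_spec(5, 0, residue_bias = c(A = 1e6))),
    context_bias = c(A = 1e6), max_tries = 3)
  expect_error(generate_databases(cfg, 9), "retry budget")
})

test_that("scop_fold_match drives the planted concordance labels", {
  g <- generate_databases(synthetic_config(list(
    plant_spec(10, c(0, 0, 0, 0), scop_fold_match = c(TRUE, FALSE, FALSE,
                                                      FALSE)))), 31)
  h <- extract_all_helices(g$query)
  occ <- map_all(h, g$target)
  rec <- ambivalency_records(h, occ, g$query, g$target)
  expect_equal(rec$same_fold_fraction, 0.25)
  expect_equal(rec$same_domain_fraction, 0.25)
})
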