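test_that("conformational parameters follow the frequency-ratio definition", {
  bg <- residue_counts(strrep(paste(AA_STANDARD, collapse = ""), 5))
  # group proportional to background -> every parameter is 1
  grp <- residue_counts(paste(AA_STANDARD, collapse = ""))
  pt <- compute_cp(grp, bg)
  expect_equal(unname(pt$cp), rep(1, 20))

  # 2 Ala among 10 group residues against a background with f(A) = 0.10:
  # CP(A) = (2/10) / 0.10 = 2
  bg2 <- residue_counts(c(strrep("A", 10), strrep("C", 30), strrep("D", 30),
                          strrep("E", 30)))
  grp2 <- residue_counts("AACCCDDDEE")
  expect_equal(compute_cp(grp2, bg2)$cp[["A"]], 2.0)
  expect_error(compute_cp(residue_counts("XX"), bg2), "empty residue group")
})

test_that("a random multinomial group matches a direct evaluation", {
  set.seed(97)
  bg_seq <- random_aa_string(5000)
  grp_seq <- random_aa_string(500)
  pt <- compute_cp(residue_counts(grp_seq), residue_counts(bg_seq))
  # independent arithmetic straight from the definition
  n_ij <- table(factor(str2vec(grp_seq), levels = AA_STANDARD))
  N_i <- table(factor(str2vec(bg_seq), levels = AA_STANDARD))
  expected <- (n_ij / sum(n_ij)) / (N_i / sum(N_i))
  expected[N_i == 0] <- NA
  expect_equal(unname(pt$cp), as.numeric(expected))
})

test_that("the background-weighted sum of every table is one", {
  set.seed(5)
  for (rep in 1:20) {
    pt <- compute_cp(residue_counts(random_aa_string(50)),
                     residue_counts(random_aa_string(2000)))
    expect_equal(cp_normalization(pt), 1, tolerance = 1e-9)
  }
})

test_that("parameters are invariant under scaling of the group counts", {
  grp <- residue_counts("AAACCD")
  bg <- residue_counts(random_aa_string(1000))
  scaled <- grp
  scaled$counts <- scaled$counts * 7L
  scaled$total <- scaled$total * 7L
  expect_equal(compute_cp(scaled, bg)$cp, compute_cp(grp, bg)$cp)
})

test_that("amino acids absent from the background get an absent parameter", {
  bg <- residue_counts("CCDDEE")      # no Ala in the background
  pt <- compute_cp(residue_counts("ACDE"), bg)
  expect_true(is.na(pt$cp[["A"]]))
  expect_false(any(is.infinite(pt$cp), na.rm = TRUE))
})

test_that("per-bin tables pool the helix sequences of each bin", {
  h <- rbind(helix_row("AAAAA", structure_id = "1AAA"),
             helix_row("CCCCC", structure_id = "1BBB"),
             helix_row("GGGGG", structure_id = "1CCC"))
  rec <- data.frame(helix_id = h$helix_id, length = 5L,
                    n_occurrences = c(1L, 1L, 0L),
                    max_shift = c(0, 40, NA), bin = c(0L, 40L, NA),
                    klass = c("CONSERVED", "PARTIAL", "UNMAPPED"),
                    stringsAsFactors = FALSE)
  bg <- residue_counts("AAAAACCCCCGGGGGWWWWW")
  bins <- cp_by_bin(rec, h, bg)
  expect_setequal(names(bins), c("0", "40"))
  # each occupied bin holds exactly that helix's composition
  expect_equal(bins[["0"]]$group_counts$counts[["A"]], 5L)
  expect_equal(bins[["0"]]$cp[["A"]], 4)   # (5/5) / (5/20)
  expect_equal(bins[["40"]]$group_counts$counts[["C"]], 5L)
})

test_that("flanks truncate at chain boundaries and preserve chain order", {
  chain <- make_chain(paste(rep(AA_STANDARD, 2), collapse = ""),
                      strrep("-", 40))
  # helix at 10-20: N-flank = residues 6-9, C-flank = residues 21-24
  expect_equal(extract_flanks(chain, 10, 20, terminus = "N"),
               substr(chain$sequence, 6, 9))
  expect_equal(extract_flanks(chain, 10, 20, terminus = "C"),
               substr(chain$sequence, 21, 24))
  # helix starting at position 3 has a 2-residue N-flank
  expect_equal(nchar(extract_flanks(chain, 3, 20, terminus = "N")), 2L)
  # helix ending at the chain end has an empty C-flank
  expect_equal(extract_flanks(chain, 30, 40, terminus = "C"), "")
  expect_equal(extract_flanks(chain, 1, 40, terminus = "N"), "")
  expect_error(extract_flanks(chain, 0, 10, terminus = "N"), "outside")
})

test_that("flank propensities recover a planted C-terminal Gly enrichment", {
  plants <- c(
    replicate(60, plant_spec(10, 100, group_label = "var",
                             c_flank_bias = c(G = 12)), simplify = FALSE),
    replicate(20, plant_spec(10, 0, group_label = "cons"),
              simplify = FALSE))
  g <- generate_databases(synthetic_config(plants), 202)
  h <- extract_all_helices(g$query)
  occ <- map_all(h, g$target)
  rec <- ambivalency_records(h, occ)
  fl <- collect_flanks(rec, h, occ, g$query, g$target)
  tabs <- flank_cp(fl, background_counts(g$query))
  expect_setequal(names(tabs),
                  c("N:HELICAL_CONF", "C:HELICAL_CONF", "N:NONHELICAL_CONF",
                    "C:NONHELICAL_CONF", "N:CONSERVED", "C:CONSERVED"))
  expect_gt(tabs[["C:HELICAL_CONF"]]$cp[["G"]],
            2 * tabs[["N:HELICAL_CONF"]]$cp[["G"]])
  expect_gt(tabs[["C:NONHELICAL_CONF"]]$cp[["G"]],
            2 * tabs[["N:NONHELICAL_CONF"]]$cp[["G"]])
  for (pt in tabs) expect_equal(cp_normalization(pt), 1, tolerance = 1e-9)
})

test_that("identical N and C flank populations give identical tables", {
  fl <- data.frame(helix_id = "h", terminus = rep(c("N", "C"), each = 2),
                   source_class = "CONSERVED", structure_id = "1AAA",
                   chain_id = "A", flank_start = 1L, flank_end = 4L,
                   flank_seq = c("ACDE", "GGKL", "ACDE", "GGKL"),
                   stringsAsFactors = FALSE)
  tabs <- flank_cp(fl, residue_counts(random_aa_string(400)))
  expect_equal(tabs[["N:CONSERVED"]]$cp, tabs[["C:CONSERVED"]]$cp)
  expect_equal(length(flank_cp(fl[0, ], residue_counts("AAAA"))), 0L)
})
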