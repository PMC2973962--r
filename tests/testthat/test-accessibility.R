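test_that("the built-in Gly-X-Gly table covers all 20 residues", {
  tab <- max_acc_gxg()
  expect_setequal(names(tab), AA_STANDARD)
  expect_true(all(tab > 0))
})

test_that("a user table round-trips and is validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- max_acc_gxg()
  writeLines(c("# custom maxima",
               paste(names(tab), tab, sep = "\t")), path)
  expect_equal(read_max_acc(path), tab)
  writeLines(paste(names(tab)[-1], tab[-1], sep = "\t"), path)
  expect_error(read_max_acc(path), "lacks residue")
})

test_that("relative accessibility normalizes, caps and skips X", {
  tab <- max_acc_gxg()
  expect_equal(as.numeric(normalize_acc("A", tab[["A"]])), 1.0)
  expect_equal(as.numeric(normalize_acc("G", 0)), 0.0)
  expect_true(is.na(normalize_acc("X", 10)))
  expect_error(normalize_acc("Z", 10), "unknown residue")
  expect_error(normalize_acc("A", -1), "negative")

  # values above the tripeptide maximum cap at 1 and the capped count is
  # reported; the count must match a brute-force tally
  set.seed(8)
  res <- sample(AA_STANDARD, 200, replace = TRUE)
  acc <- runif(200, 0, 1.3) * tab[res]
  rsa <- normalize_acc(res, acc)
  expect_true(all(rsa <= 1 & rsa >= 0))
  expect_equal(attr(rsa, "n_capped"), sum(acc / tab[res] > 1))
})

test_that("flank mean RSA equals the arithmetic mean of per-residue ratios", {
  tab <- max_acc_gxg()
  chain <- make_chain("AGCAX", "-----",
                      acc = c(0.2 * tab[["A"]], 0.6 * tab[["G"]],
                              0.4 * tab[["C"]], 0, 50))
  expect_equal(flank_mean_rsa(chain, 1, 2), 0.4)
  expect_equal(flank_mean_rsa(chain, 4, 4), 0.0)
  expect_equal(flank_mean_rsa(chain, 1, 4), mean(c(0.2, 0.6, 0.4, 0)))
  # X residues are skipped; an all-X window has no usable residue
  expect_equal(flank_mean_rsa(chain, 4, 5), 0.0)
  expect_true(is.na(flank_mean_rsa(chain, 5, 5)))
  # chains without accessibility yield NA
  expect_true(is.na(flank_mean_rsa(make_chain("AAAA", "----"), 1, 2)))

  set.seed(12)
  res <- sample(AA_STANDARD, 30, replace = TRUE)
  acc <- runif(30, 0, 1) * tab[res]
  rchain <- make_chain(paste(res, collapse = ""), strrep("-", 30), acc = acc)
  expect_equal(flank_mean_rsa(rchain, 5, 14),
               mean((acc / tab[res])[5:14]))
})

test_that("scaling accessibilities down never increases a flank mean", {
  set.seed(31)
  tab <- max_acc_gxg()
  res <- sample(AA_STANDARD, 40, replace = TRUE)
  acc <- runif(40, 0, 1.2) * tab[res]
  chain1 <- make_chain(paste(res, collapse = ""), strrep("-", 40), acc = acc)
  chain2 <- make_chain(paste(res, collapse = ""), strrep("-", 40),
                       acc = 0.6 * acc)
  for (w in list(c(1, 10), c(11, 25), c(26, 40)))
    expect_lte(flank_mean_rsa(chain2, w[1], w[2]),
               flank_mean_rsa(chain1, w[1], w[2]))
})

test_that("RSA histograms are per-class fractions summing to one", {
  fl <- data.frame(
    helix_id = "h", terminus = rep(c("N", "C"), each = 6),
    source_class = "HELICAL_CONF", structure_id = "1AAA", chain_id = "A",
    flank_start = 1L, flank_end = 4L, flank_seq = "AAAA",
    mean_rsa = c(0.05, 0.15, 0.15, 0.98, 0.5, NA,
                 rep(0.35, 6)),
    stringsAsFactors = FALSE)
  hist <- rsa_distribution(fl)
  n_strat <- split(hist$fraction, paste(hist$terminus, hist$source_class))
  for (fr in n_strat) expect_equal(sum(fr), 1, tolerance = 1e-12)
  cbin <- hist[hist$terminus == "C" & abs(hist$bin_lo - 0.3) < 1e-9, ]
  expect_equal(cbin$fraction, 1)           # all C means in one bin
  nbin <- hist[hist$terminus == "N", ]
  expect_equal(sum(nbin$n), 5L)            # NA flank dropped
  expect_equal(nrow(rsa_distribution(fl[0, ])), 0L)
})

test_that("planted N/C accessibility anisotropy shows in the histograms", {
  plants <- replicate(40, plant_spec(10, 100, group_label = "var"),
                      simplify = FALSE)
  cfg <- synthetic_config(plants,
                          acc_beta = list(helix = c(1.5, 4), coil = c(2, 2),
                                          n_flank = c(8, 2),   # exposed
                                          c_flank = c(2, 8)))  # buried
  g <- generate_databases(cfg, 77)
  h <- extract_all_helices(g$query)
  occ <- map_all(h, g$target)
  rec <- ambivalency_records(h, occ)
  fl <- collect_flanks(rec, h, occ, g$query, g$target)
  fl <- flank_rsa_means(fl, g$query, g$target)
  n_mean <- mean(fl$mean_rsa[fl$terminus == "N"], na.rm = TRUE)
  c_mean <- mean(fl$mean_rsa[fl$terminus == "C"], na.rm = TRUE)
  expect_gt(n_mean, c_mean + 0.3)   # Beta(8,2) vs Beta(2,8): means 0.8/0.2
})
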