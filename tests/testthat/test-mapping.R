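test_that("an identical fragment is mapped at its printed target window", {
  # TSELLRCLGEFLCRR occupies 148-162 of the target chain
  frag <- "TSELLRCLGEFLCRR"
  target_seq <- paste0(strrep("A", 147), frag, strrep("A", 8))
  target <- make_chain(target_seq, ss_with_helices(170, list(c(148, 162))),
                       structure_id = "1UNG", chain_id = "E")
  helix <- helix_row(frag, structure_id = "1H4L", chain_id = "D",
                     start = 148)
  occ <- map_helix_naive(helix, target)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$target_start, 148L)
  expect_equal(occ$target_end, 162L)
  expect_equal(occ$target_ss, strrep("H", 15))
})

test_that("overlapping occurrences are all reported in order", {
  target <- make_chain("AAAAAAA", "HHHHHHH")
  occ <- map_helix_naive(helix_row("AAAAA"), target)
  expect_equal(occ$target_start, c(1L, 2L, 3L))
  idx <- build_target_index(chain_db(list(target), name = "t"))
  expect_equal(map_helix_fast(helix_row("AAAAA"), idx)$target_start,
               c(1L, 2L, 3L))
})

test_that("absent sequences yield no occurrence and X helices are refused", {
  target <- make_chain("MKLVAMKLVA", strrep("-", 10))
  expect_equal(nrow(map_helix_naive(helix_row("WWWWW"), target)), 0L)
  expect_error(map_helix_naive(helix_row("AXAAA"), target), "'X'")
  idx <- build_target_index(chain_db(list(target), name = "t"))
  expect_error(map_helix_fast(helix_row("AXAAA"), idx), "'X'")
})

test_that("a helix spanning an entire chain maps once", {
  target <- make_chain("MKLVA", "HHHHH")
  idx <- build_target_index(chain_db(list(target), name = "t"))
  occ <- map_helix_fast(helix_row("MKLVA"), idx)
  expect_equal(c(occ$target_start, occ$target_end), c(1L, 5L))
})

test_that("fast and naive mappers agree with a textbook matcher", {
  set.seed(7)
  for (rep in 1:200) {
    k <- sample(2:20, 1)
    alphabet <- AA_STANDARD[seq_len(k)]
    N <- sample(5:40, 1)
    M <- sample(20:200, 1)
    hx <- helix_row(random_aa_string(N, alphabet))
    target <- make_chain(random_aa_string(M, alphabet), random_ss_string(M),
                         structure_id = "1TGT")
    naive <- map_helix_naive(hx, target)
    idx <- build_target_index(chain_db(list(target), name = "t"))
    fast <- map_helix_fast(hx, idx)
    expect_equal(fast$target_start, naive$target_start)
    expect_equal(fast$target_ss, naive$target_ss)
    expect_equal(naive$target_start,
                 regex_match_starts(hx$sequence, target$sequence))
  }
})

test_that("every reported occurrence is an exact substring match", {
  set.seed(21)
  for (rep in 1:40) {
    hx <- helix_row(random_aa_string(5, AA_STANDARD[1:3]))
    target <- make_chain(random_aa_string(60, AA_STANDARD[1:3]),
                         random_ss_string(60), structure_id = "1TGT")
    occ <- map_helix_naive(hx, target)
    for (i in seq_len(nrow(occ)))
      expect_identical(substr(target$sequence, occ$target_start[i],
                              occ$target_end[i]), hx$sequence)
  }
})

test_that("database occurrences add over chains and respect exclude_self", {
  chains <- list(
    make_chain("GGMKLVAGG", strrep("-", 9), structure_id = "1TG1"),
    make_chain("MKLVAMKLVA", strrep("-", 10), structure_id = "1TG2"),
    make_chain("GGGGGGG", strrep("-", 7), structure_id = "1TG3"),
    make_chain("AAMKLVA", strrep("-", 7), structure_id = "1QRY"))
  db <- chain_db(chains, name = "t", role = "TARGET")
  hx <- helix_row("MKLVA", structure_id = "1QRY")

  per_chain <- vapply(chains, function(ch)
    nrow(map_helix_naive(hx, ch)), integer(1))
  all_occ <- map_all(hx, db, exclude_self = FALSE)
  expect_equal(nrow(all_occ), sum(per_chain))

  excl <- map_all(hx, db, exclude_self = TRUE)
  expect_false("1QRY" %in% excl$target_structure_id)
  expect_equal(nrow(excl), sum(per_chain) - 1L)

  # helices with X are skipped rather than mapped
  hx_x <- helix_row("MKXVA", structure_id = "1QRY")
  expect_equal(nrow(map_all(rbind(hx, hx_x), db)), nrow(excl))

  # naive and fast database-level routes coincide
  expect_equal(map_all(hx, db, method = "naive")$target_start,
               excl$target_start)
})

test_that("self-mapping a helix against its own database is exact identity", {
  chain <- make_chain(paste0("GG", "MKLVAHW", "GG"),
                      ss_with_helices(11, list(c(3, 9))),
                      structure_id = "1SLF")
  db <- chain_db(list(chain), name = "q")
  h <- extract_all_helices(db)
  occ <- map_all(h, db, exclude_self = FALSE)
  expect_equal(occ$target_start, h$start)
  expect_equal(percent_shift(occ$target_ss), 0)
})
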