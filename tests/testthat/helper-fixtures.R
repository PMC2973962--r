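# Shared fixture builders; everything is generated in code at test time.

make_chain <- function(sequence, ss, acc = NULL, structure_id = "1ABC",
                       chain_id = "A", method = "XRAY", resolution = 2.0,
                       r_factor = 0.2, ...) {
  chain_record(structure_id, chain_id, sequence, ss, acc = acc,
               method = method, resolution = resolution,
               r_factor = r_factor, ...)
}

# ss string with helical runs (H) at the given 1-based inclusive ranges
ss_with_helices <- function(len, ranges, helix_code = "H", coil_code = "-") {
  ss <- rep(coil_code, len)
  for (r in ranges) ss[r[1]:r[2]] <- helix_code
  paste(ss, collapse = "")
}

# one-row helix table as extract_helices() would produce it
helix_row <- function(sequence, structure_id = "1QRY", chain_id = "A",
                      start = 1L, source_db = "query") {
  end <- start + nchar(sequence) - 1L
  data.frame(
    helix_id = sprintf("%s_%s|%d-%d", structure_id, chain_id, start, end),
    structure_id = structure_id, chain_id = chain_id,
    start = as.integer(start), end = as.integer(end),
    length = nchar(sequence), sequence = sequence,
    has_x = grepl("X", sequence, fixed = TRUE), source_db = source_db,
    stringsAsFactors = FALSE)
}

# classic DSSP text; rows is a data.frame with columns chain, aa, ss, acc
# (aa == "!" marks a chain-break row)
make_dssp_text <- function(rows, structure_id = "1ABC") {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    sprintf("HEADER    TEST PROTEIN                            01-JAN-10   %s",
            structure_id),
    "  119  1  0  0  0 TOTAL NUMBER OF RESIDUES ...",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    ",
           "O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$aa == "!")
      return(sprintf("%5d      %1s %1s", i, " ", "!"))
    sprintf("%5d%5d %1s %1s  %1s%s%4d", i, i, r$chain, r$aa, r$ss,
            strrep(" ", 17), as.integer(r$acc))
  }, character(1))
  c(header, body)
}

dssp_rows <- function(chain, aa, ss, acc = 50) {
  data.frame(chain = chain, aa = aa, ss = ss, acc = acc,
             stringsAsFactors = FALSE)
}

# small database pair with one planted helix per spec, used across tests
basic_synth_config <- function(...) {
  synthetic_config(list(
    plant_spec(12, 75, group_label = "partial"),
    plant_spec(10, c(0, 0), group_label = "conserved"),
    plant_spec(10, c(50, 60, 70), group_label = "multi"),
    plant_spec(10, 100, group_label = "variable"),
    plant_spec(8, numeric(0), group_label = "unmapped")), ...)
}

str2vec <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

random_aa_string <- function(n, alphabet = AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_ss_string <- function(n) {
  paste(sample(DSSP_CODES, n, replace = TRUE), collapse = "")
}

# third, textbook route for exact substring positions (regex lookahead)
regex_match_starts <- function(pattern, subject) {
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
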