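#' Helical/non-helical binarization of DSSP codes
#'
#' `H` (alpha-helix) and `G` (3-10 helix) count as helical; all other
#' 8-state codes (`B, E, I, S, T, -`) as non-helical.
#'
#' @param ss_code Character vector of single 8-state codes.
#' @return Logical vector.
#' @examples
#' is_helical(c("H", "G", "I", "E"))
#' @export
is_helical <- function(ss_code) {
  bad <- setdiff(unique(ss_code), DSSP_CODES)
  if (length(bad))
    stop("unknown secondary-structure code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  ss_code %in% HELICAL_CODES
}

#' Extract helix segments from one chain
#'
#' Finds maximal runs of helical codes (binarization precedes run-finding,
#' so a run mixing `H` and `G` is a single helix) and keeps those of at
#' least `min_length` residues. Positions are 1-based inclusive. Helices
#' containing nonstandard residues (`X`) are extracted but flagged via
#' `has_x`; they can never be mapped (exact matching excludes `X`) and are
#' excluded from propensity counts downstream.
#'
#' @param chain A `chain_record`.
#' @param min_length Minimum helix length in residues (default 5).
#' @param source_db Name recorded in the `source_db` column.
#' @return Data frame with columns `helix_id`, `structure_id`, `chain_id`,
#'   `start`, `end`, `length`, `sequence`, `has_x`, `source_db`; zero rows
#'   when the chain has no qualifying helix.
#' @export
extract_helices <- function(chain, min_length = 5L, source_db = "query") {
  hel <- is_helical(str_chars(chain$ss))
  r <- rle(hel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  starts <- starts[keep]; ends <- ends[keep]
  seqs <- if (length(starts)) substring(chain$sequence, starts, ends)
          else character(0)
  data.frame(
    helix_id = sprintf("%s_%s|%d-%d", chain$structure_id, chain$chain_id,
                       starts, ends),
    structure_id = rep(chain$structure_id, length(starts)),
    chain_id = rep(chain$chain_id, length(starts)),
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    sequence = seqs,
    has_x = grepl("X", seqs, fixed = TRUE),
    source_db = rep(source_db, length(starts)),
    stringsAsFactors = FALSE)
}

#' Extract helices from every chain of a database
#'
#' @param db A `chain_db`.
#' @param min_length Minimum helix length (default 5).
#' @return Row-bound helix table (see [extract_helices()]), ordered by chain
#'   then start position.
#' @export
extract_all_helices <- function(db, min_length = 5L) {
  parts <- lapply(db$chains, extract_helices, min_length = min_length,
                  source_db = db$name)
  empty <- extract_helices(chain_record("0XXX", "A", "A", "-"),
                           min_length = 1L, source_db = db$name)
  do.call(rbind, c(list(empty), parts, list(make.row.names = FALSE)))
}

#' Write a helix table as TSV
#'
#' @param helices Helix table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_table <- function(helices, path) {
  utils::write.table(helices, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
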