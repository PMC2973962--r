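#' Maximum solvent accessibility in a Gly-X-Gly tripeptide
#'
#' Per-residue maximum accessible surface areas (A^2) of residue X in an
#' extended Gly-X-Gly tripeptide, used to turn DSSP's absolute
#' accessibilities into relative solvent accessibility (RSA). The default
#' values are the tripeptide maxima of Miller, Janin, Lesk & Chothia (1987)
#' J Mol Biol 196:641-656; a user-supplied table may replace them via
#' [read_max_acc()].
#'
#' @return Named numeric vector over the 20 standard amino acids (A^2).
#' @export
max_acc_gxg <- function() {
  c(A = 113, C = 140, D = 151, E = 183, F = 218, G = 85, H = 194,
    I = 182, K = 211, L = 180, M = 204, N = 158, P = 143, Q = 189,
    R = 241, S = 122, T = 146, V = 160, W = 259, Y = 229)
}

#' Read a maximum-accessibility table
#'
#' Two-column TSV (`#` comments allowed): one-letter residue code and the
#' maximum accessibility in A^2. All 20 standard residues must be present
#' with positive values.
#'
#' @param path Path to the table.
#' @return Named numeric vector over the 20 standard letters.
#' @export
read_max_acc <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("aa", "max_acc"),
                           stringsAsFactors = FALSE)
  vals <- tab$max_acc
  names(vals) <- toupper(tab$aa)
  missing <- setdiff(AA_STANDARD, names(vals))
  if (length(missing))
    stop("max-accessibility table lacks residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(vals[AA_STANDARD] <= 0))
    stop("max-accessibility values must be positive", call. = FALSE)
  vals[AA_STANDARD]
}

#' Relative solvent accessibility of residues
#'
#' Divides an absolute accessibility by the residue's Gly-X-Gly maximum,
#' capping at 1 (DSSP occasionally reports areas above the tripeptide
#' maximum). Nonstandard residues (`"X"`) yield `NA`. The number of capped
#' values is attached as attribute `"n_capped"`.
#'
#' @param residue Character vector of one-letter codes.
#' @param acc Numeric vector of non-negative absolute accessibilities (A^2).
#' @param table Maximum-accessibility table (default [max_acc_gxg()]).
#' @return Numeric vector of RSA values in `[0, 1]` (`NA` for `"X"`), with
#'   attribute `n_capped`.
#' @export
normalize_acc <- function(residue, acc, table = max_acc_gxg()) {
  stopifnot(length(residue) == length(acc))
  bad <- setdiff(unique(residue), c(AA_STANDARD, "X"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(acc < 0, na.rm = TRUE))
    stop("negative accessibility", call. = FALSE)
  rsa <- ifelse(residue == "X", NA_real_, acc / table[residue])
  n_capped <- sum(rsa > 1, na.rm = TRUE)
  rsa <- pmin(rsa, 1)
  attr(rsa, "n_capped") <- n_capped
  rsa
}

#' Mean relative accessibility over a chain segment
#'
#' Averages the normalized accessibilities of the residues in
#' `[start, end]`; nonstandard residues are skipped. Returns `NA` when the
#' chain carries no accessibility vector or no usable residue remains.
#'
#' @param chain A `chain_record` (with `acc`).
#' @param start,end 1-based inclusive segment coordinates.
#' @param table Maximum-accessibility table.
#' @return Mean RSA in `[0, 1]`, or `NA`.
#' @export
flank_mean_rsa <- function(chain, start, end, table = max_acc_gxg()) {
  if (is.null(chain$acc)) return(NA_real_)
  if (start < 1L || end > nchar(chain$sequence) || start > end)
    stop("segment ", start, "-", end, " outside chain ",
         chain_key(chain), call. = FALSE)
  res <- str_chars(substr(chain$sequence, start, end))
  rsa <- normalize_acc(res, chain$acc[start:end], table)
  if (all(is.na(rsa))) return(NA_real_)
  mean(rsa, na.rm = TRUE)
}

#' Mean flank RSA per collected flank
#'
#' Computes the average relative accessibility of every flank in a
#' [collect_flanks()] table, looking the residues up in the corresponding
#' database chains.
#'
#' @param flanks Flank table.
#' @param query_db,target_db `chain_db`s holding the flanked chains.
#' @param table Maximum-accessibility table.
#' @return The flank table with an added `mean_rsa` column (`NA` where no
#'   accessibility is available).
#' @export
flank_rsa_means <- function(flanks, query_db, target_db,
                            table = max_acc_gxg()) {
  qkeys <- chain_keys(query_db)
  means <- vapply(seq_len(nrow(flanks)), function(i) {
    key <- paste0(flanks$structure_id[i], "_", flanks$chain_id[i])
    db <- if (key %in% qkeys) query_db else target_db
    flank_mean_rsa(get_chain(db, key), flanks$flank_start[i],
                   flanks$flank_end[i], table)
  }, numeric(1))
  flanks$mean_rsa <- means
  flanks
}

#' Distribution of flank mean accessibilities
#'
#' Histograms the per-flank mean RSA values over `[0, 1]` separately for
#' each `(terminus, source_class)` stratum; fractions within a stratum sum
#' to 1. Bins are right-closed (`(lo, hi]`) with the first bin closed at 0.
#'
#' @param flanks Flank table with `mean_rsa` (see [flank_rsa_means()]).
#' @param bin_width Histogram bin width (default 0.1).
#' @return Data frame with columns `terminus`, `source_class`, `bin_lo`,
#'   `bin_hi`, `n`, `fraction`; strata with no usable flank are absent.
#' @export
rsa_distribution <- function(flanks, bin_width = 0.1) {
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  usable <- flanks[!is.na(flanks$mean_rsa), , drop = FALSE]
  out <- list()
  strata <- split(usable$mean_rsa,
                  paste(usable$terminus, usable$source_class, sep = ":"))
  for (nm in names(strata)) {
    v <- strata[[nm]]
    if (!length(v)) next
    cls <- cut(v, breaks = breaks, right = TRUE, include.lowest = TRUE)
    counts <- as.integer(table(cls))
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    out[[nm]] <- data.frame(
      terminus = parts[1L], source_class = parts[2L],
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
      n = counts, fraction = counts / length(v),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE))) else NULL
  if (is.null(res))
    res <- data.frame(terminus = character(0), source_class = character(0),
                      bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), fraction = numeric(0))
  res
}
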