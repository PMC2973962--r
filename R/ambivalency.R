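#' Percentage conformational shift of mapped occurrences
#'
#' For an occurrence of a (fully helical) query helix, the conformational
#' shift is the percentage of its positions annotated non-helical in the
#' target chain: `100 * (# positions with a non-helical code) / N`. Only the
#' helical/non-helical binarization matters; which of the non-helical codes
#' appears is irrelevant.
#'
#' @param target_ss Character vector of 8-state code strings, one per
#'   occurrence (the `target_ss` column of an occurrence table).
#' @return Numeric vector of shifts in `[0, 100]`.
#' @examples
#' percent_shift(c("HHHH", "HHT-", "EEEE"))  # 0, 50, 100
#' @export
percent_shift <- function(target_ss) {
  vapply(target_ss, function(ss) {
    codes <- str_chars(ss)
    100 * sum(!is_helical(codes)) / length(codes)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decade bin of a helix's conformational shifts
#'
#' A helix with several mapped occurrences is placed in the highest decade
#' bin reached by any of its shifts: bin 0 holds conserved helices (maximum
#' shift exactly 0); otherwise the bin is the smallest multiple of 10 at or
#' above the maximum shift (left-open/right-closed decades, so shifts in
#' (0, 10] fall in the 10% bin, (10, 20] in the 20% bin, and so on).
#'
#' @param shifts Non-empty numeric vector of shifts in `[0, 100]`.
#' @return Integer bin in `{0, 10, ..., 100}`.
#' @examples
#' assign_bin(c(50, 60, 70))  # 70
#' @export
assign_bin <- function(shifts) {
  if (!length(shifts))
    stop("cannot bin an empty shift list (unmapped helix)", call. = FALSE)
  if (any(shifts < 0 | shifts > 100))
    stop("shifts must lie in [0, 100]", call. = FALSE)
  mx <- max(shifts)
  if (mx == 0) 0L else as.integer(10L * ceiling(mx / 10))
}

#' Conserved / partial / variable classification
#'
#' `CONSERVED`: mapped and every occurrence fully helical (maximum shift 0).
#' `VARIABLE`: at least one occurrence with a complete (100%) shift.
#' `PARTIAL`: mapped with intermediate maximum shift. `UNMAPPED`: no
#' occurrence.
#'
#' @param shifts Numeric vector of shifts (possibly empty).
#' @return One of `"CONSERVED"`, `"PARTIAL"`, `"VARIABLE"`, `"UNMAPPED"`.
#' @export
classify_shifts <- function(shifts) {
  if (!length(shifts)) return("UNMAPPED")
  if (any(shifts == 100)) return("VARIABLE")
  if (max(shifts) == 0) return("CONSERVED")
  "PARTIAL"
}

#' SCOP fold/domain concordance of one helix
#'
#' Fraction of a helix's occurrences whose target chain carries the same
#' SCOP fold (resp. domain) label as the helix's source chain. Computed only
#' over occurrences where both sides carry the label; `NA` when no such
#' occurrence exists or the query label is absent.
#'
#' @param query_chain The helix's source `chain_record`.
#' @param target_chains List of `chain_record`s, one per occurrence.
#' @return Named numeric vector `c(same_fold_fraction, same_domain_fraction)`.
#' @export
concordance <- function(query_chain, target_chains) {
  frac <- function(q_label, t_labels) {
    if (is.na(q_label)) return(NA_real_)
    ok <- !is.na(t_labels)
    if (!any(ok)) return(NA_real_)
    mean(t_labels[ok] == q_label)
  }
  folds <- vapply(target_chains, `[[`, character(1), "scop_fold")
  doms <- vapply(target_chains, `[[`, character(1), "scop_domain")
  c(same_fold_fraction = frac(query_chain$scop_fold, folds),
    same_domain_fraction = frac(query_chain$scop_domain, doms))
}

#' Per-helix ambivalency records
#'
#' Aggregates the occurrence table per helix: number of occurrences,
#' maximum shift, decade bin, class, and (when SCOP labels are available on
#' both databases) fold/domain concordance fractions. Unmapped helices get
#' `n_occurrences = 0`, `NA` shift/bin and class `UNMAPPED`; helices flagged
#' `has_x` are always unmapped.
#'
#' @param helices Helix table.
#' @param occurrences Occurrence table from [map_all()].
#' @param query_db,target_db Optional `chain_db`s enabling concordance.
#' @return Data frame, one row per helix, with columns `helix_id`, `length`,
#'   `n_occurrences`, `max_shift`, `bin`, `klass`, `same_fold_fraction`,
#'   `same_domain_fraction`.
#' @export
ambivalency_records <- function(helices, occurrences, query_db = NULL,
                                target_db = NULL) {
  shift <- percent_shift(occurrences$target_ss)
  occ_by_helix <- split(seq_len(nrow(occurrences)), occurrences$helix_id)
  rows <- lapply(seq_len(nrow(helices)), function(i) {
    hx <- helices[i, ]
    idx <- occ_by_helix[[hx$helix_id]]
    shifts <- if (is.null(idx)) numeric(0) else shift[idx]
    klass <- classify_shifts(shifts)
    conc <- c(same_fold_fraction = NA_real_, same_domain_fraction = NA_real_)
    if (length(shifts) && !is.null(query_db) && !is.null(target_db)) {
      qch <- get_chain(query_db, paste0(hx$structure_id, "_", hx$chain_id))
      tch <- lapply(idx, function(j)
        get_chain(target_db, paste0(occurrences$target_structure_id[j], "_",
                                    occurrences$target_chain_id[j])))
      conc <- concordance(qch, tch)
    }
    data.frame(helix_id = hx$helix_id, length = hx$length,
               n_occurrences = length(shifts),
               max_shift = if (length(shifts)) max(shifts) else NA_real_,
               bin = if (length(shifts)) assign_bin(shifts) else NA_integer_,
               klass = klass,
               same_fold_fraction = conc[["same_fold_fraction"]],
               same_domain_fraction = conc[["same_domain_fraction"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Length-versus-shift summary table
#'
#' Cross-tabulates mapped helices by decade bin and helix-length class, and
#' reports, per bin, the count of helices, the fraction of all mapped
#' helices, and the longest helix. Length-class boundaries are
#' user-configurable.
#'
#' @param records Ambivalency record table.
#' @param length_breaks Increasing break points for the length classes
#'   (right-closed intervals).
#' @return List with `counts` (data frame bin x length-class), `per_bin`
#'   (data frame with `bin`, `n_helices`, `fraction`, `max_length`).
#' @export
length_shift_table <- function(records,
                               length_breaks = c(0, 10, 15, 20, 30, Inf)) {
  mapped <- records[records$klass != "UNMAPPED", , drop = FALSE]
  if (!nrow(mapped))
    return(list(counts = data.frame(), per_bin = data.frame(
      bin = integer(0), n_helices = integer(0), fraction = numeric(0),
      max_length = integer(0))))
  len_class <- cut(mapped$length, breaks = length_breaks,
                   include.lowest = FALSE, right = TRUE)
  bins <- factor(mapped$bin, levels = seq(0L, 100L, by = 10L))
  counts <- as.data.frame.matrix(table(bin = bins, length_class = len_class))
  counts <- cbind(bin = seq(0L, 100L, by = 10L), counts)
  rownames(counts) <- NULL
  per_bin_n <- as.integer(table(bins))
  max_len <- vapply(split(mapped$length, bins), function(v)
    if (length(v)) max(v) else NA_integer_, numeric(1))
  per_bin <- data.frame(bin = seq(0L, 100L, by = 10L),
                        n_helices = per_bin_n,
                        fraction = per_bin_n / nrow(mapped),
                        max_length = as.integer(max_len))
  list(counts = counts, per_bin = per_bin)
}

#' Write ambivalency records as TSV
#'
#' @param records Ambivalency record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ambivalency_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
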