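#' Normalized conformational parameter of a residue group
#'
#' For amino acid i and residue group j the normalized conformational
#' parameter is
#' \deqn{CP_{ij} = f_{ij} / f_i = (n_{ij} / \sum_i n_{ij}) / (N_i / \sum_i N_i)}
#' where `n_ij` counts amino acid i within the group and `N_i` counts it in
#' the whole background database. `CP > 1` marks preference for the group,
#' `CP < 1` aversion. Amino acids absent from the background get an `NA`
#' (absent) parameter rather than an infinity.
#'
#' @param group `residue_counts` of the group (numerator).
#' @param background `residue_counts` of the background database.
#' @param group_name Label stored in the table.
#' @return Object of class `"propensity_table"`: list with `group_name`,
#'   `cp` (named numeric over the 20 standard letters, `NA` where the
#'   background count is zero), `group_counts`, `background`.
#' @export
compute_cp <- function(group, background, group_name = "group") {
  stopifnot(inherits(group, "residue_counts"),
            inherits(background, "residue_counts"))
  if (group$total <= 0) stop("empty residue group", call. = FALSE)
  if (background$total <= 0) stop("empty background", call. = FALSE)
  f_group <- group$counts / group$total
  f_bg <- background$counts / background$total
  cp <- ifelse(background$counts > 0, f_group / f_bg, NA_real_)
  names(cp) <- AA_STANDARD
  structure(list(group_name = group_name, cp = cp, group_counts = group,
                 background = background),
            class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, ...) {
  cat(sprintf("<propensity_table '%s': %d group residues, %d background>\n",
              x$group_name, x$group_counts$total, x$background$total))
  print(round(x$cp, 3))
  invisible(x)
}

#' Background-weighted normalization sum of a propensity table
#'
#' Returns `sum_i f_i * CP_i` over the amino acids with a defined parameter;
#' when the background covers every group residue this equals 1 exactly (up
#' to floating-point error), a built-in consistency check on every emitted
#' table.
#'
#' @param pt A `propensity_table`.
#' @return Numeric scalar.
#' @export
cp_normalization <- function(pt) {
  f_bg <- pt$background$counts / pt$background$total
  ok <- !is.na(pt$cp)
  sum(f_bg[ok] * pt$cp[ok])
}

#' Per-bin conformational parameters
#'
#' Pools the residues of the (query) helix sequences assigned to each
#' decade bin and computes a propensity table per bin against the database
#' background. Helices flagged `has_x` are excluded; empty bins yield no
#' entry.
#'
#' @param records Ambivalency record table.
#' @param helices Helix table (source of the pooled sequences).
#' @param background `residue_counts` of the query database.
#' @return Named list (names `"0"`, `"10"`, ..., `"100"`, present bins only)
#'   of `propensity_table`s.
#' @export
cp_by_bin <- function(records, helices, background) {
  mapped <- records[records$klass != "UNMAPPED", , drop = FALSE]
  seqs <- helices$sequence[match(mapped$helix_id, helices$helix_id)]
  has_x <- helices$has_x[match(mapped$helix_id, helices$helix_id)]
  keep <- !has_x
  out <- list()
  for (b in sort(unique(mapped$bin[keep]))) {
    s <- seqs[keep & mapped$bin == b]
    if (!length(s)) next
    out[[as.character(b)]] <- compute_cp(residue_counts(s), background,
                                         group_name = paste0("bin_", b))
  }
  out
}

#' Flanking residues of a helix or occurrence
#'
#' Returns up to `flank_width` residues immediately preceding the segment
#' (N-terminal flank, chain order preserved) or immediately following it
#' (C-terminal flank), truncated at the chain boundaries. Nonstandard
#' residues are retained in the string but are excluded from any counts
#' made from it.
#'
#' @param chain A `chain_record`.
#' @param start,end 1-based inclusive segment coordinates in `chain`.
#' @param flank_width Maximum flank length (default 4).
#' @param terminus `"N"` or `"C"`.
#' @return Flank string (possibly empty).
#' @export
extract_flanks <- function(chain, start, end, flank_width = 4L,
                           terminus = c("N", "C")) {
  terminus <- match.arg(terminus)
  len <- nchar(chain$sequence)
  if (start < 1L || end > len || start > end)
    stop("segment ", start, "-", end, " outside chain ",
         chain_key(chain), call. = FALSE)
  if (terminus == "N") {
    from <- max(1L, start - flank_width)
    if (from > start - 1L) return("")
    substr(chain$sequence, from, start - 1L)
  } else {
    to <- min(len, end + flank_width)
    if (end + 1L > to) return("")
    substr(chain$sequence, end + 1L, to)
  }
}

flank_coords <- function(chain, start, end, flank_width, terminus) {
  len <- nchar(chain$sequence)
  if (terminus == "N") c(max(1L, start - flank_width), start - 1L)
  else c(end + 1L, min(len, end + flank_width))
}

#' Collect flanking sequences by terminus and conformational class
#'
#' Builds the flank populations used for flank propensity and accessibility
#' statistics: for every variable helix, the flanks of its (helical) query
#' segment (`HELICAL_CONF`) and the flanks of its completely non-helical
#' occurrences in the target chains (`NONHELICAL_CONF`); for every conserved
#' helix, the flanks of its query segment (`CONSERVED`). Each population is
#' split into N- and C-terminal flanks.
#'
#' @param records Ambivalency record table.
#' @param helices Helix table.
#' @param occurrences Occurrence table.
#' @param query_db,target_db The corresponding `chain_db`s.
#' @param flank_width Maximum flank length (default 4).
#' @return Data frame with columns `helix_id`, `terminus`, `source_class`,
#'   `structure_id`, `chain_id`, `flank_start`, `flank_end`, `flank_seq`
#'   (rows with empty flanks are dropped).
#' @export
collect_flanks <- function(records, helices, occurrences, query_db,
                           target_db, flank_width = 4L) {
  rows <- list()
  add <- function(helix_id, chain, start, end, source_class) {
    for (terminus in c("N", "C")) {
      fl <- extract_flanks(chain, start, end, flank_width, terminus)
      if (!nzchar(fl)) next
      fc <- flank_coords(chain, start, end, flank_width, terminus)
      rows[[length(rows) + 1L]] <<- data.frame(
        helix_id = helix_id, terminus = terminus,
        source_class = source_class,
        structure_id = chain$structure_id, chain_id = chain$chain_id,
        flank_start = fc[1L], flank_end = fc[2L], flank_seq = fl,
        stringsAsFactors = FALSE)
    }
  }
  shift <- percent_shift(occurrences$target_ss)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (!rec$klass %in% c("VARIABLE", "CONSERVED")) next
    hx <- helices[match(rec$helix_id, helices$helix_id), ]
    qch <- get_chain(query_db, paste0(hx$structure_id, "_", hx$chain_id))
    add(rec$helix_id, qch, hx$start, hx$end,
        if (rec$klass == "VARIABLE") "HELICAL_CONF" else "CONSERVED")
    if (rec$klass == "VARIABLE") {
      idx <- which(occurrences$helix_id == rec$helix_id & shift == 100)
      for (j in idx) {
        tch <- get_chain(target_db,
                         paste0(occurrences$target_structure_id[j], "_",
                                occurrences$target_chain_id[j]))
        add(rec$helix_id, tch, occurrences$target_start[j],
            occurrences$target_end[j], "NONHELICAL_CONF")
      }
    }
  }
  cols <- c("helix_id", "terminus", "source_class", "structure_id",
            "chain_id", "flank_start", "flank_end", "flank_seq")
  if (!length(rows)) {
    out <- data.frame(helix_id = character(0), terminus = character(0),
                      source_class = character(0),
                      structure_id = character(0), chain_id = character(0),
                      flank_start = integer(0), flank_end = integer(0),
                      flank_seq = character(0), stringsAsFactors = FALSE)
    return(out[cols])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))[cols]
}

#' Flank propensity tables by terminus and class
#'
#' One propensity table per occupied `(terminus, source_class)` stratum of
#' the flank set; empty strata yield no entry.
#'
#' @param flanks Flank table from [collect_flanks()].
#' @param background `residue_counts` of the query database.
#' @return Named list of `propensity_table`s; names like
#'   `"N:HELICAL_CONF"`, `"C:CONSERVED"`.
#' @export
flank_cp <- function(flanks, background) {
  out <- list()
  if (!nrow(flanks)) return(out)
  strata <- split(flanks$flank_seq,
                  paste(flanks$terminus, flanks$source_class, sep = ":"))
  for (nm in names(strata)) {
    rc <- residue_counts(strata[[nm]])
    if (rc$total == 0) next
    out[[nm]] <- compute_cp(rc, background, group_name = nm)
  }
  out
}

#' Write propensity tables as long-format TSV
#'
#' @param tables Named list of `propensity_table`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cp_table <- function(tables, path) {
  rows <- lapply(names(tables), function(nm) {
    pt <- tables[[nm]]
    data.frame(group = nm, aa = AA_STANDARD,
               cp = unname(pt$cp),
               group_count = unname(pt$group_counts$counts),
               group_total = pt$group_counts$total,
               background_fraction =
                 unname(pt$background$counts / pt$background$total),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(out))
    out <- data.frame(group = character(0), aa = character(0),
                      cp = numeric(0), group_count = integer(0),
                      group_total = integer(0),
                      background_fraction = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
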