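#' Reference exact mapper: the N-by-M match matrix
#'
#' For a query helix of N residues and a target chain of M residues an
#' N-by-M binary matrix `A` is formed with `A[i, j] = 1` when the i-th helix
#' residue equals the j-th chain residue. The helix is mapped at target
#' position `l` (spanning `l .. l + N - 1`) whenever `A[1, l] = 1` and the
#' diagonal sum `sum_{m=0}^{N-1} A[1 + m, l + m]` equals N. Every exact
#' occurrence is reported, including overlapping ones, ordered by
#' `target_start`. This is the reference algorithm; [map_helix_fast()] is
#' the production matcher and must agree with it exactly.
#'
#' @param helix One row of a helix table (data frame or list with at least
#'   `helix_id`, `structure_id`, `length`, `sequence`).
#' @param target A `chain_record`.
#' @return Occurrence data frame with columns `helix_id`,
#'   `helix_structure_id`, `helix_length`, `target_structure_id`,
#'   `target_chain_id`, `target_start`, `target_end`, `target_ss`
#'   (the 8-state codes over the occurrence window).
#' @export
map_helix_naive <- function(helix, target) {
  h <- str_chars(helix$sequence)
  if (!length(h)) stop("empty helix sequence", call. = FALSE)
  if (any(h == "X"))
    stop("helix ", helix$helix_id,
         " contains nonstandard residues ('X') and cannot be mapped; ",
         "filter on has_x first", call. = FALSE)
  t_chars <- str_chars(target$sequence)
  N <- length(h); M <- length(t_chars)
  starts <- integer(0)
  if (M >= N) {
    A <- outer(h, t_chars, "==")          # the N x M matrix
    for (l in seq_len(M - N + 1L)) {
      if (A[1L, l] &&
          sum(A[cbind(seq_len(N), l + seq_len(N) - 1L)]) == N)
        starts <- c(starts, l)
    }
  }
  occurrence_frame(helix, target, starts)
}

occurrence_frame <- function(helix, target, starts) {
  N <- nchar(helix$sequence)
  data.frame(
    helix_id = rep(helix$helix_id, length(starts)),
    helix_structure_id = rep(helix$structure_id, length(starts)),
    helix_length = rep(as.integer(N), length(starts)),
    target_structure_id = rep(target$structure_id, length(starts)),
    target_chain_id = rep(target$chain_id, length(starts)),
    target_start = as.integer(starts),
    target_end = as.integer(starts + N - 1L),
    target_ss = if (length(starts))
      substring(target$ss, starts, starts + N - 1L) else character(0),
    stringsAsFactors = FALSE)
}

#' Build an exact-match index over a target database
#'
#' Wraps the target chains in a `Biostrings::AAStringSet` so each helix can
#' be matched against every chain with an exact, overlap-complete string
#' matcher.
#'
#' @param db A `chain_db`.
#' @return Object of class `"target_index"`.
#' @export
build_target_index <- function(db) {
  set <- Biostrings::AAStringSet(vapply(db$chains, `[[`, character(1),
                                        "sequence"))
  names(set) <- chain_keys(db)
  structure(list(set = set, db = db), class = "target_index")
}

#' Fast exact mapper over an indexed database
#'
#' Matches one helix against every chain of the indexed database and returns
#' exactly the occurrences [map_helix_naive()] would report chain by chain
#' (all exact, possibly overlapping, matches).
#'
#' @param helix One helix-table row.
#' @param index A `target_index` from [build_target_index()].
#' @return Occurrence data frame (see [map_helix_naive()]), ordered by chain
#'   as indexed, then by `target_start`.
#' @export
map_helix_fast <- function(helix, index) {
  if (!nchar(helix$sequence)) stop("empty helix sequence", call. = FALSE)
  if (grepl("X", helix$sequence, fixed = TRUE))
    stop("helix ", helix$helix_id,
         " contains nonstandard residues ('X') and cannot be mapped; ",
         "filter on has_x first", call. = FALSE)
  m <- Biostrings::vmatchPattern(helix$sequence, index$set, fixed = TRUE)
  starts <- Biostrings::startIndex(m)
  parts <- lapply(seq_along(starts), function(i) {
    s <- starts[[i]]
    if (is.null(s) || !length(s)) return(NULL)
    occurrence_frame(helix, index$db$chains[[i]], sort(s))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    return(occurrence_frame(helix, chain_record("0XXX", "A", "A", "-"),
                            integer(0)))
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Map all query helices into a target database
#'
#' Unions the exact occurrences of each query helix over every target
#' chain. Helices flagged `has_x` are skipped (they cannot match). With
#' `exclude_self = TRUE` (default), occurrences in target chains sharing the
#' helix's source `structure_id` are removed, so a helix is never scored
#' against its own structure.
#'
#' @param query_helices Helix table.
#' @param target_db A `chain_db` (or a prebuilt `target_index`).
#' @param exclude_self Drop occurrences in the helix's own structure.
#' @param method `"fast"` (indexed matcher) or `"naive"` (reference
#'   algorithm); both give identical output.
#' @return Occurrence data frame over all helices.
#' @export
map_all <- function(query_helices, target_db, exclude_self = TRUE,
                    method = c("fast", "naive")) {
  method <- match.arg(method)
  index <- if (inherits(target_db, "target_index")) target_db else
    build_target_index(target_db)
  usable <- query_helices[!query_helices$has_x, , drop = FALSE]
  parts <- lapply(seq_len(nrow(usable)), function(i) {
    hx <- usable[i, ]
    if (method == "fast") {
      map_helix_fast(hx, index)
    } else {
      do.call(rbind, lapply(index$db$chains, function(ch)
        map_helix_naive(hx, ch)))
    }
  })
  empty <- occurrence_frame(list(helix_id = character(0),
                                 structure_id = character(0),
                                 sequence = ""),
                            chain_record("0XXX", "A", "A", "-"), integer(0))
  occ <- do.call(rbind, c(list(empty), parts, list(make.row.names = FALSE)))
  if (exclude_self)
    occ <- occ[occ$target_structure_id != occ$helix_structure_id, ,
               drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Write an occurrence table as TSV
#'
#' Includes the percentage conformational shift of each occurrence.
#'
#' @param occurrences Occurrence table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(occurrences, path) {
  out <- occurrences
  if (!"shift" %in% names(out)) out$shift <- percent_shift(out$target_ss)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
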