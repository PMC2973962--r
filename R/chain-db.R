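#' Construct a single protein-chain record
#'
#' A chain record couples a one-letter amino-acid sequence with a
#' residue-wise 8-state secondary-structure string (DSSP alphabet), an
#' optional absolute solvent-accessibility vector (A^2, as reported by
#' DSSP), and structure-level metadata used for quality filtering and
#' SCOP concordance statistics.
#'
#' @param structure_id Structure identifier (PDB-style 4-character code or a
#'   synthetic id).
#' @param chain_id Chain identifier (one or more characters).
#' @param sequence One-letter sequence over the 20 standard codes plus `"X"`
#'   for nonstandard residues.
#' @param ss Secondary-structure string over `H,G,I,B,E,S,T,-`; same length
#'   as `sequence`.
#' @param acc Optional numeric vector of non-negative absolute accessibilities
#'   (A^2), same length as `sequence`, or `NULL` when unavailable.
#' @param method Experimental method, `"XRAY"` or `"OTHER"`.
#' @param resolution Crystallographic resolution in Angstrom (positive), or
#'   `NA` when unknown.
#' @param r_factor Crystallographic R-factor in `[0, 1]`, or `NA`.
#' @param scop_class,scop_fold,scop_domain Optional SCOP labels (`NA` when
#'   absent).
#' @return An object of class `"chain_record"`.
#' @examples
#' chain_record("1ABC", "A", "MKLVA", "-HHHG")
#' @export
chain_record <- function(structure_id, chain_id, sequence, ss, acc = NULL,
                         method = c("XRAY", "OTHER"),
                         resolution = NA_real_, r_factor = NA_real_,
                         scop_class = NA_character_, scop_fold = NA_character_,
                         scop_domain = NA_character_) {
  method <- match.arg(method)
  rec <- structure(
    list(structure_id = as.character(structure_id),
         chain_id = as.character(chain_id),
         sequence = toupper(as.character(sequence)),
         ss = as.character(ss),
         acc = if (is.null(acc)) NULL else as.numeric(acc),
         method = method,
         resolution = as.numeric(resolution),
         r_factor = as.numeric(r_factor),
         scop_class = as.character(scop_class),
         scop_fold = as.character(scop_fold),
         scop_domain = as.character(scop_domain)),
    class = "chain_record")
  validate_chain_record(rec)
  rec
}

validate_chain_record <- function(rec) {
  key <- paste0(rec$structure_id, "_", rec$chain_id)
  if (!nzchar(rec$structure_id) || !nzchar(rec$chain_id))
    stop("chain record has empty structure_id or chain_id", call. = FALSE)
  if (nchar(rec$sequence) != nchar(rec$ss))
    stop("chain ", key, ": sequence and ss lengths differ (",
         nchar(rec$sequence), " vs ", nchar(rec$ss), ")", call. = FALSE)
  bad_aa <- setdiff(unique(str_chars(rec$sequence)), c(AA_STANDARD, "X"))
  if (length(bad_aa))
    stop("chain ", key, ": invalid residue letter(s): ",
         paste(bad_aa, collapse = ", "), call. = FALSE)
  bad_ss <- setdiff(unique(str_chars(rec$ss)), DSSP_CODES)
  if (length(bad_ss))
    stop("chain ", key, ": invalid secondary-structure code(s): ",
         paste(bad_ss, collapse = ", "), call. = FALSE)
  if (!is.null(rec$acc)) {
    if (length(rec$acc) != nchar(rec$sequence))
      stop("chain ", key, ": accessibility vector length (", length(rec$acc),
           ") differs from sequence length (", nchar(rec$sequence), ")",
           call. = FALSE)
    if (any(rec$acc < 0, na.rm = TRUE))
      stop("chain ", key, ": negative accessibility value", call. = FALSE)
  }
  if (!is.na(rec$resolution) && rec$resolution <= 0)
    stop("chain ", key, ": resolution must be positive", call. = FALSE)
  if (!is.na(rec$r_factor) && (rec$r_factor < 0 || rec$r_factor > 1))
    stop("chain ", key, ": r_factor outside [0, 1]", call. = FALSE)
  invisible(rec)
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record %s_%s  %d residues  %s  res=%s R=%s>\n",
              x$structure_id, x$chain_id, nchar(x$sequence), x$method,
              format(x$resolution), format(x$r_factor)))
  invisible(x)
}

#' Construct a chain database
#'
#' An ordered collection of [chain_record()] objects with unique
#' `(structure_id, chain_id)` keys, tagged with a name and a role
#' (`QUERY` for the non-redundant source of helices, `TARGET` for the
#' database the helices are mapped into).
#'
#' @param chains List of `chain_record` objects.
#' @param name Database name.
#' @param role `"QUERY"` or `"TARGET"`.
#' @return An object of class `"chain_db"`.
#' @export
chain_db <- function(chains, name = "db", role = c("QUERY", "TARGET")) {
  role <- match.arg(role)
  stopifnot(is.list(chains))
  for (ch in chains)
    if (!inherits(ch, "chain_record"))
      stop("all elements of 'chains' must be chain_record objects",
           call. = FALSE)
  keys <- vapply(chains, chain_key, character(1))
  dup <- keys[duplicated(keys)]
  if (length(dup))
    stop("duplicate chain key(s) in database '", name, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  structure(list(chains = chains, name = name, role = role),
            class = "chain_db")
}

#' @export
print.chain_db <- function(x, ...) {
  cat(sprintf("<chain_db '%s' (%s): %d chains, %d residues>\n", x$name,
              x$role, length(x$chains),
              sum(vapply(x$chains, function(ch) nchar(ch$sequence), 1L))))
  invisible(x)
}

#' @export
length.chain_db <- function(x) length(x$chains)

#' Chain keys of a database
#'
#' @param db A `chain_db`.
#' @return Character vector `structure_id_chain_id`, one per chain.
#' @export
chain_keys <- function(db) vapply(db$chains, chain_key, character(1))

chain_key <- function(rec) paste0(rec$structure_id, "_", rec$chain_id)

#' Look up a chain by key
#'
#' @param db A `chain_db`.
#' @param key A key as produced by [chain_keys()].
#' @return The matching `chain_record`, or an error if absent.
#' @export
get_chain <- function(db, key) {
  idx <- match(key, chain_keys(db))
  if (is.na(idx)) stop("no chain with key '", key, "' in database '",
                       db$name, "'", call. = FALSE)
  db$chains[[idx]]
}

#' Filter chains on structure quality
#'
#' Keeps X-ray structures with resolution and crystallographic R-factor at
#' or below the cutoffs (both boundaries inclusive). Chains whose resolution
#' or R-factor is unknown are dropped while the corresponding filter is
#' active, as are non-X-ray chains unless `xray_only = FALSE`.
#'
#' @param db A `chain_db`.
#' @param max_resolution Maximum resolution in Angstrom (default 3.0).
#' @param max_r Maximum R-factor (default 0.3).
#' @param xray_only Keep X-ray structures only (default `TRUE`).
#' @return A filtered `chain_db` in the original order.
#' @export
filter_chains <- function(db, max_resolution = 3.0, max_r = 0.3,
                          xray_only = TRUE) {
  keep <- vapply(db$chains, function(ch) {
    if (xray_only && ch$method != "XRAY") return(FALSE)
    if (!is.null(max_resolution) && !is.na(max_resolution)) {
      if (is.na(ch$resolution) || ch$resolution > max_resolution) return(FALSE)
    }
    if (!is.null(max_r) && !is.na(max_r)) {
      if (is.na(ch$r_factor) || ch$r_factor > max_r) return(FALSE)
    }
    TRUE
  }, logical(1))
  chain_db(db$chains[keep], name = db$name, role = db$role)
}

#' Read a chain-table file
#'
#' The chain table is a UTF-8, tab-separated text format with one row per
#' chain and a header line naming the columns `structure_id, chain_id,
#' method, resolution, r_factor, scop_class, scop_fold, scop_domain,
#' sequence, ss, acc`. The `acc` column holds comma-separated absolute
#' accessibilities or `NA` when unavailable; other optional fields use `NA`.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param name Database name (defaults to the file name).
#' @param role Database role, `"QUERY"` or `"TARGET"`.
#' @return A `chain_db`.
#' @seealso [write_chain_table()]
#' @export
read_chain_table <- function(path, name = basename(path),
                             role = c("QUERY", "TARGET")) {
  role <- match.arg(role)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chain table: ", path, call. = FALSE)
  cols <- c("structure_id", "chain_id", "method", "resolution", "r_factor",
            "scop_class", "scop_fold", "scop_domain", "sequence", "ss", "acc")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, cols))
    stop("chain table header mismatch in ", path, "; expected columns: ",
         paste(cols, collapse = ", "), call. = FALSE)
  chains <- lapply(lines[-1L], function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(cols))
      stop("chain table row with ", length(f), " fields (expected ",
           length(cols), "): ", substr(line, 1, 40), "...", call. = FALSE)
    names(f) <- cols
    acc <- if (identical(f[["acc"]], "NA")) NULL else
      as.numeric(strsplit(f[["acc"]], ",", fixed = TRUE)[[1L]])
    opt <- function(v) if (identical(v, "NA")) NA_character_ else v
    num <- function(v) if (identical(v, "NA")) NA_real_ else as.numeric(v)
    chain_record(f[["structure_id"]], f[["chain_id"]], f[["sequence"]],
                 f[["ss"]], acc = acc, method = f[["method"]],
                 resolution = num(f[["resolution"]]),
                 r_factor = num(f[["r_factor"]]),
                 scop_class = opt(f[["scop_class"]]),
                 scop_fold = opt(f[["scop_fold"]]),
                 scop_domain = opt(f[["scop_domain"]]))
  })
  chain_db(chains, name = name, role = role)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         vapply(x, function(v)
           format(v, digits = 15, scientific = FALSE, trim = TRUE),
           character(1)))
}

#' Write a chain database to a chain-table file
#'
#' Inverse of [read_chain_table()]; round-trips field-for-field (numbers are
#' written at up to 15 significant digits).
#'
#' @param db A `chain_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_table <- function(db, path) {
  cols <- c("structure_id", "chain_id", "method", "resolution", "r_factor",
            "scop_class", "scop_fold", "scop_domain", "sequence", "ss", "acc")
  rows <- vapply(db$chains, function(ch) {
    opt <- function(v) if (is.na(v)) "NA" else v
    acc <- if (is.null(ch$acc)) "NA" else paste(fmt_num(ch$acc), collapse = ",")
    paste(c(ch$structure_id, ch$chain_id, ch$method, fmt_num(ch$resolution),
            fmt_num(ch$r_factor), opt(ch$scop_class), opt(ch$scop_fold),
            opt(ch$scop_domain), ch$sequence, ch$ss, acc), collapse = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Residue counts over the standard amino acids
#'
#' Tallies one-letter residues over the 20 standard amino acids; `"X"` and
#' any other letter are excluded from both the counts and the total. These
#' objects hold the group numerator counts and the database background
#' counts of the normalized conformational parameter.
#'
#' @param x Character vector of sequences (each string may hold many
#'   residues).
#' @return Object of class `"residue_counts"`: list with `counts` (named
#'   integer vector over the 20 standard letters) and `total`.
#' @examples
#' residue_counts(c("AAG", "CX"))
#' @export
residue_counts <- function(x) {
  chars <- unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE)
  tab <- table(factor(chars, levels = AA_STANDARD))
  counts <- as.integer(tab)
  names(counts) <- AA_STANDARD
  structure(list(counts = counts, total = sum(counts)),
            class = "residue_counts")
}

#' @export
print.residue_counts <- function(x, ...) {
  cat("<residue_counts: total", x$total, "residues>\n")
  print(x$counts)
  invisible(x)
}

#' Combine residue counts elementwise
#'
#' @param ... `residue_counts` objects.
#' @return A `residue_counts` with summed counts.
#' @export
combine_counts <- function(...) {
  parts <- list(...)
  counts <- Reduce(`+`, lapply(parts, `[[`, "counts"))
  structure(list(counts = counts, total = sum(counts)),
            class = "residue_counts")
}

#' Background residue counts of a chain database
#'
#' Counts every residue of every chain; nonstandard residues (`"X"`) are
#' excluded from the counts and the total. The resulting frequencies are the
#' background of the normalized conformational parameter.
#'
#' @param db A non-empty `chain_db`.
#' @return A `residue_counts`.
#' @export
background_counts <- function(db) {
  if (!length(db$chains))
    stop("cannot compute background counts of an empty database",
         call. = FALSE)
  residue_counts(vapply(db$chains, `[[`, character(1), "sequence"))
}

#' Write extracted helices as FASTA
#'
#' Headers follow `structure_id_chain|start-end` with 1-based inclusive
#' positions.
#'
#' @param helices Helix table from [extract_all_helices()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_fasta <- function(helices, path) {
  set <- Biostrings::AAStringSet(helices$sequence)
  names(set) <- helices$helix_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a helix FASTA written by [write_helix_fasta()]
#'
#' @param path FASTA path.
#' @return Data frame with `helix_id`, `structure_id`, `chain_id`, `start`,
#'   `end`, `length`, `sequence`.
#' @export
read_helix_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- names(set)
  m <- regmatches(ids, regexec("^(.+)_([^_|]+)\\|(\\d+)-(\\d+)$", ids))
  bad <- which(vapply(m, length, 1L) != 5L)
  if (length(bad))
    stop("malformed helix FASTA header: ", ids[bad[1L]], call. = FALSE)
  data.frame(
    helix_id = ids,
    structure_id = vapply(m, `[[`, character(1), 2L),
    chain_id = vapply(m, `[[`, character(1), 3L),
    start = as.integer(vapply(m, `[[`, character(1), 4L)),
    end = as.integer(vapply(m, `[[`, character(1), 5L)),
    length = Biostrings::width(set),
    sequence = as.character(set),
    stringsAsFactors = FALSE)
}
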