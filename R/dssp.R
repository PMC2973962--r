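#' Read classic DSSP output
#'
#' Parses the fixed-width per-residue table of a classic DSSP text file
#' (header block followed by a `#  RESIDUE AA STRUCTURE ...` table) into
#' chain records. Per the DSSP conventions:
#' * lowercase residue letters (SS-bonded half-cystines) are mapped to `C`;
#' * a blank structure code becomes `-` (no assignment);
#' * `!` rows mark chain breaks and split the surrounding residues into
#'   separate records — a discontinuous chain `A` yields records with chain
#'   ids `A`, `A.2`, `A.3`, ...;
#' * residues DSSP cannot assign to a standard amino acid (letter `X` or
#'   other non-alphabetic codes) are stored as `X`.
#'
#' DSSP insertion codes and author residue numbering are discarded:
#' positions are sequential indices along the chain as parsed. Classic DSSP
#' output carries no reliable experimental metadata, so `method`,
#' `resolution` and `r_factor` default to "unknown" values and may be
#' supplied by the caller.
#'
#' @param path Path to a DSSP file.
#' @param method,resolution,r_factor Metadata applied to every parsed chain.
#' @param name Database name for the returned collection.
#' @param role Database role.
#' @return A `chain_db` with one `chain_record` per (sub-)chain.
#' @export
read_dssp <- function(path, method = "OTHER", resolution = NA_real_,
                      r_factor = NA_real_, name = basename(path),
                      role = c("QUERY", "TARGET")) {
  role <- match.arg(role)
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("malformed DSSP file (no '  #  RESIDUE' table header): ", path,
         call. = FALSE)
  hdr <- hdr[[1L]]
  structure_id <- dssp_structure_id(lines[seq_len(hdr - 1L)])
  body_idx <- seq.int(hdr + 1L, length(lines))
  body_idx <- body_idx[nzchar(lines[body_idx])]

  seqs <- character(0); sss <- character(0); accs <- list()
  cur_aa <- character(0); cur_ss <- character(0); cur_acc <- numeric(0)
  cur_chain <- NA_character_
  part <- integer(0)  # per emitted record: part number within its chain id
  chains_out <- list()

  flush_chain <- function() {
    if (!length(cur_aa)) return()
    n_prev <- sum(vapply(chains_out, function(x) x$chain == cur_chain, TRUE))
    cid <- if (n_prev == 0L) cur_chain else
      paste0(cur_chain, ".", n_prev + 1L)
    chains_out[[length(chains_out) + 1L]] <<- list(
      chain = cur_chain, chain_id = cid,
      sequence = paste(cur_aa, collapse = ""),
      ss = paste(cur_ss, collapse = ""), acc = cur_acc)
    cur_aa <<- character(0); cur_ss <<- character(0); cur_acc <<- numeric(0)
  }

  for (i in body_idx) {
    line <- lines[[i]]
    aa <- substr(line, 14L, 14L)
    if (aa == "!") {           # chain break or chain terminator
      flush_chain()
      next
    }
    if (nchar(line) < 17L)
      stop("malformed DSSP residue line ", i, " in ", path, call. = FALSE)
    chain <- substr(line, 12L, 12L)
    if (!is.na(cur_chain) && length(cur_aa) && chain != cur_chain)
      flush_chain()
    cur_chain <- chain
    ss <- substr(line, 17L, 17L)
    if (ss == " ") ss <- "-"
    if (!ss %in% DSSP_CODES)
      stop("malformed DSSP residue line ", i, " in ", path,
           " (structure code '", ss, "')", call. = FALSE)
    if (grepl("[a-z]", aa)) aa <- "C"           # SS-bonded half-cystine
    if (!aa %in% AA_STANDARD) aa <- "X"
    acc_field <- trimws(substr(line, 35L, 38L))
    acc <- suppressWarnings(as.numeric(acc_field))
    if (is.na(acc) && nzchar(acc_field))
      stop("malformed DSSP residue line ", i, " in ", path,
           " (ACC field '", acc_field, "')", call. = FALSE)
    cur_aa <- c(cur_aa, aa)
    cur_ss <- c(cur_ss, ss)
    cur_acc <- c(cur_acc, if (is.na(acc)) 0 else acc)
  }
  flush_chain()
  if (!length(chains_out))
    stop("DSSP file contains no residues: ", path, call. = FALSE)

  recs <- lapply(chains_out, function(x)
    chain_record(structure_id, x$chain_id, x$sequence, x$ss, acc = x$acc,
                 method = method, resolution = resolution,
                 r_factor = r_factor))
  chain_db(recs, name = name, role = role)
}

# Pull the 4-character PDB id off the embedded HEADER line, if present.
dssp_structure_id <- function(header_lines) {
  h <- grep("^HEADER", header_lines, value = TRUE)
  if (length(h)) {
    tokens <- strsplit(trimws(sub("\\.$", "", h[[1L]])), "\\s+")[[1L]]
    last <- tokens[length(tokens)]
    if (grepl("^[0-9][A-Za-z0-9]{3}$", last)) return(toupper(last))
  }
  "UNKN"
}
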