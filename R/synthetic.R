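#' Specification of one planted helix
#'
#' Describes a helix to be planted in the synthetic query database together
#' with its mapped occurrences in the target database: the helix length, the
#' prescribed conformational shift of every occurrence, the sampling bias of
#' its residues and of its N-/C-terminal flanks, and whether each target
#' chain shares the query chain's SCOP fold/domain labels.
#'
#' The number of non-helical positions of an occurrence is
#' `round(shift * length / 100)` (nearest integer); the realized shift
#' recorded in the ground truth is recomputed from that count. A shift that
#' rounds to a different conformational class than planted (a positive shift
#' rounding to 0 non-helical positions, or a sub-100 shift rounding to all
#' positions) is rejected as infeasible.
#'
#' @param helix_length Helix length in residues (>= 5).
#' @param occurrence_shifts Numeric vector of shifts in `[0, 100]`, one per
#'   planted target occurrence (may be empty: the helix stays unmapped).
#' @param group_label Group name used in the ground truth.
#' @param residue_bias Optional named positive weights over amino-acid
#'   letters; unnamed residues keep weight 1. `NULL` = uniform.
#' @param n_flank_bias,c_flank_bias Optional weight maps for the flank
#'   residues (both query and target side).
#' @param scop_fold_match Logical vector (recycled over occurrences): does
#'   the target chain share the query chain's SCOP fold/domain labels?
#' @param shift_mode `"block"`: the non-helical positions form a contiguous
#'   block at the C-terminal end of the occurrence (fraying); `"scattered"`:
#'   they are sampled uniformly over the occurrence.
#' @return Object of class `"plant_spec"`.
#' @export
plant_spec <- function(helix_length, occurrence_shifts = numeric(0),
                       group_label = "group", residue_bias = NULL,
                       n_flank_bias = NULL, c_flank_bias = NULL,
                       scop_fold_match = TRUE,
                       shift_mode = c("block", "scattered")) {
  shift_mode <- match.arg(shift_mode)
  helix_length <- as.integer(helix_length)
  if (helix_length < 5L)
    stop("helix_length must be at least 5", call. = FALSE)
  if (length(occurrence_shifts) &&
      any(occurrence_shifts < 0 | occurrence_shifts > 100))
    stop("occurrence shifts must lie in [0, 100]", call. = FALSE)
  k <- round(occurrence_shifts * helix_length / 100)
  bad <- (occurrence_shifts > 0 & k == 0L) |
    (occurrence_shifts < 100 & k == helix_length)
  if (any(bad))
    stop("infeasible shift(s) for helix length ", helix_length, ": ",
         paste(occurrence_shifts[bad], collapse = ", "),
         " (rounding changes the conformational class)", call. = FALSE)
  structure(list(helix_length = helix_length,
                 occurrence_shifts = as.numeric(occurrence_shifts),
                 n_nonhelical = as.integer(k),
                 realized_shifts = 100 * as.integer(k) / helix_length,
                 group_label = group_label,
                 residue_bias = residue_bias,
                 n_flank_bias = n_flank_bias,
                 c_flank_bias = c_flank_bias,
                 scop_fold_match = rep_len(scop_fold_match,
                                           length(occurrence_shifts)),
                 shift_mode = shift_mode),
            class = "plant_spec")
}

#' Global configuration of the synthetic generator
#'
#' @param plants List of [plant_spec()]s.
#' @param n_decoy_query,n_decoy_target Numbers of unrelated all-coil decoy
#'   chains added to each database (default 0).
#' @param context_length Integer range (min, max) of the random non-helical
#'   context segments placed before and after each planted segment.
#' @param flank_width Planted flank width (default 4).
#' @param context_bias Optional residue weight map for context and decoy
#'   residues.
#' @param helix_hg_prob Sampling probabilities of codes `H` and `G` within
#'   helical stretches.
#' @param acc_beta Per-class Beta shape pairs for synthetic accessibility,
#'   list with elements `helix`, `coil`, `n_flank`, `c_flank`; each RSA draw
#'   is scaled by the residue's Gly-X-Gly maximum.
#' @param max_tries Whole-database regeneration budget when the collision
#'   scan finds accidental extra occurrences of a planted sequence.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(plants, n_decoy_query = 0L, n_decoy_target = 0L,
                             context_length = c(6L, 20L), flank_width = 4L,
                             context_bias = NULL,
                             helix_hg_prob = c(0.85, 0.15),
                             acc_beta = list(helix = c(1.5, 4),
                                             coil = c(2, 2),
                                             n_flank = c(2, 2),
                                             c_flank = c(2, 2)),
                             max_tries = 20L) {
  for (p in plants)
    if (!inherits(p, "plant_spec"))
      stop("'plants' must be a list of plant_spec objects", call. = FALSE)
  stopifnot(length(context_length) == 2L,
            context_length[1L] >= 1L,
            context_length[2L] >= context_length[1L])
  structure(list(plants = plants,
                 n_decoy_query = as.integer(n_decoy_query),
                 n_decoy_target = as.integer(n_decoy_target),
                 context_length = as.integer(context_length),
                 flank_width = as.integer(flank_width),
                 context_bias = context_bias,
                 helix_hg_prob = helix_hg_prob,
                 acc_beta = acc_beta,
                 max_tries = as.integer(max_tries)),
            class = "synthetic_config")
}

bias_prob <- function(bias) {
  w <- stats::setNames(rep(1, length(AA_STANDARD)), AA_STANDARD)
  if (!is.null(bias)) {
    bad <- setdiff(names(bias), AA_STANDARD)
    if (length(bad))
      stop("bias names must be standard amino-acid letters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(bias <= 0)) stop("bias weights must be positive", call. = FALSE)
    w[names(bias)] <- bias
  }
  w / sum(w)
}

sample_aa <- function(n, prob) {
  if (n <= 0L) return(character(0))
  sample(AA_STANDARD, n, replace = TRUE, prob = prob)
}

sample_coil_ss <- function(n) {
  if (n <= 0L) return(character(0))
  sample(NONHELICAL_CODES, n, replace = TRUE)
}

sample_helical_ss <- function(n, hg_prob) {
  if (n <= 0L) return(character(0))
  sample(HELICAL_CODES, n, replace = TRUE, prob = hg_prob)
}

sample_acc <- function(residues, shape, max_table) {
  if (!length(residues)) return(numeric(0))
  round(stats::rbeta(length(residues), shape[1L], shape[2L]) *
          max_table[residues], 2)
}

#' Generate seeded query/target databases with planted ground truth
#'
#' Builds a query database holding one fully helical planted segment per
#' [plant_spec()] (embedded in non-helical flank + context residues) and a
#' target database holding, for each prescribed occurrence, one chain with
#' the identical sequence annotated at the prescribed conformational shift.
#' Chain metadata (X-ray, resolution, R-factor, SCOP labels) and per-residue
#' accessibility are drawn per the configuration. After generation, every
#' planted sequence is scanned against both databases (overlap-aware) and
#' the whole generation is retried with a derived sub-seed if the context
#' accidentally created extra occurrences; the retry budget exhausting is an
#' error. Identical seeds give byte-identical databases.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed controlling every random draw.
#' @return List with `query` (`chain_db`), `target` (`chain_db`) and `truth`
#'   (ground-truth list: `seed`, per-helix data frame `helices` with
#'   realized shifts/bins/classes, per-occurrence frame `occurrences`,
#'   per-group sampling distributions `groups`).
#' @export
generate_databases <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  for (attempt in seq_len(config$max_tries)) {
    sub_seed <- (seed + (attempt - 1L) * 1000003) %% 2147483647
    set.seed(sub_seed)
    built <- build_databases(config)
    report <- verify_no_collisions(built$query, built$target,
                                   built$truth$helices)
    if (all(report$ok)) {
      built$truth$seed <- seed
      return(built)
    }
  }
  stop("collision retry budget exhausted: planted sequences keep ",
       "reappearing in the random context (", config$max_tries, " tries)",
       call. = FALSE)
}

build_databases <- function(config) {
  maxt <- max_acc_gxg()
  fw <- config$flank_width
  ctx_prob <- bias_prob(config$context_bias)
  rand_len <- function()
    sample(seq.int(config$context_length[1L], config$context_length[2L]), 1L)

  query_chains <- list(); target_chains <- list()
  helix_rows <- list(); occ_rows <- list(); groups <- list()
  t_counter <- 0L

  for (i in seq_along(config$plants)) {
    p <- config$plants[[i]]
    N <- p$helix_length
    hx_prob <- bias_prob(p$residue_bias)
    nf_prob <- bias_prob(p$n_flank_bias %||0% config$context_bias)
    cf_prob <- bias_prob(p$c_flank_bias %||0% config$context_bias)
    helix_seq <- paste(sample_aa(N, hx_prob), collapse = "")

    sid_q <- sprintf("q%03d", i)
    pre <- sample_aa(rand_len(), ctx_prob)
    nfl <- sample_aa(fw, nf_prob)
    cfl <- sample_aa(fw, cf_prob)
    post <- sample_aa(rand_len(), ctx_prob)
    q_seq <- paste(c(pre, nfl, str_chars(helix_seq), cfl, post),
                   collapse = "")
    start <- length(pre) + fw + 1L
    end <- start + N - 1L
    q_ss <- paste(c(sample_coil_ss(length(pre)), sample_coil_ss(fw),
                    sample_helical_ss(N, config$helix_hg_prob),
                    sample_coil_ss(fw), sample_coil_ss(length(post))),
                  collapse = "")
    q_acc <- c(sample_acc(pre, config$acc_beta$coil, maxt),
               sample_acc(nfl, config$acc_beta$n_flank, maxt),
               sample_acc(str_chars(helix_seq), config$acc_beta$helix, maxt),
               sample_acc(cfl, config$acc_beta$c_flank, maxt),
               sample_acc(post, config$acc_beta$coil, maxt))
    query_chains[[length(query_chains) + 1L]] <- chain_record(
      sid_q, "A", q_seq, q_ss, acc = q_acc, method = "XRAY",
      resolution = round(stats::runif(1, 1.0, 2.8), 2),
      r_factor = round(stats::runif(1, 0.15, 0.28), 3),
      scop_class = "a", scop_fold = paste0("F", i),
      scop_domain = paste0("D", i))

    for (j in seq_along(p$occurrence_shifts)) {
      t_counter <- t_counter + 1L
      sid_t <- sprintf("t%04d", t_counter)
      k <- p$n_nonhelical[j]
      nonhel_pos <- if (p$shift_mode == "block") {
        if (k > 0L) seq.int(N - k + 1L, N) else integer(0)
      } else {
        sort(sample.int(N, k))
      }
      occ_ss <- sample_helical_ss(N, config$helix_hg_prob)
      occ_ss[nonhel_pos] <- sample_coil_ss(length(nonhel_pos))
      pre_t <- sample_aa(rand_len(), ctx_prob)
      nfl_t <- sample_aa(fw, nf_prob)
      cfl_t <- sample_aa(fw, cf_prob)
      post_t <- sample_aa(rand_len(), ctx_prob)
      t_seq <- paste(c(pre_t, nfl_t, str_chars(helix_seq), cfl_t, post_t),
                     collapse = "")
      t_start <- length(pre_t) + fw + 1L
      t_ss <- paste(c(sample_coil_ss(length(pre_t)), sample_coil_ss(fw),
                      occ_ss, sample_coil_ss(fw),
                      sample_coil_ss(length(post_t))), collapse = "")
      t_acc <- c(sample_acc(pre_t, config$acc_beta$coil, maxt),
                 sample_acc(nfl_t, config$acc_beta$n_flank, maxt),
                 sample_acc(str_chars(helix_seq), config$acc_beta$helix,
                            maxt),
                 sample_acc(cfl_t, config$acc_beta$c_flank, maxt),
                 sample_acc(post_t, config$acc_beta$coil, maxt))
      match_labels <- p$scop_fold_match[j]
      target_chains[[length(target_chains) + 1L]] <- chain_record(
        sid_t, "A", t_seq, t_ss, acc = t_acc, method = "XRAY",
        resolution = round(stats::runif(1, 1.0, 2.8), 2),
        r_factor = round(stats::runif(1, 0.15, 0.28), 3),
        scop_class = "a",
        scop_fold = if (match_labels) paste0("F", i) else paste0("F", i, "x"),
        scop_domain = if (match_labels) paste0("D", i)
                      else paste0("D", i, "x"))
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        helix_id = sprintf("%s_A|%d-%d", sid_q, start, end),
        target_structure_id = sid_t, target_chain_id = "A",
        target_start = t_start, target_end = t_start + N - 1L,
        planted_shift = p$realized_shifts[j],
        scop_match = match_labels, stringsAsFactors = FALSE)
    }

    shifts <- p$realized_shifts
    helix_rows[[length(helix_rows) + 1L]] <- data.frame(
      helix_id = sprintf("%s_A|%d-%d", sid_q, start, end),
      structure_id = sid_q, chain_id = "A", start = start, end = end,
      length = N, sequence = helix_seq, group_label = p$group_label,
      n_occurrences = length(shifts),
      max_shift = if (length(shifts)) max(shifts) else NA_real_,
      bin = if (length(shifts)) assign_bin(shifts) else NA_integer_,
      klass = classify_shifts(shifts),
      shifts = paste(shifts, collapse = ","),
      stringsAsFactors = FALSE)
    if (is.null(groups[[p$group_label]]))
      groups[[p$group_label]] <- list(prob = bias_prob(p$residue_bias),
                                      n_flank_prob = nf_prob,
                                      c_flank_prob = cf_prob,
                                      n_residues = 0L)
    groups[[p$group_label]]$n_residues <-
      groups[[p$group_label]]$n_residues + N
  }

  decoy <- function(prefix, idx) {
    len <- sample(40:80, 1L)
    res <- sample_aa(len, ctx_prob)
    chain_record(sprintf("%s%03d", prefix, idx), "A",
                 paste(res, collapse = ""),
                 paste(sample_coil_ss(len), collapse = ""),
                 acc = sample_acc(res, config$acc_beta$coil, maxt),
                 method = "XRAY",
                 resolution = round(stats::runif(1, 1.0, 2.8), 2),
                 r_factor = round(stats::runif(1, 0.15, 0.28), 3))
  }
  for (d in seq_len(config$n_decoy_query))
    query_chains[[length(query_chains) + 1L]] <- decoy("x", d)
  for (d in seq_len(config$n_decoy_target))
    target_chains[[length(target_chains) + 1L]] <- decoy("y", d)

  truth <- list(
    helices = do.call(rbind, c(helix_rows, list(make.row.names = FALSE))),
    occurrences = do.call(rbind, c(occ_rows, list(make.row.names = FALSE))),
    groups = groups)
  list(query = chain_db(query_chains, name = "synthetic_query",
                        role = "QUERY"),
       target = chain_db(target_chains, name = "synthetic_target",
                         role = "TARGET"),
       truth = truth)
}

# fall back to b when a is NULL (used for flank bias defaulting)
`%||0%` <- function(a, b) if (is.null(a)) b else a

# newline-joined chain sequences: patterns are amino-acid letters only, so
# matches can never span the separator
collapse_db <- function(db) {
  paste(vapply(db$chains, `[[`, character(1), "sequence"), collapse = "\n")
}

count_in_text <- function(pattern, text) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

count_occurrences <- function(pattern, db) {
  count_in_text(pattern, collapse_db(db))
}

#' Verify that planted sequences occur exactly as specified
#'
#' Overlap-aware scan of each planted helix sequence against the query and
#' target databases; the sequence must occur exactly once in the query
#' database (its own helix) and exactly `n_occurrences` times in the target
#' database. Used internally by [generate_databases()], which regenerates
#' on violation.
#'
#' @param query_db,target_db The generated `chain_db`s.
#' @param planted The `truth$helices` data frame (needs `sequence` and
#'   `n_occurrences`).
#' @return Data frame with one row per distinct planted sequence:
#'   `sequence`, `expected_query`, `found_query`, `expected_target`,
#'   `found_target`, `ok`.
#' @export
verify_no_collisions <- function(query_db, target_db, planted) {
  if (is.null(planted) || !nrow(planted))
    return(data.frame(sequence = character(0), expected_query = integer(0),
                      found_query = integer(0), expected_target = integer(0),
                      found_target = integer(0), ok = logical(0)))
  agg <- stats::aggregate(
    cbind(expected_query = rep(1L, nrow(planted)),
          expected_target = planted$n_occurrences),
    by = list(sequence = planted$sequence), FUN = sum)
  qtext <- collapse_db(query_db)
  ttext <- collapse_db(target_db)
  agg$found_query <- vapply(agg$sequence, count_in_text, integer(1),
                            text = qtext)
  agg$found_target <- vapply(agg$sequence, count_in_text, integer(1),
                             text = ttext)
  agg$ok <- agg$found_query == agg$expected_query &
    agg$found_target == agg$expected_target
  agg[c("sequence", "expected_query", "found_query", "expected_target",
        "found_target", "ok")]
}

#' Serialize a ground-truth object as JSON
#'
#' @param truth The `truth` element of [generate_databases()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
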