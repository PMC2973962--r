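#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. `query` and `target`
#' may be chain-table paths or in-memory `chain_db` objects.
#'
#' @param query,target Chain-table paths or `chain_db`s.
#' @param out_dir Output directory (created if needed).
#' @param max_resolution,max_r,xray_only Structure-quality filter settings
#'   (applied to both databases).
#' @param min_helix_length Minimum helix length in residues.
#' @param flank_width Maximum flank width in residues.
#' @param exclude_self Exclude occurrences in the helix's own structure.
#' @param length_breaks Helix-length class boundaries of the
#'   length-versus-shift table.
#' @param rsa_bin_width Bin width of the accessibility histograms.
#' @param max_acc_table Optional path to a maximum-accessibility TSV
#'   (default: the built-in Gly-X-Gly table).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(query, target, out_dir,
                       max_resolution = 3.0, max_r = 0.3, xray_only = TRUE,
                       min_helix_length = 5L, flank_width = 4L,
                       exclude_self = TRUE,
                       length_breaks = c(0, 10, 15, 20, 30, Inf),
                       rsa_bin_width = 0.1, max_acc_table = NULL) {
  stopifnot(min_helix_length >= 1L, flank_width >= 1L,
            rsa_bin_width > 0, rsa_bin_width <= 1)
  structure(list(query = query, target = target, out_dir = out_dir,
                 max_resolution = max_resolution, max_r = max_r,
                 xray_only = xray_only,
                 min_helix_length = as.integer(min_helix_length),
                 flank_width = as.integer(flank_width),
                 exclude_self = exclude_self,
                 length_breaks = length_breaks,
                 rsa_bin_width = rsa_bin_width,
                 max_acc_table = max_acc_table),
            class = "run_config")
}

load_db <- function(x, role) {
  if (inherits(x, "chain_db")) return(x)
  read_chain_table(x, role = role)
}

#' Run the full ambivalent-helix analysis
#'
#' Executes every stage in order — structure-quality filtering of both
#' databases, helix extraction, exact cross-database mapping, per-helix
#' ambivalency records, conformational-parameter tables (conserved vs
#' variable, per bin, flanks by terminus), flank accessibility histograms
#' and the length-versus-shift summary — and writes each result as TSV
#' plus a machine-readable JSON manifest (package version, configuration,
#' record counts per stage) into `out_dir`. Reruns with the same
#' configuration and inputs produce byte-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every intermediate object and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  maxt <- if (is.null(config$max_acc_table)) max_acc_gxg() else
    read_max_acc(config$max_acc_table)

  query_raw <- load_db(config$query, "QUERY")
  target_raw <- load_db(config$target, "TARGET")
  query <- filter_chains(query_raw, config$max_resolution, config$max_r,
                         config$xray_only)
  target <- filter_chains(target_raw, config$max_resolution, config$max_r,
                          config$xray_only)

  helices <- extract_all_helices(query, config$min_helix_length)
  if (!nrow(helices))
    stop("no helices after filtering", call. = FALSE)
  occurrences <- map_all(helices, target,
                         exclude_self = config$exclude_self)
  occurrences$shift <- percent_shift(occurrences$target_ss)
  records <- ambivalency_records(helices, occurrences, query, target)
  background <- background_counts(query)

  cp_tables <- list()
  for (kl in c("CONSERVED", "VARIABLE")) {
    ids <- records$helix_id[records$klass == kl]
    seqs <- helices$sequence[match(ids, helices$helix_id)]
    seqs <- seqs[!helices$has_x[match(ids, helices$helix_id)]]
    if (length(seqs) && residue_counts(seqs)$total > 0)
      cp_tables[[kl]] <- compute_cp(residue_counts(seqs), background,
                                    group_name = kl)
  }
  # non-helical conformations of variable helices, counted per occurrence
  var_ids <- records$helix_id[records$klass == "VARIABLE"]
  occ_var <- occurrences[occurrences$helix_id %in% var_ids &
                           occurrences$shift == 100, , drop = FALSE]
  if (nrow(occ_var)) {
    seqs <- helices$sequence[match(occ_var$helix_id, helices$helix_id)]
    cp_tables[["VARIABLE_NONHELICAL"]] <-
      compute_cp(residue_counts(seqs), background,
                 group_name = "VARIABLE_NONHELICAL")
  }

  bins <- cp_by_bin(records, helices, background)
  flanks <- collect_flanks(records, helices, occurrences, query, target,
                           config$flank_width)
  fl_cp <- flank_cp(flanks, background)
  flanks <- flank_rsa_means(flanks, query, target, maxt)
  rsa_hist <- rsa_distribution(flanks, config$rsa_bin_width)
  ls_table <- length_shift_table(records, config$length_breaks)

  paths <- list(
    helices = file.path(config$out_dir, "helices.tsv"),
    helix_fasta = file.path(config$out_dir, "helices.fasta"),
    occurrences = file.path(config$out_dir, "occurrences.tsv"),
    ambivalency = file.path(config$out_dir, "ambivalency.tsv"),
    cp_classes = file.path(config$out_dir, "cp_classes.tsv"),
    cp_by_bin = file.path(config$out_dir, "cp_by_bin.tsv"),
    cp_flanks = file.path(config$out_dir, "cp_flanks.tsv"),
    rsa_histogram = file.path(config$out_dir, "rsa_histogram.tsv"),
    length_shift = file.path(config$out_dir, "length_shift.tsv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_helix_table(helices, paths$helices)
  write_helix_fasta(helices, paths$helix_fasta)
  write_occurrence_table(occurrences, paths$occurrences)
  write_ambivalency_table(records, paths$ambivalency)
  write_cp_table(cp_tables, paths$cp_classes)
  write_cp_table(bins, paths$cp_by_bin)
  write_cp_table(fl_cp, paths$cp_flanks)
  utils::write.table(rsa_hist, paths$rsa_histogram, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(ls_table$per_bin, paths$length_shift, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  class_counts <- table(factor(records$klass,
                               levels = c("CONSERVED", "PARTIAL",
                                          "VARIABLE", "UNMAPPED")))
  manifest <- list(
    package = "ambihelix",
    version = as.character(utils::packageVersion("ambihelix")),
    config = list(
      query = if (is.character(config$query)) config$query else
        paste0("<chain_db:", query_raw$name, ">"),
      target = if (is.character(config$target)) config$target else
        paste0("<chain_db:", target_raw$name, ">"),
      max_resolution = config$max_resolution, max_r = config$max_r,
      xray_only = config$xray_only,
      min_helix_length = config$min_helix_length,
      flank_width = config$flank_width,
      exclude_self = config$exclude_self,
      length_breaks = config$length_breaks,
      rsa_bin_width = config$rsa_bin_width),
    counts = list(
      query_chains_in = length(query_raw),
      query_chains_kept = length(query),
      target_chains_in = length(target_raw),
      target_chains_kept = length(target),
      helices = nrow(helices),
      helices_mapped = sum(records$klass != "UNMAPPED"),
      occurrences = nrow(occurrences),
      by_class = as.list(as.integer(class_counts) |>
                           stats::setNames(names(class_counts))),
      by_bin = as.list(stats::setNames(ls_table$per_bin$n_helices,
                                       ls_table$per_bin$bin))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(query = query, target = target, helices = helices,
                 occurrences = occurrences, records = records,
                 background = background, cp_tables = cp_tables,
                 cp_bins = bins, flanks = flanks, flank_cp = fl_cp,
                 rsa_histogram = rsa_hist, length_shift = ls_table,
                 manifest = manifest, paths = paths))
}

#' Read a pipeline configuration file
#'
#' JSON (always supported) or YAML (when the `yaml` package is installed)
#' file whose keys mirror the [run_config()] arguments.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("query", "target", "out_dir")
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop("config lacks required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}
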