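#' Read a well-level measurement table
#'
#' Reads a comma- or tab-delimited table (delimiter sniffed from the header
#' line) and validates the mandatory columns of the requested record type:
#' localization records need `plate_id, well, content, replicate, metric`;
#' reporter records need `plate_id, well, content, firefly, bgal`.
#' Unknown columns are kept untouched.
#'
#' @param path File path.
#' @param type `"localization"` or `"reporter"`.
#' @return Data.frame of typed records.
#' @export
read_well_table <- function(path, type = c("localization", "reporter")) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop("read_well_table: file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- switch(type,
                 localization = c("plate_id", "well", "content", "replicate",
                                  "metric"),
                 reporter = c("plate_id", "well", "content", "firefly",
                              "bgal"))
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("read_well_table: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- switch(type,
                     localization = c("replicate", "metric"),
                     reporter = c("firefly", "bgal"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(is.na(v) & !is.na(d[[cl]]) & nzchar(d[[cl]]))
    if (length(bad))
      stop("read_well_table: malformed numeric value in column '", cl,
           "', row ", bad[1], ": '", d[[cl]][bad[1]], "'", call. = FALSE)
    d[[cl]] <- v
  }
  if (type == "localization") d$replicate <- as.integer(d$replicate)
  d
}

#' Write a well or hit table as CSV
#'
#' @param x Data.frame.
#' @param path Output path (directory created if needed).
#' @return `path`, invisibly.
#' @export
write_well_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full screen run configuration
#'
#' Collects every tunable of the end-to-end simulated dual-modality screen:
#' library composition, plate formats and control schemes, the analysis
#' thresholds (FITC ratio classification at 0.4/0.65, top fraction 0.25,
#' nuclear Z cutoff -1.8, reporter fold cutoffs 0.5/2), noise levels and
#' the master seed. The configuration serializes losslessly to JSON.
#'
#' @param n_genes Library size.
#' @param n_dual_inhibitors Genes spiked as inhibitors in both modalities.
#' @param effect_magnitude Localization effect of spiked genes (SD units).
#' @param fold_magnitude Reporter effect of spiked genes (ratio).
#' @param overlap_fraction Fraction of localization hits also spiked in the
#'   reporter modality.
#' @param cell_lines Named numeric vector: cell line -> siMARK4 effect (SD
#'   units) in that line.
#' @param n_replicates Localization biological replicates.
#' @param baseline_pct_cytoplasmic Baseline localization metric (percent).
#' @param loc_well_sd Localization well SD (percent points).
#' @param rep_well_sdlog Reporter luminescence sdlog.
#' @param plate_effect_sd Reporter plate-factor sdlog.
#' @param yap_fold siYAP reporter effect.
#' @param t_nuclear,t_cytoplasmic FITC ratio class thresholds.
#' @param top_fraction Top fraction per replicate for cytoplasmic hits.
#' @param nuclear_cutoff Z cutoff for nuclear-direction hits.
#' @param fold_low,fold_high Reporter fold cutoffs.
#' @param loc_control_scheme,rep_control_scheme Control schemes (see
#'   [layout_plates()]; the reporter scheme is applied per plate).
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `screen_config` (a validated list).
#' @export
screen_config <- function(n_genes = 720L,
                          n_dual_inhibitors = 20L,
                          effect_magnitude = 3,
                          fold_magnitude = 0.3,
                          overlap_fraction = 1,
                          cell_lines = c(MDA_MB231 = 6, MDA_MB468 = 0),
                          n_replicates = 2L,
                          baseline_pct_cytoplasmic = 15,
                          loc_well_sd = 1,
                          rep_well_sdlog = 0.2,
                          plate_effect_sd = 0.15,
                          yap_fold = 0.2,
                          t_nuclear = 0.4,
                          t_cytoplasmic = 0.65,
                          top_fraction = 0.25,
                          nuclear_cutoff = -1.8,
                          fold_low = 0.5,
                          fold_high = 2.0,
                          loc_control_scheme = c(siCTL = 72, siMARK4 = 16),
                          rep_control_scheme = c(siCTL = 8, siYAP = 4),
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_dual_inhibitors = as.integer(n_dual_inhibitors),
              effect_magnitude = effect_magnitude,
              fold_magnitude = fold_magnitude,
              overlap_fraction = overlap_fraction,
              cell_lines = cell_lines,
              n_replicates = as.integer(n_replicates),
              baseline_pct_cytoplasmic = baseline_pct_cytoplasmic,
              loc_well_sd = loc_well_sd,
              rep_well_sdlog = rep_well_sdlog,
              plate_effect_sd = plate_effect_sd,
              yap_fold = yap_fold,
              t_nuclear = t_nuclear,
              t_cytoplasmic = t_cytoplasmic,
              top_fraction = top_fraction,
              nuclear_cutoff = nuclear_cutoff,
              fold_low = fold_low,
              fold_high = fold_high,
              loc_control_scheme = loc_control_scheme,
              rep_control_scheme = rep_control_scheme,
              seed = as.integer(seed))
  if (!(cfg$t_nuclear > 0 && cfg$t_nuclear < cfg$t_cytoplasmic))
    stop("screen_config: need 0 < t_nuclear < t_cytoplasmic", call. = FALSE)
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1)
    stop("screen_config: top_fraction must be in (0, 1]", call. = FALSE)
  if (!(cfg$fold_low > 0 && cfg$fold_low < cfg$fold_high))
    stop("screen_config: need 0 < fold_low < fold_high", call. = FALSE)
  if (is.null(names(cfg$cell_lines)) || length(cfg$cell_lines) < 1L)
    stop("screen_config: cell_lines must be a named vector", call. = FALSE)
  class(cfg) <- "screen_config"
  cfg
}

#' @rdname screen_config
#' @param x A `screen_config`.
#' @param path JSON file path.
#' @export
write_config <- function(x, path) {
  y <- unclass(x)
  # named atomic vectors must go out as objects, not bare arrays
  for (nm in c("cell_lines", "loc_control_scheme", "rep_control_scheme"))
    y[[nm]] <- as.list(y[[nm]])
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname screen_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cell_lines <- unlist(raw$cell_lines)
  raw$loc_control_scheme <- unlist(raw$loc_control_scheme)
  raw$rep_control_scheme <- unlist(raw$rep_control_scheme)
  do.call(screen_config, raw)
}

# md5 of the canonical JSON serialization, used to stamp outputs
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

# deterministic substream seeds below 2^31, one per (stage, cell line)
stage_seed <- function(seed, stage, line_idx = 0L) {
  offsets <- c(library = 1L, loc_layout = 2L, loc_sim = 3L,
               rep_layout = 4L, rep_sim = 5L, images = 6L)
  as.integer((as.numeric(seed) * 1009 + line_idx * 101 + offsets[[stage]]) %%
               2147483647)
}

#' Run the end-to-end simulated dual-modality screen
#'
#' Executes, for each configured cell line: library simulation, plate
#' layout, localization-well simulation over biological replicates, siCTL
#' normalization, screen-wide Z-scores, top-fraction replicate-intersection
#' and nuclear-cutoff hit calling; reporter plate layout and simulation,
#' beta-gal normalization, fold over plate median and fold-cutoff hit
#' calling; then modality intersection per line and cell-line intersection
#' across lines, with Venn region counts and a ranked hit report per line.
#' Every output file is stamped with the config hash and seed; a rerun with
#' the same config is bit-identical.
#'
#' @param config A [screen_config()].
#' @param outdir Output directory; created if needed. `NULL` skips writing.
#' @return (Invisibly) a list: per-line results (`wells`, `zscores`,
#'   `loc_hits`, `nuc_hits`, `reporter`, `rep_hits`, `dual_inhibitors`,
#'   `dual_activators`, `report`), `cross_line` hit sets, `venn`, `library`,
#'   `config_hash`, and a `log` of stage row counts.
#' @examples
#' res <- run_full_pipeline(screen_config(n_genes = 50, n_dual_inhibitors = 5,
#'                                        loc_control_scheme = c(siCTL = 8, siMARK4 = 4),
#'                                        seed = 3))
#' res$cross_line$dual_inhibitors
#' @export
run_full_pipeline <- function(config = screen_config(), outdir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  hash <- config_hash(config)
  log <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    message(line)
  }

  lib <- build_kinome_library(
    n_genes = config$n_genes,
    n_loc_inhibitors = config$n_dual_inhibitors,
    n_rep_inhibitors = config$n_dual_inhibitors,
    effect_magnitude = config$effect_magnitude,
    fold_magnitude = config$fold_magnitude,
    overlap_fraction = config$overlap_fraction,
    seed = stage_seed(config$seed, "library"))
  note("library: ", nrow(lib), " genes, ",
       sum(lib$loc_class != "null"), " localization / ",
       sum(lib$rep_class != "null"), " reporter spiked")

  lines <- names(config$cell_lines)
  per_line <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    loc_lay <- layout_plates(lib, 384, config$loc_control_scheme,
                             plate_prefix = paste0(ln, "_LOC"),
                             seed = stage_seed(config$seed, "loc_layout", i))
    wells <- simulate_localization_wells(
      loc_lay, lib,
      baseline_pct_cytoplasmic = config$baseline_pct_cytoplasmic,
      mark4_effect = config$cell_lines[[ln]],
      noise = noise_model(well_sd = config$loc_well_sd,
                          seed = stage_seed(config$seed, "loc_sim", i)),
      n_replicates = config$n_replicates)
    normed <- normalize_to_controls(wells)
    zs <- compute_zscores(normed)
    tops <- top_fraction(zs, config$top_fraction)
    loc_hits <- call_cytoplasmic_hits(tops)
    nuc_hits <- call_nuclear_hits(zs, config$nuclear_cutoff)
    note(ln, " localization: ", nrow(wells), " well records -> ",
         length(loc_hits), " cytoplasmic / ", length(nuc_hits),
         " nuclear hits")

    rep_lay <- layout_plates(lib, 96, config$rep_control_scheme,
                             per_plate = TRUE,
                             plate_prefix = paste0(ln, "_REP"),
                             seed = stage_seed(config$seed, "rep_layout", i))
    rw <- simulate_reporter_wells(
      rep_lay, lib, yap_fold = config$yap_fold,
      noise = noise_model(well_sd = config$rep_well_sdlog,
                          plate_effect_sd = config$plate_effect_sd,
                          seed = stage_seed(config$seed, "rep_sim", i)))
    folds <- fold_over_plate_median(normalize_reporter(rw))
    rep_hits <- call_reporter_hits(folds, config$fold_low, config$fold_high)
    note(ln, " reporter: ", nrow(rw), " wells -> ",
         sum(rep_hits$inhibitor), " inhibitors / ",
         sum(rep_hits$activator), " activators")

    dual_inh <- intersect_modalities(loc_hits,
                                     rep_hits$gene_id[rep_hits$inhibitor])
    dual_act <- intersect_modalities(nuc_hits,
                                     rep_hits$gene_id[rep_hits$activator])
    per_line[[ln]] <- list(wells = normed, zscores = zs,
                           loc_hits = loc_hits, nuc_hits = nuc_hits,
                           reporter = folds, rep_hits = rep_hits,
                           dual_inhibitors = dual_inh,
                           dual_activators = dual_act)
  }

  cross <- list()
  venn <- list()
  if (length(lines) >= 2L) {
    cross$dual_inhibitors <- intersect_cell_lines(
      lapply(per_line, `[[`, "dual_inhibitors"))
    cross$dual_activators <- intersect_cell_lines(
      lapply(per_line, `[[`, "dual_activators"))
    venn$localization <- venn_counts(lapply(per_line, `[[`, "loc_hits"))
    venn$dual_inhibitors <- venn_counts(
      lapply(per_line, `[[`, "dual_inhibitors"))
    note("cross-line: ", length(cross$dual_inhibitors),
         " dual-modality inhibitors common to all lines")
  }
  for (ln in lines) {
    pl <- per_line[[ln]]
    per_line[[ln]]$report <- build_hit_report(
      pl$zscores, pl$rep_hits,
      loc_hits = pl$loc_hits, nuc_hits = pl$nuc_hits,
      rep_inhibitors = pl$rep_hits$gene_id[pl$rep_hits$inhibitor],
      rep_activators = pl$rep_hits$gene_id[pl$rep_hits$activator],
      cross_line_hits = c(cross$dual_inhibitors, cross$dual_activators))
  }

  res <- list(per_line = per_line, cross_line = cross, venn = venn,
              library = lib, config = config, config_hash = hash, log = log)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- data.frame(config_hash = hash, seed = config$seed)
    write_well_table(stamp, file.path(outdir, "run_stamp.csv"))
    write_config(config, file.path(outdir, "config.json"))
    for (ln in lines) {
      write_well_table(per_line[[ln]]$wells,
                       file.path(outdir, paste0(ln, "_localization_wells.csv")))
      write_well_table(per_line[[ln]]$zscores,
                       file.path(outdir, paste0(ln, "_zscores.csv")))
      write_well_table(per_line[[ln]]$reporter,
                       file.path(outdir, paste0(ln, "_reporter_wells.csv")))
      write_well_table(per_line[[ln]]$report,
                       file.path(outdir, paste0(ln, "_hit_report.csv")))
    }
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, cross_line = cross,
           venn = venn, log = log),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
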