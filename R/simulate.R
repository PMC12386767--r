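#' Simulate well-level localization measurements
#'
#' Produces the per-well "percent cytoplasmic-translocated cells" metric for
#' every occupied well of the supplied layouts, for `n_replicates` biological
#' replicates. Null genes and siCTL wells are drawn from the baseline
#' distribution; spiked genes are shifted by `loc_effect * effect_sd` and
#' siMARK4 positive-control wells by `mark4_effect * effect_sd`. Gaussian
#' well noise of SD `noise$well_sd` is added and values are clamped to
#' `[0, 100]` (silently; values at the bounds are legal).
#'
#' @param layouts Layout data.frame from [layout_plates()].
#' @param library Library data.frame from [build_kinome_library()].
#' @param baseline_pct_cytoplasmic Baseline metric (percent, in `[0, 100]`).
#' @param mark4_effect Shift of siMARK4 wells, in `effect_sd` units. The
#'   MDA-MB231-like condition uses a large value (clear separation from
#'   siCTL); the MDA-MB468-like condition uses 0 (overlapping controls).
#' @param noise A [noise_model()].
#' @param n_replicates Biological replicates.
#' @param effect_sd Scale (percent points) converting effect sizes in SD
#'   units into metric shifts; defaults to `noise$well_sd`. Making it
#'   explicit keeps effects alive in the noiseless limit `well_sd = 0`.
#' @return Data.frame of well records: `plate_id`, `well`, `content`,
#'   `replicate`, `metric`. Wells with content `"empty"` yield no record.
#' @examples
#' lib <- build_kinome_library(10)
#' lay <- layout_plates(lib, 96, c(siCTL = 4), seed = 1)
#' simulate_localization_wells(lay, lib, noise = noise_model(seed = 7))
#' @export
simulate_localization_wells <- function(layouts, library,
                                        baseline_pct_cytoplasmic = 15,
                                        mark4_effect = 6,
                                        noise = noise_model(),
                                        n_replicates = 2L,
                                        effect_sd = NULL) {
  if (is.null(layouts) || nrow(layouts) == 0L)
    stop("simulate_localization_wells: empty layouts", call. = FALSE)
  if (baseline_pct_cytoplasmic < 0 || baseline_pct_cytoplasmic > 100)
    stop("simulate_localization_wells: baseline_pct_cytoplasmic must be in [0, 100]",
         call. = FALSE)
  if (is.null(effect_sd)) effect_sd <- noise$well_sd
  occ <- layouts[layouts$content != "empty", , drop = FALSE]
  effects <- structure(library$loc_effect, names = library$gene_id)
  shift <- numeric(nrow(occ))
  is_gene <- occ$content %in% names(effects)
  shift[is_gene] <- effects[occ$content[is_gene]]
  shift[occ$content == "siMARK4"] <- mark4_effect
  unknown <- !is_gene & !(occ$content %in% .control_labels)
  if (any(unknown))
    stop("simulate_localization_wells: content not in library or controls: ",
         paste(unique(occ$content[unknown]), collapse = ", "), call. = FALSE)

  set.seed(noise$seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    metric <- baseline_pct_cytoplasmic + shift * effect_sd +
      stats::rnorm(nrow(occ), 0, noise$well_sd)
    data.frame(plate_id = occ$plate_id, well = occ$well,
               content = occ$content, replicate = r,
               metric = pmin(pmax(metric, 0), 100),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, reps)
  rownames(res) <- NULL
  res
}

#' Simulate TEAD-reporter luminescence wells
#'
#' Each well gets a firefly-luciferase reading and a beta-galactosidase
#' reading. Both share a per-plate multiplicative factor (transfection
#' efficiency), so the firefly/beta-gal ratio cancels it; firefly is
#' additionally scaled by the silenced gene's `rep_effect` (or `yap_fold`
#' for siYAP positive controls) and each reading carries independent
#' lognormal noise with sdlog `noise$well_sd`.
#'
#' @param layouts Layout data.frame from [layout_plates()].
#' @param library Library data.frame from [build_kinome_library()].
#' @param baseline_firefly,baseline_bgal Baseline counts (> 0).
#' @param yap_fold Multiplicative effect of siYAP on the reporter (> 0).
#' @param noise A [noise_model()]; `well_sd` is the luminescence sdlog.
#' @return Data.frame: `plate_id`, `well`, `content`, `replicate`,
#'   `firefly`, `bgal`.
#' @examples
#' lib <- build_kinome_library(10)
#' lay <- layout_plates(lib, 96, c(siCTL = 8, siYAP = 4), per_plate = TRUE)
#' simulate_reporter_wells(lay, lib, noise = noise_model(well_sd = 0.2))
#' @export
simulate_reporter_wells <- function(layouts, library,
                                    baseline_firefly = 5e5,
                                    baseline_bgal = 1e3,
                                    yap_fold = 0.2,
                                    noise = noise_model(well_sd = 0.2)) {
  if (is.null(layouts) || nrow(layouts) == 0L)
    stop("simulate_reporter_wells: empty layouts", call. = FALSE)
  if (baseline_firefly <= 0 || baseline_bgal <= 0)
    stop("simulate_reporter_wells: baselines must be > 0", call. = FALSE)
  if (yap_fold <= 0)
    stop("simulate_reporter_wells: 'yap_fold' must be > 0", call. = FALSE)
  occ <- layouts[layouts$content != "empty", , drop = FALSE]
  effects <- structure(library$rep_effect, names = library$gene_id)
  eff <- rep(1, nrow(occ))
  is_gene <- occ$content %in% names(effects)
  eff[is_gene] <- effects[occ$content[is_gene]]
  eff[occ$content == "siYAP"] <- yap_fold
  unknown <- !is_gene & !(occ$content %in% .control_labels)
  if (any(unknown))
    stop("simulate_reporter_wells: content not in library or controls: ",
         paste(unique(occ$content[unknown]), collapse = ", "), call. = FALSE)

  set.seed(noise$seed)
  plates <- sort(unique(occ$plate_id))
  plate_factor <- stats::setNames(
    exp(stats::rnorm(length(plates), 0, noise$plate_effect_sd)), plates)
  pf <- plate_factor[occ$plate_id]
  firefly <- baseline_firefly * pf * eff *
    exp(stats::rnorm(nrow(occ), 0, noise$well_sd))
  bgal <- baseline_bgal * pf *
    exp(stats::rnorm(nrow(occ), 0, noise$well_sd))
  res <- data.frame(plate_id = occ$plate_id, well = occ$well,
                    content = occ$content, replicate = 1L,
                    firefly = firefly, bgal = bgal,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
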