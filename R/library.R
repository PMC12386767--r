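#' Build a synthetic kinome siRNA library with known ground truth
#'
#' Creates a library of `n_genes` screened genes, a chosen number of which are
#' spiked as localization-modality hits (shifting the percent-cytoplasmic well
#' metric when silenced) and/or reporter-modality hits (scaling the normalized
#' TEAD-reporter signal when silenced). The remaining genes are nulls. The
#' returned table doubles as the simulation ground truth: `loc_class` /
#' `rep_class` record each gene's true role per modality.
#'
#' Localization inhibitors (genes whose knockdown releases Hippo inhibition
#' and drives YAP/TAZ to the cytoplasm) get `loc_effect = +effect_magnitude`
#' (control-SD units; positive = cytoplasmic shift); localization activators
#' get `-effect_magnitude`. Reporter inhibitors get
#' `rep_effect = fold_magnitude`; reporter activators `1 / fold_magnitude`.
#' `overlap_fraction` controls the fraction of localization hits (per
#' direction) that are also reporter hits, modelling bona fide Hippo pathway
#' regulators detectable in both modalities.
#'
#' @param n_genes Library size.
#' @param n_loc_inhibitors,n_loc_activators Spiked localization hits.
#' @param n_rep_inhibitors,n_rep_activators Spiked reporter hits.
#' @param effect_magnitude Localization effect size, control-SD units (> 0).
#' @param fold_magnitude Reporter inhibitor multiplicative effect (> 0,
#'   conventionally < 1); activators get its reciprocal.
#' @param overlap_fraction Fraction of localization hits that are also
#'   reporter hits, in `[0, 1]`.
#' @param seed Integer seed; identical calls reproduce the same assignment.
#' @return A data.frame with columns `gene_id`, `symbol`, `loc_effect`,
#'   `rep_effect`, `loc_class`, `rep_class` (classes are one of
#'   `"inhibitor"`, `"activator"`, `"null"`).
#' @examples
#' lib <- build_kinome_library(100, n_loc_inhibitors = 10,
#'                             effect_magnitude = 3, seed = 1)
#' table(lib$loc_class)
#' @export
build_kinome_library <- function(n_genes = 720L,
                                 n_loc_inhibitors = 0L,
                                 n_loc_activators = 0L,
                                 n_rep_inhibitors = 0L,
                                 n_rep_activators = 0L,
                                 effect_magnitude = 3,
                                 fold_magnitude = 0.3,
                                 overlap_fraction = 1,
                                 seed = 1L) {
  counts <- c(n_genes = n_genes,
              n_loc_inhibitors = n_loc_inhibitors,
              n_loc_activators = n_loc_activators,
              n_rep_inhibitors = n_rep_inhibitors,
              n_rep_activators = n_rep_activators)
  for (nm in names(counts)) {
    if (counts[[nm]] < 0 || counts[[nm]] != round(counts[[nm]]))
      stop("build_kinome_library: '", nm, "' must be a non-negative integer",
           call. = FALSE)
  }
  if (n_loc_inhibitors + n_loc_activators > n_genes)
    stop("build_kinome_library: n_loc_inhibitors + n_loc_activators exceeds n_genes",
         call. = FALSE)
  if (n_rep_inhibitors + n_rep_activators > n_genes)
    stop("build_kinome_library: n_rep_inhibitors + n_rep_activators exceeds n_genes",
         call. = FALSE)
  if (effect_magnitude <= 0)
    stop("build_kinome_library: 'effect_magnitude' must be > 0", call. = FALSE)
  if (fold_magnitude <= 0)
    stop("build_kinome_library: 'fold_magnitude' must be > 0", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("build_kinome_library: 'overlap_fraction' must be in [0, 1]",
         call. = FALSE)

  gene_id <- sprintf("KIN%04d", seq_len(n_genes))
  lib <- data.frame(gene_id = gene_id,
                    symbol = sprintf("KINASE%04d", seq_len(n_genes)),
                    loc_effect = rep(0, n_genes),
                    rep_effect = rep(1, n_genes),
                    loc_class = rep("null", n_genes),
                    rep_class = rep("null", n_genes),
                    stringsAsFactors = FALSE)
  if (n_genes == 0L) return(lib)

  set.seed(as.integer(seed))
  pool <- sample(gene_id)  # one shuffle drives every assignment
  loc_inh <- pool[seq_len(n_loc_inhibitors)]
  loc_act <- pool[n_loc_inhibitors + seq_len(n_loc_activators)]
  loc_hits <- c(loc_inh, loc_act)

  pick_rep <- function(loc_same_dir, n_rep) {
    # share round(overlap_fraction * min(...)) genes with the localization
    # hits of the same direction, fill the rest from untouched nulls
    n_shared <- as.integer(round(overlap_fraction * min(length(loc_same_dir), n_rep)))
    shared <- loc_same_dir[seq_len(n_shared)]
    free <- setdiff(pool, c(loc_hits, .picked))
    if (n_rep - n_shared > length(free))
      stop("build_kinome_library: hit counts with this 'overlap_fraction' ",
           "exceed the available null genes", call. = FALSE)
    fresh <- free[seq_len(n_rep - n_shared)]
    .picked <<- c(.picked, fresh)
    c(shared, fresh)
  }
  .picked <- character(0)
  rep_inh <- pick_rep(loc_inh, n_rep_inhibitors)
  rep_act <- pick_rep(loc_act, n_rep_activators)

  lib$loc_effect[lib$gene_id %in% loc_inh] <- effect_magnitude
  lib$loc_effect[lib$gene_id %in% loc_act] <- -effect_magnitude
  lib$loc_class[lib$gene_id %in% loc_inh] <- "inhibitor"
  lib$loc_class[lib$gene_id %in% loc_act] <- "activator"
  lib$rep_effect[lib$gene_id %in% rep_inh] <- fold_magnitude
  lib$rep_effect[lib$gene_id %in% rep_act] <- 1 / fold_magnitude
  lib$rep_class[lib$gene_id %in% rep_inh] <- "inhibitor"
  lib$rep_class[lib$gene_id %in% rep_act] <- "activator"
  lib
}
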