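#' EPP configuration
#'
#' All tunable parameters of the gating algorithm with their defaults. The
#' algorithm is deterministic; there is no seed.
#'
#' @param W_init initial kernel standard deviation as a fraction of full
#'   scale: 0.01 for fluorescence, 0.025 for mass cytometry.
#' @param W_max give up widening a dimension pair beyond this kernel width.
#' @param grid_size density grid nodes per axis (2^k + 1; default 257).
#' @param sigma noise-floor significance parameter (window mass must exceed
#'   `sigma^2` events).
#' @param dbm_z standard-error multiplier of the density-dip test.
#' @param dbm_both_modes require the dip significant against both modes.
#' @param kld_threshold_normal,kld_threshold_exponential qualification
#'   thresholds on the divergence from the normal / exponential reference.
#' @param exponential_test apply the exponential reference test; `NULL`
#'   means "in mass mode only".
#' @param max_clusters widen the kernel when modal clustering founds more
#'   clusters than this.
#' @param max_edges widen the kernel when the cluster graph has more edges
#'   than this (bit-vector capacity).
#' @param mode split selection: `"best_balance"` weighs the boundary score
#'   by 4P(1-P); `"best_separation"` uses the raw events-near-boundary
#'   score.
#' @param cytometry `"fluorescence"` or `"mass"`; sets the default `W_init`
#'   and whether the exponential qualification test runs.
#' @param min_events_abs,min_events_rel stop recursing into populations
#'   smaller than this absolute count / fraction of the root (defaults 0:
#'   off).
#' @param rdp_tolerance polygon simplification tolerance, fraction of full
#'   scale.
#' @return an `epp_config` list.
#' @export
epp_config <- function(W_init = NULL, W_max = 0.2, grid_size = 257L,
                       sigma = 3, dbm_z = 3, dbm_both_modes = TRUE,
                       kld_threshold_normal = 0.04,
                       kld_threshold_exponential = 0.2,
                       exponential_test = NULL,
                       max_clusters = 12L, max_edges = 32L,
                       mode = c("best_balance", "best_separation"),
                       cytometry = c("fluorescence", "mass"),
                       min_events_abs = 0L, min_events_rel = 0,
                       rdp_tolerance = 0.01) {
  mode <- match.arg(mode)
  cytometry <- match.arg(cytometry)
  if (is.null(W_init)) W_init <- if (cytometry == "mass") 0.025 else 0.01
  stopifnot(W_init > 0, W_max >= W_init, grid_size >= 17, sigma > 0,
            dbm_z > 0, kld_threshold_normal > 0,
            kld_threshold_exponential > 0, max_clusters >= 1,
            max_edges >= 1, min_events_abs >= 0, min_events_rel >= 0,
            rdp_tolerance >= 0)
  structure(list(W_init = W_init, W_max = W_max,
                 grid_size = as.integer(grid_size), sigma = sigma,
                 dbm_z = dbm_z, dbm_both_modes = dbm_both_modes,
                 kld_threshold_normal = kld_threshold_normal,
                 kld_threshold_exponential = kld_threshold_exponential,
                 exponential_test = exponential_test,
                 max_clusters = as.integer(max_clusters),
                 max_edges = as.integer(max_edges), mode = mode,
                 cytometry = cytometry,
                 min_events_abs = as.integer(min_events_abs),
                 min_events_rel = min_events_rel,
                 rdp_tolerance = rdp_tolerance),
            class = "epp_config")
}
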