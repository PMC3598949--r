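#' Parameters for direct sampling of per-element scalar fields
#'
#' The direct-field mode emulates the structure of the solved problem --
#' predominantly compressive hydrostatic stress in the coronal follicle cap
#' and tensile stress in the apical cap -- without running a solve, so the
#' analysis stages can be exercised and calibrated on their own. Hydrostatic
#' stresses are Gaussian per cap; element volumes are log-normal (the
#' follicle of an unstructured anatomical mesh has strongly right-skewed
#' element volumes; the defaults give a mean element volume of about
#' 0.01 mm^3, matching a follicle of ~2000 mm^3 meshed into ~190k elements).
#'
#' @param n_coronal,n_apical Element counts per cap (>= 1).
#' @param mu_c Mean coronal hydrostatic stress, MPa (negative = compression).
#' @param mu_a Mean apical hydrostatic stress, MPa.
#' @param sigma Stress spread, MPa (>= 0).
#' @param vol_meanlog,vol_sdlog Log-mean and log-sd of element volume (mm^3).
#' @param seed Integer seed.
#' @return A `direct_field_params` list.
#' @export
direct_field_params <- function(n_coronal = 5000, n_apical = 5000,
                                mu_c = -0.02, mu_a = 0.02, sigma = 0.005,
                                vol_meanlog = log(0.01), vol_sdlog = 0.5,
                                seed = 1L) {
  if (n_coronal < 1 || n_apical < 1) stop("element counts must be >= 1")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(vol_sdlog) || vol_sdlog < 0) stop("vol_sdlog must be >= 0")
  structure(list(n_coronal = as.integer(n_coronal),
                 n_apical = as.integer(n_apical),
                 mu_c = mu_c, mu_a = mu_a, sigma = sigma,
                 vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
                 seed = as.integer(seed)),
            class = "direct_field_params")
}

#' Sample per-element scalar records directly from stated distributions
#'
#' Coronal hydrostatic stresses are drawn `Normal(mu_c, sigma)`, apical
#' `Normal(mu_a, sigma)`; volumes are log-normal and strictly positive; the
#' BRU field is filled as stress x volume. Fully reproducible under the
#' stored seed. Equivalent strain is not part of the sampled model and is
#' left `NA` (the cap analysis does not consume it).
#'
#' @param params A [direct_field_params()].
#' @return List with elements `coronal` and `apical`, each an
#'   `element_records` data frame (columns `element`, `region`, `volume`,
#'   `sigma_h`, `s_e`, `bru`).
#' @export
sample_direct_fields <- function(params) {
  stopifnot(inherits(params, "direct_field_params"))
  set.seed(params$seed)
  draw <- function(n, mu, region) {
    sigma_h <- stats::rnorm(n, mean = mu, sd = params$sigma)
    volume <- stats::rlnorm(n, meanlog = params$vol_meanlog,
                            sdlog = params$vol_sdlog)
    rec <- data.frame(element = seq_len(n), region = region,
                      volume = volume, sigma_h = sigma_h,
                      s_e = NA_real_, bru = bru(sigma_h, volume))
    class(rec) <- c("element_records", "data.frame")
    rec
  }
  list(coronal = draw(params$n_coronal, params$mu_c, "follicle_pdl"),
       apical = draw(params$n_apical, params$mu_a, "follicle_pdl"))
}
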