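#' Default acoustic and thermal tissue properties
#'
#' Property table used throughout the package for prostate-scene and
#' ex-vivo simulations.  Values are the standard ones used in the
#' catheter-based ultrasound thermal-therapy modeling literature:
#' attenuation (assumed equal to absorption) around 0.45-0.6 dB/cm/MHz
#' depending on tissue, conductivities near 0.5 W/m/degC and volumetric
#' heat capacities near 3.9e6 J/m3/degC.  Nominal perfusion for prostate
#' is the moderate 2.5 kg/m3/s of the planning sweep; ex-vivo runs set
#' perfusion to zero explicitly.
#'
#' @return named list of [TissueProperties-class]: `prostate`, `tumor`,
#'   `urethra`, `rectum_wall`, `background`, `muscle`, `liver`.
#' @examples
#' defaultTissueTable()$prostate
#' @export
defaultTissueTable <- function() {
  tt <- list(
    prostate    = TissueProperties("prostate",    alpha = 5.75, k = 0.51,
                                   rho = 1045, c = 3760, wb = 2.5),
    tumor       = TissueProperties("tumor",       alpha = 5.75, k = 0.51,
                                   rho = 1045, c = 3760, wb = 2.5),
    urethra     = TissueProperties("urethra",     alpha = 5.75, k = 0.53,
                                   rho = 1045, c = 3760, wb = 2.5),
    rectum_wall = TissueProperties("rectum_wall", alpha = 5.75, k = 0.55,
                                   rho = 1045, c = 3760, wb = 2.5),
    ## unsegmented surround defaults to generic prostatic/soft tissue
    background  = TissueProperties("background",  alpha = 5.75, k = 0.51,
                                   rho = 1045, c = 3760, wb = 2.5),
    muscle      = TissueProperties("muscle",      alpha = 6.60, k = 0.49,
                                   rho = 1050, c = 3600, wb = 0.7),
    liver       = TissueProperties("liver",       alpha = 5.20, k = 0.52,
                                   rho = 1050, c = 3600, wb = 16)
  )
  tt
}
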