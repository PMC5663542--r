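#' Treatment registry for the melanoma ICI network
#'
#' The ten regimens compared in the network plus the auxiliary
#' glycoprotein-100 vaccine node (`GP100`).  gp100 alone was only ever a
#' control arm; it participates in the likelihood so that the three-arm
#' trial that used it keeps its within-trial randomization, but it is
#' excluded from league tables and rankings (`reportable = FALSE`).
#'
#' @return A data.frame with columns `id`, `label` and `reportable`.
#'   `CHE` (chemotherapy) is the designated network reference treatment.
#' @export
#' @examples
#' melanoma_treatments()
melanoma_treatments <- function() {
  data.frame(
    id = c("CHE", "IPI", "TRE", "NIV", "PEM",
           "IPI_CHE", "IPI_NIV", "IPI_GP100", "IPI_BUD", "IPI_SAR",
           "GP100"),
    label = c("chemotherapy", "ipilimumab", "tremelimumab", "nivolumab",
              "pembrolizumab", "ipilimumab plus chemotherapy",
              "ipilimumab plus nivolumab", "ipilimumab plus gp100",
              "ipilimumab plus budesonide", "ipilimumab plus sargramostim",
              "gp100"),
    reportable = c(rep(TRUE, 10), FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default network reference treatment
#'
#' Chemotherapy is the most connected node of the evidence network and is
#' used as the reference against which basic parameters are defined.
#' @return A treatment id string.
#' @export
reference_treatment <- function() "CHE"
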