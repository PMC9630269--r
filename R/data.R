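#' Ct values of 10 candidate reference genes in six Himalayan livestock species
#'
#' The packaged study data set: average raw Ct values of 10 candidate
#' reference genes (GAPDH, ACTB, RPS9, EEF1A1, RPS15, RPS23, UXT, RPL4,
#' B2M, HPRT1) measured by RT-qPCR in peripheral blood mononuclear cells
#' of 32 animals from six livestock species native to the trans-Himalayan
#' Leh-Ladakh region: Ladakhi cattle (LAC, 6 animals), Ladakhi yak (LAY, 6),
#' Ladakhi donkey (LAD, 5), Changthangi goat (CHG, 5), double-hump camel
#' (DHC, 5) and Zanskar pony (ZAP, 5). Values are stored at the 3-decimal
#' precision of the published table; no attempt is made to recover further
#' digits.
#'
#' @return A [ct_matrix()] with 10 genes, 32 samples and the species code as
#'   group label.
#' @examples
#' ct <- ladakh_pbmc()
#' table(ct_groups(ct))
#' @export
ladakh_pbmc <- function() {
  read_ct(system.file("extdata", "ladakh_pbmc_ct.csv", package = "refstab",
                      mustWork = TRUE),
          layout = "wide",
          annotation = system.file("extdata", "ladakh_pbmc_samples.csv",
                                   package = "refstab", mustWork = TRUE))
}
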