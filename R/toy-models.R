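#' Minimal three-level chain food web
#'
#' Producer -> herbivore -> carnivore on a detritus base, with one artisanal
#' fleet landing the carnivore. Useful for worked examples and as a fixture
#' with hand-checkable balance and trophic levels (1, 2, 3).
#'
#' @return an (unbalanced) `ecopath_model`; pass to [solve_mass_balance()].
#' @export
toy_chain_model <- function() {
  groups <- data.frame(
    name = c("producer", "herbivore", "carnivore", "detritus"),
    category = c("producer", "consumer", "consumer", "detritus"),
    B = c(10, 1, 0.2, 5),
    PB = c(10, 2, 0.8, NA),
    QB = c(0, 8, 3, NA),
    EE = NA_real_,
    GS = c(0, 0.3, 0.2, 0),
    BA = 0,
    net_migration = 0,
    role_tags = c("", "forage", "", ""))
  diet <- matrix(0, 4, 4, dimnames = list(groups$name, groups$name))
  diet["producer", "herbivore"] <- 0.9
  diet["detritus", "herbivore"] <- 0.1
  diet["herbivore", "carnivore"] <- 1
  landings <- matrix(c(0, 0, 0.05, 0), ncol = 1,
                     dimnames = list(groups$name, "artisanal"))
  ecopath_model(groups, diet, landings = landings)
}
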