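# Synthetic per-branch omega (dN/dS): lognormal around category-specific
# medians, with an extra multiplier on branches carrying an expression
# shift. Emulates the qualitative structure seen in vertebrate gene
# families (duplication- and retrotransposition-descended branches evolve
# faster; shift branches differ from their sisters).

#' Parameters for omega simulation
#'
#' @param median_s,median_d,median_r Category medians of omega.
#' @param shift_multiplier Multiplicative effect applied to a branch's
#'   omega when it carries a true expression shift.
#' @param sdlog Lognormal spread.
#' @param seed Integer seed.
#' @return An `omega_sim_params` list.
#' @export
omega_sim_params <- function(median_s = 0.10, median_d = 0.20,
                             median_r = 0.25, shift_multiplier = 1.5,
                             sdlog = 0.5, seed = 1) {
  stopifnot(median_s > 0, median_d > 0, median_r > 0,
            shift_multiplier > 0, sdlog >= 0)
  structure(list(median = c(S = median_s, D = median_d, R = median_r),
                 shift_multiplier = shift_multiplier, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "omega_sim_params")
}

#' Simulate per-branch omega values for a gene family
#'
#' @param family A `gene_family` with a tree.
#' @param shift_branches Branch IDs carrying true expression shifts.
#' @param params An [omega_sim_params()] list.
#' @return Named numeric vector, branch ID -> omega.
#' @export
simulate_omega <- function(family, shift_branches = character(),
                           params = omega_sim_params()) {
  stopifnot(!is.null(family$tree))
  set.seed(derive_seed(params$seed, "omega"))
  bid <- branch_ids(family$tree)
  med <- params$median[family$branch_category[bid]]
  mult <- ifelse(bid %in% shift_branches, params$shift_multiplier, 1)
  stats::setNames(
    med * mult * exp(stats::rnorm(length(bid), 0, params$sdlog)), bid)
}
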