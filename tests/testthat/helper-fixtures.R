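# Shared fixtures: the reference state used throughout the sensitivity
# analyses (drivers held constant while one is swept), and default traits.

ref_traits <- function() hydraulic_traits(-2, 3, rp_min = 1, rp_units = "per_mmol")

ref_env <- function(...) {
  args <- utils::modifyList(
    list(ipar = 600e-6, t_air = 25, ca = 36, patm = 101325,
         d = 0.5 * 1000 / 101325, psi_pd = -0.5),
    list(...))
  do.call(leaf_env, args)
}

# random valid hydraulic traits for property loops
random_traits <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    hydraulic_traits(psi50 = runif(1, -6, -0.5),
                     shape_a = runif(1, 1, 10),
                     rp_min = runif(1, 100, 5000)))
}

# internal-unit driver grid over predawn potential
psi_grid <- function(n = 25, lo = -5, hi = -0.1, d = 0.01) {
  data.frame(ipar = 600e-6, t_air = 25, ca = 36, patm = 101325,
             d = d, psi_pd = seq(lo, hi, length.out = n))
}
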