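# Shared fixtures: small, deterministic configurations built in code.

# solution (diffusion-only) run with the bench solution-experiment setup
solution_config <- function(P = 0.289, X0 = 100, Vs = 0.5) {
  experiment_config(
    initial_amount = X0, donor_volume = 0.58, receptor_volume = 1.5,
    drug = drug_properties(permeability = P),
    schedule = diffusion_schedule(sample_volume = Vs))
}

# particle run on the synthetic lognormal PSD (MMAD 3.7 um, GSD 1.8, 23 ug)
particle_config <- function(Cs = 5.3, X0 = 23, F = 0.0244,
                            schedule = sampling_schedule(),
                            psd = synthetic_psd(total_mass = X0)) {
  experiment_config(
    initial_amount = X0, donor_volume = 0.58, receptor_volume = 1.5,
    psd = psd, correction_factor = F,
    medium = medium_properties(Cs), schedule = schedule)
}

# mass-balance check: X_d + Y + S + sum(X_i) == X_initial at every time
mass_balance_error <- function(sim) {
  bal <- sim$donor_dissolved + sim$receptor_amount + sim$removed_cumulative +
    (if (is.null(sim$per_bin_mass)) 0 else rowSums(sim$per_bin_mass))
  max(abs(bal - sim$config$initial_amount)) / sim$config$initial_amount
}

# exact Weibull profile at given sampling times
weibull_profile <- function(times_min, mdt_min, b) {
  transfer_profile(times_min, 100 * (1 - exp(-(times_min / mdt_min)^b)))
}
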