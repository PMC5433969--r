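# Fixture builders shared across the suite. All data are generated in
# code; nothing is read from disk.

# records lying exactly on ln M = b ln L + log_a (no noise)
power_law_records <- function(n = 12, b = 2, log_a = -9,
                              lengths = seq(60, 170, length.out = n)) {
  data.frame(id = sprintf("R%02d", seq_len(n)), sex = "male",
             date = as.Date("2014-03-01") + seq_len(n),
             cod_class = rep(c("acute", "chronic"), length.out = n),
             age_class = cetacond::assign_age_class(lengths),
             season = "nonbreeding",
             mass_kg = exp(b * log(lengths) + log_a),
             length_cm = lengths, girth_cm = 0.62 * lengths,
             blubber_dorsal_mm = 12, blubber_lateral_mm = 13,
             blubber_ventral_mm = 14, stringsAsFactors = FALSE)
}

# random records with lognormal scatter about a power law
noisy_records <- function(n = 10, b = 2.3, log_a = -10, sd = 0.1,
                          seed = 42) {
  set.seed(seed)
  lengths <- runif(n, 70, 170)
  r <- power_law_records(n, b, log_a, lengths)
  r$mass_kg <- r$mass_kg * exp(rnorm(n, 0, sd))
  r
}

# a default generator config shared by tests (seed fixed per test site)
default_config <- function(seed = 1, ...) cetacond::synth_config(seed = seed, ...)
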