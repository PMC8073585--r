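# Builders for synthetic chromatographic traces used across test files.

gaussian_trace <- function(amplitude = 1e4, apex = 20, sigma = 0.08,
                           from = 19, to = 21, step = 0.005,
                           fragment = "y3") {
  t <- seq(from, to, by = step)
  data.frame(fragment = fragment, time_min = t,
             intensity = amplitude * exp(-(t - apex)^2 / (2 * sigma^2)))
}

flat_trace <- function(level = 0, from = 19, to = 21, step = 0.01,
                       fragment = "y3") {
  t <- seq(from, to, by = step)
  data.frame(fragment = fragment, time_min = t,
             intensity = rep(level, length(t)))
}

# closed-form area of a Gaussian peak
gaussian_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

random_tryptic_peptide <- function(min_len = 5, max_len = 14) {
  body <- sample(setdiff(names(aa_mass_table()$residue_mass), c("K", "R")),
                 sample(min_len:max_len, 1) - 1L, replace = TRUE)
  paste0(paste0(body, collapse = ""), sample(c("K", "R"), 1))
}
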