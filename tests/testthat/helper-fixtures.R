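# Shared fixtures: a clean (noise- and crosstalk-free) measurement model and
# the default serine-junction reference pair.

clean_params <- function(...) trace_params(noise_sd = 0, crosstalk = 0, ...)

clean_gel <- function(...) gel_params(noise_sd = 0, background_level = 0, ...)

serine_refs <- default_serine_reference()

# Dirichlet(alpha) sample of four isoform fractions
rdirichlet4 <- function(alpha = 2) {
  g <- stats::rgamma(4, shape = alpha)
  g / sum(g)
}
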