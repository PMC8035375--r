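# shared fixtures: schemes, regimes and the default reference matrix
scheme3 <- function() age_class_scheme(c(0, 75, 150))
scheme110 <- function() age_class_scheme(c(0, 110, 150))
neg_exp <- function(lambda = 100) disturbance_regime("negative_exponential", lambda)
weib <- function(lambda = 100, shape = 2) disturbance_regime("weibull", lambda, shape)
revised <- function() build_revised_matrix()
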