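# Shared vocabulary of the model.
SEXES <- c("men", "women")
POOLS <- c("healthy", "obese", "smoker", "obese_smoker")
COMPARTMENTS <- c(POOLS, "t2d", "dead_t2d", "dead_other")
LIVE <- c(POOLS, "t2d")
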