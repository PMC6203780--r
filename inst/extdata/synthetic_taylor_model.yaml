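# Synthetic stand-in for a published Cox-model specification (fixture,
# not the published coefficients).
type: taylor
rates: synthetic_age_rates.tsv
fh_rr: synthetic_fh_rr.tsv
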