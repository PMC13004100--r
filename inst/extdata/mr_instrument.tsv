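# Worked single-instrument MR example at the APOH locus: rs1801690 as the
# instrument, total anti-b2GPI antibody level (inverse-normal units) as the
# exposure and venous thromboembolism (log-odds) as the outcome.
# Betas are as published; the standard errors are reconstructed from the
# published instrument F-statistic (42) and Wald-ratio p-value (3.95e-6),
# which the published tables do not print directly:
#   se_exposure = 0.21 / sqrt(42)
#   beta_outcome = -0.25 * 0.21, se_outcome = |beta_outcome| / |qnorm(3.95e-6 / 2)|
role	variant_id	chromosome	position	effect_allele	other_allele	eaf	beta	se	n
exposure	rs1801690	17	66212167	G	C	0.05	0.21	0.0324037	5969
outcome	rs1801690	17	66212167	G	C	0.05	-0.0525	0.0113734	11500861
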