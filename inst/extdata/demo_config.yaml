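# Bundled demonstration scenario: a synthetic chronic-transfusion cohort at
# registry scale (~340 prevalent patients, mean ~38.7 units/patient-year,
# overdispersion 1.71, ~1%/yr adult mortality, incidence 0.13/100k), with a
# compact variant grid so the full simulate -> report pipeline runs in minutes.
n_patients: 340
years: [2005, 2009]
horizon: 15
grid: small
parsimony_delta: 0.01
reductions: [0, 0.4, 0.8]
seed: 20090101
pop_growth_rate: 0.009
pop_cv: 0.02
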