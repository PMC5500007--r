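# Fitted constants of the Ph+ ALL Nilotinib / low-dose-radiation model.
# Flat map: linear dose-response coefficients (rS0..dR2), LQ radiosensitivity
# (alpha, beta), carrying capacity K, initial resistant fraction f_R0,
# initial population N0, and the drug-induced conversion rates fitted for the
# drug-only (nu_drug) and drug-plus-radiation (nu_combo) contexts.
rS0: 2.5369
rR0: 2.5369
rS1: 0.0155
rR1: 0.0
rS2: 0.0140
rR2: 0.0
dS0: 2.0550
dR0: 2.0550
dS1: 0.0
dR1: 0.0
dS2: 0.0025
dR2: 0.0114
alpha: 0.6647
beta: 0.079
K: 4.2
f_R0: 0.001
N0: 1.0
nu_drug: 0.0409
nu_combo: 0.1768
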