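scenario,path,low,high
discount_rate,economics.discount_rate,0,0.10
relatives_tested_per_index,costs.n_relatives_per_index,4,1
bc_risk_after_both_surgeries,probabilities.well_to_bc_after_both,0,0.08
oc_risk_after_oophorectomy,probabilities.well_to_oc_after_oophorectomy,0.004,0.03
bc_treatment_cost_index,costs.bc_index_yearly,10687.866;575.37;431.418;431.418;431.418,24938.354;1342.53;1006.642;1006.642;1006.642
uptake_mastectomy,probabilities.uptake_mastectomy,0.02,0.04
uptake_oophorectomy,probabilities.uptake_oophorectomy,0.10,0.14
uptake_both,probabilities.uptake_both,0.09,0.17
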