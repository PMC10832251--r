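# Designed genotypes (and expected caller output) for the
# six-individual demonstration FASTA; deterministic rendering of the
# synthetic reference (seed 20230901)
"id","M918T","T929I","L1014F","L1014H","call_M918T","call_T929I","call_L1014F","call_L1014H"
"fly_01","SS","SS","SS","SS","SS","SS","SS","SS"
"fly_02","SS","SS","RR","SS","SS","SS","RR","INDETERMINATE"
"fly_03","SS","SS","RS","SS","SS","SS","RS","SS"
"fly_04","SS","RS","RR","SS","SS","RS","RR","INDETERMINATE"
"fly_05","RS","SS","SS","RS","RS","SS","SS","RS"
"fly_06","RR","RR","SS","SS","RR","RR","SS","SS"
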