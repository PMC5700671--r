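# Demonstration pipeline configuration: simulate a small hospital population
# with five planted dual-associated confounder codes and a borderline
# hyponatremia effect on in-hospital death of OR 2.
simulate:
  n_patients: 20000
seed: 1
alpha_family: 0.05
min_los: 2
out_dir: natriwas-demo
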