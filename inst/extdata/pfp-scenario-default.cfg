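# Baseline scenario: uncoated PFP nanodroplet in fluid-like tissue at
# physiological temperature, 5 MHz drive. All keys carry unit suffixes;
# see config-schema.tsv for the full schema.
R20_nm = 140
sigma2_mN_per_m = 56
T0_K = 310
K2_GPa = 2.2
K3_MPa = 0
Pc_conf_MPa = 0
f_MHz = 5
tau_divisor = 10
include_gas = true
include_elastic_barrier = true
laplace_factor = 1
Psat_kPa = 135
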