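id,ozone,pm25,diesel,toxic_release,traffic,lead_risk,superfund,haz_waste,rmp,wastewater,cardio,low_birth_weight,low_education,ling_iso,poverty,unemployment,housing_burden,race_eth,transport
ozone,1.00,-0.16,-0.40,-0.38,-0.21,-0.11,0.04,-0.11,-0.12,-0.18,0.11,-0.02,0.02,-0.27,0.11,0.11,-0.14,-0.34,0.46
pm25,-0.16,1.00,0.51,0.21,0.23,0.22,0.39,0.36,0.48,0.29,0.17,0.13,0.29,0.40,0.21,0.08,0.27,0.47,-0.38
diesel,-0.40,0.51,1.00,0.36,0.49,0.23,0.37,0.31,0.31,0.16,-0.02,0.11,-0.03,0.36,0.01,0.00,0.41,0.43,-0.78
toxic_release,-0.38,0.21,0.36,1.00,0.14,0.12,0.38,0.52,0.14,0.16,-0.10,0.10,-0.07,0.17,-0.14,-0.11,0.09,0.26,-0.47
traffic,-0.21,0.23,0.49,0.14,1.00,0.01,0.21,0.21,0.04,0.09,0.05,0.03,0.06,0.24,0.08,0.00,0.27,0.25,-0.40
lead_risk,-0.11,0.22,0.23,0.12,0.01,1.00,0.16,0.02,0.27,0.13,0.10,0.15,0.22,0.05,0.34,0.08,0.18,0.09,-0.13
superfund,0.04,0.39,0.37,0.38,0.21,0.16,1.00,0.52,0.22,0.14,0.05,0.20,-0.02,0.12,0.11,0.03,0.25,0.24,-0.33
haz_waste,-0.11,0.36,0.31,0.52,0.21,0.02,0.52,1.00,0.25,-0.02,0.06,0.05,0.06,0.25,-0.04,0.00,0.17,0.37,-0.38
rmp,-0.12,0.48,0.31,0.14,0.04,0.27,0.22,0.25,1.00,0.31,0.05,0.09,0.24,0.29,0.21,0.03,0.13,0.31,-0.10
wastewater,-0.18,0.29,0.16,0.16,0.09,0.13,0.14,-0.02,0.31,1.00,0.04,0.09,0.04,0.04,0.09,-0.02,0.11,0.04,-0.11
cardio,0.11,0.17,-0.02,-0.10,0.05,0.10,0.05,0.06,0.05,0.04,1.00,0.08,0.41,0.11,0.36,0.19,0.25,0.15,0.05
low_birth_weight,-0.02,0.13,0.11,0.10,0.03,0.15,0.20,0.05,0.09,0.09,0.08,1.00,0.13,0.05,0.17,0.06,0.14,0.12,-0.09
low_education,0.02,0.29,-0.03,-0.07,0.06,0.22,-0.02,0.06,0.24,0.04,0.41,0.13,1.00,0.49,0.70,0.33,0.34,0.43,0.10
ling_iso,-0.27,0.40,0.36,0.17,0.24,0.05,0.12,0.25,0.29,0.04,0.11,0.05,0.49,1.00,0.32,0.12,0.31,0.81,-0.32
poverty,0.11,0.21,0.01,-0.14,0.08,0.34,0.11,-0.04,0.21,0.09,0.36,0.17,0.70,0.32,1.00,0.39,0.57,0.32,0.05
unemployment,0.11,0.08,0.00,-0.11,0.00,0.08,0.03,0.00,0.03,-0.02,0.19,0.06,0.33,0.12,0.39,1.00,0.25,0.15,0.05
housing_burden,-0.14,0.27,0.41,0.09,0.27,0.18,0.25,0.17,0.13,0.11,0.25,0.14,0.34,0.31,0.57,0.25,1.00,0.37,-0.45
race_eth,-0.34,0.47,0.43,0.26,0.25,0.09,0.24,0.37,0.31,0.04,0.15,0.12,0.43,0.81,0.32,0.15,0.37,1.00,-0.47
transport,0.46,-0.38,-0.78,-0.47,-0.40,-0.13,-0.33,-0.38,-0.10,-0.11,0.05,-0.09,0.10,-0.32,0.05,0.05,-0.45,-0.47,1.00
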