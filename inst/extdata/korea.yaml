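# South Korea, societal perspective — published model inputs as printed
# (rounded AI unit cost and AI specificity).
label: South Korea (printed inputs)
perspective: societal
currency: USD
exchange_rate: 1416.54
pd_dx_rate: 0.5
n_pd: 48888
ai_adoption: 0.3
pet_unaffordable: 0.3
sens_ai: 0.943
spec_ai: 0.917
sens_pet: 0.932
spec_pet: 0.857
cost_pet: 735
cost_ai: 7
cost_early: 4062
cost_delayed: 4753
persons_per_visit: 2
hours_pet: 4
hours_visit: 4
wage_65plus: 14.6
employment_65plus: 0.396
transport_roundtrip: 18.2
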