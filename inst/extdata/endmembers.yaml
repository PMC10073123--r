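# Isotopic endmembers for the three-source mixing model.
# d13c in permil vs VPDB; D14c in permil. The Delta14C means of the plant
# sources match contemporary tropospheric CO2; fossil carbon is
# radiocarbon-dead. Delta14C SDs are near-point defaults (the reference
# values are treated as fixed), configurable.
sources:
  fossil:
    d13c_mean: -29.0
    d13c_sd: 1.3
    D14c_mean: -1000.0
    D14c_sd: 5.0
  C3:
    d13c_mean: -26.7
    d13c_sd: 1.8
    D14c_mean: 30.0
    D14c_sd: 5.0
  C4:
    d13c_mean: -16.4
    d13c_sd: 1.4
    D14c_mean: 30.0
    D14c_sd: 5.0
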