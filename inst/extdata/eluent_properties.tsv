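# Physical properties of binary water/organic mobile phases at 25 C,
# tabulated against the volume fraction of organic modifier.
# surface_tension in mN/m; viscosity in mPa*s.
# Sources: water/methanol surface tension after Vazquez, Alvarez & Navaza,
# J. Chem. Eng. Data 1995, 40, 611-614; mixture viscosities after the
# compilations in Thompson et al., J. Chem. Eng. Data 2006, 51, 703-708
# (methanol/water) and Chen, Fang & Wu, J. Chromatogr. A 2016
# (acetonitrile/water); pure-component values from the CRC Handbook.
# Both mixture viscosities pass through a maximum (hydrogen-bond network
# disruption), so viscosity is deliberately non-monotone in the fraction.
# polarity index is not tabulated here: it mixes linearly from the pure
# values (water 10.2, methanol 5.1, acetonitrile 5.8; Snyder scale).
modifier	fraction	surface_tension	viscosity
methanol	0.0	72.8	0.89
methanol	0.1	56.2	1.16
methanol	0.2	47.2	1.40
methanol	0.3	40.4	1.56
methanol	0.4	35.6	1.62
methanol	0.5	32.3	1.58
methanol	0.6	29.7	1.47
methanol	0.7	27.6	1.30
methanol	0.8	25.9	1.08
methanol	0.9	24.2	0.83
methanol	1.0	22.5	0.55
acetonitrile	0.0	72.8	0.89
acetonitrile	0.1	55.0	1.02
acetonitrile	0.2	46.5	1.06
acetonitrile	0.3	41.0	1.04
acetonitrile	0.4	37.5	0.98
acetonitrile	0.5	34.9	0.89
acetonitrile	0.6	32.9	0.79
acetonitrile	0.7	31.3	0.68
acetonitrile	0.8	30.1	0.57
acetonitrile	0.9	29.1	0.47
acetonitrile	1.0	28.2	0.37
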