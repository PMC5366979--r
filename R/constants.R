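## Physical constants (CODATA 2018 exact values where defined)
## Boltzmann constant, J/K
.kB <- 1.380649e-23
## Vacuum permittivity, F/m
.eps0 <- 8.85418781e-12
## Avogadro constant, 1/mol
.NA <- 6.02214076e23
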