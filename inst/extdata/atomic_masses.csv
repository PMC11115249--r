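# Monoisotopic atomic masses (Da), IUPAC 2021 / CODATA; most-abundant isotope.
# This file is the single authoritative constants table for all mass arithmetic.
element,monoisotopic_mass
H,1.0078250319
C,12.0000000000
N,14.0030740044
O,15.9949146196
Na,22.9897692820
S,31.9720711744
K,38.9637064864
P,30.9737619984
F,18.9984031627
Cl,34.9688526820
Br,78.9183376000
I,126.9044719000
Se,79.9165218000
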