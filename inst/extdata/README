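overplus15_directions.tsv

Synthetic 15-direction "over-plus"-style gradient table (unnormalised
integer component form; directions are unit-normalised on load).  It is
constructed from combined gradient axes -- 6 face diagonals, 4 body
diagonals and 5 double-axis combinations -- to reproduce the defining
property of vendor over-plus schemes (anisotropic, clustered angular
coverage exploiting simultaneous gradient axes).  It is NOT any vendor's
table; substitute a measured bvec/bval pair via readScheme() or the
`directions` argument of buildOverplusScheme() when vendor fidelity
matters.
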