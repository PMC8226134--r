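# Reported per-species binding decomposition components (kJ/mol) for mixing
# a buffered lysozyme dimer with five tripolyphosphate ("tpp") or citrate
# ("cit") molecules: change in Gibbs energy, enthalpy and T*entropy per
# species, with W_<x> rows for the hydration-shell water of species x.
# Component rows only; totals are recomputed by the package.
species,dG_tpp,dG_cit,dH_tpp,dH_cit,dTS_tpp,dTS_cit
lysozyme,-297,-226,-287,-267,10,-42
polyanion,131,-76,136,-29,5,47
tris,-106,-85,-97,-80,9,6
sodium,4,-4,4,-4,1,0
chloride,-3,-1,-3,-1,0,0
W_lysozyme,4,-14,28,17,23,32
W_polyanion,-43,31,-84,30,-41,-1
W_tris,34,40,38,43,4,3
W_sodium,2,-18,-28,-27,-29,-9
W_chloride,-2,-1,0,1,2,2
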