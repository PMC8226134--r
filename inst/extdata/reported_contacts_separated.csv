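# Reported ensemble-average united-atom contact counts for the separated
# (dilute reference) lysozyme/excipient systems: a buffered lysozyme dimer
# with chloride counterions, and each polyanion (tripolyphosphate "tpp",
# citrate "cit") with sodium counterions. n_molecules_a is the number of
# molecules of species_a the total is summed over.
species_a,species_b,contacts,n_molecules_a
lysozyme,lysozyme,3.8,2
lysozyme,tris,5.7,2
lysozyme,chloride,0.9,2
tris,tris,0.0,3
tris,chloride,0.1,3
tpp,sodium,51.1,5
cit,sodium,16.3,5
water,lysozyme,918.5,NA
water,tpp,76.0,NA
water,cit,91.3,NA
water,tris,54.1,NA
water,sodium_tpp,79.9,NA
water,sodium_cit,69.8,NA
water,chloride,137.8,NA
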