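# Reported ensemble-average water-environment counts for each
# protein-excipient system (buffer-only "tris", tripolyphosphate "tpp",
# citrate "cit"): number of waters whose coordination shell holds one
# protein (WP), two proteins (WPP), one protein plus excipient/counterion
# (WEP) or two proteins plus excipient/counterion (WEPP). Totals are
# recomputed by the package.
environment,tris,tpp,cit
WP,906.9,843.1,837.2
WPP,5.2,15.0,15.4
WEP,6.4,7.8,11.0
WEPP,0.0,0.3,0.5
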