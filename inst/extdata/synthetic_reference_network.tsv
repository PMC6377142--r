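# SYNTHETIC reference adjacency (ground truth of the package's default
# synthetic_spec() network). This is a constructed stand-in for a curated
# literature network, shipped so that threshold_sweep() has a worked example;
# it is NOT a curated biological network.
source	target
D1	G2
D2	G3
D2	G4
G3	G5
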