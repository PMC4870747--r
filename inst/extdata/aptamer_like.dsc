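# SYNTHETIC descriptor: an ATP-aptamer-like motif — three single-stranded
# elements and two nested helices.  Topology and element counts only; the
# sequence content is invented for testing.
name: aptamer_like_synthetic
s1 h1 s2 h2 s3 h2' h1'
s1 0:0 GGAAG
s2 1:0 NNN*
s3 0:0 WTTNA
h1 0:1:0 GSNC:CSNG
h2 0:0:1 RNYA:YNRT
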