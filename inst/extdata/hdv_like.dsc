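# SYNTHETIC descriptor: an HDV-ribozyme-like motif with four helical
# elements organized in a double pseudoknot (h2 crosses h1; h4 crosses h2).
# Topology and element counts only — the sequence content is invented for
# testing, not taken from any curated ribozyme alignment.
name: hdv_like_synthetic
h1 s1 h2 s2 h1' h3 s3 h4 h3' s4 h2' h4'
s1 0:0 CTNA
s2 0:0 ARG
s3 0:0 TTNCG
s4 0:0 YAC
h1 0:0:0 CCGNG:GGCNC
h2 0:0:0 GCNC:CGNG
h3 0:0:0 RGGC:YCCG
h4 0:0:0 GNCG:CNGC
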