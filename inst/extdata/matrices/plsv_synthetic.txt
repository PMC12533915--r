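# SYNTHETIC stand-in for the P-wave least-squares (PLSV) transform.
# 3 x 8: rows X Y Z, columns I II V1 V2 V3 V4 V5 V6.
# The original data-fitted PLSV coefficients are not printed in an accessible
# source; this stand-in is the weighted least-squares pseudo-inverse of the
# Dower forward matrix with lead weights (1,3,3,1.5,1,0.75,0.75,1) emphasizing
# II and V1 where the atrial signal is best seen.
# Edit this file to substitute transcribed coefficients; the loader only
# requires a 3 x 8 numeric grid.
 0.1438  0.0101 -0.3470  0.0032  0.1821  0.1881  0.1742  0.1723
-0.0962  0.9275  0.0590 -0.0427 -0.0790 -0.0353 -0.0110  0.0000
-0.0044  0.1197 -0.3729 -0.2881 -0.1797 -0.0601 -0.0041  0.0376
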