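# SYNTHETIC stand-in for the QRS least-squares (QLSV) transform.
# 3 x 8: rows X Y Z, columns I II V1 V2 V3 V4 V5 V6.
# The original data-fitted QLSV coefficients are not printed in an accessible
# source; this stand-in is the weighted least-squares pseudo-inverse of the
# Dower forward matrix with lead weights (1,1,1,1.5,2,2,1.5,1) emphasizing the
# mid/left precordials where the QRS has the best signal-to-noise ratio.
# Edit this file to substitute transcribed coefficients; the loader only
# requires a 3 x 8 numeric grid.
 0.1143 -0.0203 -0.1439 -0.1263  0.1158  0.2991  0.2500  0.1416
-0.2231  0.8805  0.0711  0.0104 -0.1552 -0.0100  0.0710  0.0474
 0.0258  0.0922 -0.1686 -0.3186 -0.2997 -0.0298  0.0981  0.0954
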