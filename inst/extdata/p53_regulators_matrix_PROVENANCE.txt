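p53_regulators_matrix.csv
-------------------------
Row-stochastic transition matrix of the augmented nine-protein p53-MDM2
regulator network (11 nodes: initial node S, nine proteins, transition
node T), with entries printed to 4 decimal places.

Transcription note: the published rendering of this matrix is laid out
column-major (transposed) — in the printed array it is the COLUMNS, not
the rows, that sum to 1, and the first printed line holds the inflow
probabilities INTO S (the reciprocal out-degrees 1/7, 1/5, 1/4, 1/8,
1/9, 1/5, 1/2, 1/7, 1/3 of the nine proteins, plus 1.0 from T). This
file stores the transpose of the printed array so that rows are
from-nodes, the orientation the package's solvers expect. The
transcription was validated by reproducing the published stationary
eigenvector (unit Euclidean norm) to a maximum absolute difference of
5.0e-5 per entry and the normalized nine-protein influence vector to
4.8e-5 per entry, both well inside the 5e-4 band implied by the
4-decimal rounding of the matrix entries.

Because of that rounding, row sums deviate from 1 by up to ~5e-4;
load_transition() renormalizes each row on load.

Labels: only the fifth protein position is identified as HDAC1 (pinned
by its published 15.25% influence score); the published text does not
state the row order of the remaining eight proteins, so they carry the
positional placeholder labels P1-P4 and P6-P9. The accompanying
p53_regulators_proteins.txt lists the nine protein names in their
published table order, which is NOT asserted to be the matrix order.
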