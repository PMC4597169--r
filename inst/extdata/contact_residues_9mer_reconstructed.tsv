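# Contact residues of the Class I HLA groove per 9-mer peptide position.
# Numbering: 1-based mature chain of A*02:01 (PDB 3HLA); the shipped
# alignment convention covers residues 2-182.
# RECONSTRUCTED from the classical A-F pocket literature; not a verbatim
# copy of any single published table. Replace this file to use another
# contact definition (e.g. NetMHCpan pseudo-sequence positions).
peptide_position	residues
1	5,7,59,62,63,66,99,159,163,167,171
2	7,9,24,25,34,45,63,66,67,70,99
3	97,99,114,152,155,156,159
4	65,66,69,70,155,156,159,160
5	69,70,73,74,97,114,147,152,155,156
6	70,73,74,97,114,147,152
7	73,74,76,77,80,97,114,116,123,133,143,146,147
8	72,73,76,77,80,143,144,146,147
9	74,77,80,81,84,95,96,97,114,116,118,123,143,146,147
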