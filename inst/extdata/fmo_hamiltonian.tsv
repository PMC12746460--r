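# 7-site one-exciton Hamiltonian of a single FMO (Fenna-Matthews-Olson)
# monomer, Chlorobaculum tepidum, in cm^-1.  Diagonal entries are Qy site
# energies, off-diagonal entries electronic couplings.
# Values follow the widely used Adolphs-Renger parametrization as it
# circulates in the exciton-dynamics literature; this transcription has not
# been checked digit-by-digit against the original table, and no result of
# this package depends on the exact values -- only on structural properties
# (7 sites, symmetric couplings, zero-diagonal coupling matrix, site-energy
# spread below 500 cm^-1, dominant 1-2, 2-3, 3-4, 4-5/4-7, 5-6, 6-7
# coupling pattern).
# version: 1
label	Bchl1	Bchl2	Bchl3	Bchl4	Bchl5	Bchl6	Bchl7
Bchl1	12410	-87.7	5.5	-5.9	6.7	-13.7	-9.9
Bchl2	-87.7	12530	30.8	8.2	0.7	11.8	4.3
Bchl3	5.5	30.8	12210	-53.5	-2.2	-9.6	6.0
Bchl4	-5.9	8.2	-53.5	12320	-70.7	-17.0	-63.3
Bchl5	6.7	0.7	-2.2	-70.7	12480	81.1	-1.3
Bchl6	-13.7	11.8	-9.6	-17.0	81.1	12630	39.7
Bchl7	-9.9	4.3	6.0	-63.3	-1.3	39.7	12440
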