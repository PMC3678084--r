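# RNA/RNA nearest-neighbor thermodynamic parameters, Freier et al. (1986),
# PNAS 83:9373-9377, 1 M NaCl. Stacks written 5'->3' on one strand; the
# parameters of a stack equal those of its reverse complement. dH in
# kcal/mol, dS in cal/(mol*K). The 'initiation' row carries the helix
# initiation terms.
stack	dH_kcal_mol	dS_cal_molK
AA	-6.6	-18.4
AC	-10.2	-26.2
AG	-7.6	-19.2
AU	-5.7	-15.5
CA	-10.5	-27.8
CC	-12.2	-29.7
CG	-8.0	-19.4
CU	-7.6	-19.2
GA	-13.3	-35.5
GC	-14.2	-34.9
GG	-12.2	-29.7
GU	-10.2	-26.2
UA	-8.1	-22.6
UC	-13.3	-35.5
UG	-10.5	-27.8
UU	-6.6	-18.4
initiation	0.0	-10.8
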