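# Per-residue scalar properties used for variant featurization.
# Columns:
#   hydrophobicity   : Fauchere-Pliska octanol/water side-chain transfer scale
#                      (kcal/mol); more positive = more hydrophobic. Users
#                      modelling a specific membrane may substitute a
#                      membrane-transfer scale with the same sign convention.
#   polarizability   : normalized side-chain polarizability (dimensionless,
#                      approx. [0, 0.41]; Gly = 0).
#   steric_parameter : graph shape index of the side chain (dimensionless;
#                      encodes complexity, branching and symmetry; Gly = 0).
#   n_h_donors       : side-chain hydrogen-bond donor H count at pH 7
#                      (Asp/Glu carboxylates deprotonated, Lys/Arg protonated).
#   n_h_acceptors    : side-chain heavy-atom hydrogen-bond acceptor sites at
#                      pH 7 (protonated amines count 0).
#   vdw_volume       : residue van der Waals volume (A^3).
# Override with a file of the same layout via the `table` arguments.
aa	hydrophobicity	polarizability	steric_parameter	n_h_donors	n_h_acceptors	vdw_volume
A	0.31	0.046	1.28	0	0	67
R	-1.01	0.291	2.34	5	0	148
N	-0.60	0.134	1.60	2	1	96
D	-0.77	0.105	1.60	0	2	91
C	1.54	0.128	1.77	1	1	86
Q	-0.22	0.180	1.56	2	1	114
E	-0.64	0.151	1.56	0	2	109
G	0.00	0.000	0.00	0	0	48
H	0.13	0.230	2.99	1	1	118
I	1.80	0.186	4.19	0	0	124
L	1.70	0.186	2.59	0	0	124
K	-0.99	0.219	1.89	3	0	135
M	1.23	0.221	2.35	0	1	124
F	1.79	0.290	2.94	0	0	135
P	0.72	0.131	2.67	0	0	90
S	-0.04	0.062	1.31	1	1	73
T	0.26	0.108	3.03	1	1	93
W	2.25	0.409	3.21	1	0	163
Y	0.96	0.298	2.94	1	1	141
V	1.22	0.140	3.67	0	0	105
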