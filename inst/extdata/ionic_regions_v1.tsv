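# Ionic conductance-multiplier table, version 1.
# Multipliers are relative to the published Courtemanche-Ramirez-Nattel
# maximal conductances and compose multiplicatively:
#   effective = af_remodelling * global * regional (* experimental scalings).
# 'af_remodelling' is the persistent-AF electrical-remodelling set
# (ICaL -70%, Ito -50%, IKur -50%); 'global' carries the sodium-conductance
# doubling (upstroke velocity) and the 20% IK1 reduction (restitution).
# Regional rows are calibrated so that the composed models reproduce the
# anchor measurements: PV APD90 = ~181 ms at CL 1000 ms, LA APD90 = ~185 ms
# at CL 200 ms, and a PV IK1 scaling k in [0.5, 2.5] spanning ~[190, 100] ms.
scope	gNa	gK1	gto	gKur	gCaL	gKr	gKs	gbNa	gbCa	gNaK	gNaCa	gpCa
af_remodelling	1	1	0.5	0.5	0.3	1	1	1	1	1	1	1
global	2	0.8	1	1	1	1	1	1	1	1	1	1
LA_BODY	1	1	0.8	1	1.10	0.70	1	1	1	1	1	1
LAA	1	1	0.8	1	1.10	0.70	1	1	1	1	1	1
RA	1	1	1	1	1	1	1	1	1	1	1	1
SAN	1	1	1	1	1	1	1	1	1	1	1	1
LSPV	1	0.8948	1.5431	1.2578	0.7946	1.515	1.6222	1	1	1	0.9582	1
LIPV	1	0.8948	1.5431	1.2578	0.7946	1.515	1.6222	1	1	1	0.9582	1
RSPV	1	0.8948	1.5431	1.2578	0.7946	1.515	1.6222	1	1	1	0.9582	1
RIPV	1	0.8948	1.5431	1.2578	0.7946	1.515	1.6222	1	1	1	0.9582	1
PVI_LESION_L	1	1	0.8	1	1.10	0.70	1	1	1	1	1	1
PVI_LESION_R	1	1	0.8	1	1.10	0.70	1	1	1	1	1	1
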