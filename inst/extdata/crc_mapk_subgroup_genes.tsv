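gene	subgroup	fold_change	direction	note
CACNB4	MSS	0.65	down	stronger in MSS than overall (FC 0.67)
MAP3K6	MSS	0.66	down	stronger in MSS than overall (FC 0.73)
CD14	MSS	0.66	down	stronger in MSS than overall (FC 0.68)
CACNA2D4	MSS	0.66	down	stronger in MSS than overall (FC 0.67)
MAP4K4	MSS	1.52	up	stronger in MSS than overall (FC 1.47)
RPS6KA6	MSI	0.20	down	MSI-specific only
PLA2G4E	MSI	0.30	down	MSI-specific only
RASGFR1	MSI	0.39	down	MSI-specific only (as printed)
PLA2G4C	MSI	0.47	down	MSI-specific only
MAPK8IP1	MSI	0.47	down	MSI-specific only
PDGFA	MSI	0.53	down	MSI-specific only
TGFBR2	MSI	0.61	down	MSI-specific only
DUSP7	MSI	1.57	up	MSI-specific only
HRAS	MSI	1.92	up	MSI-specific only
IL1B	MSI	2.06	up	MSI-specific only
PLA2G4A	MSI	2.70	up	MSI-specific only
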