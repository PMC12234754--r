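# Molecular band assignments for head-and-neck tissue Raman spectra.
# Tolerance 15 cm^-1 (below the ~20 cm^-1 instrument resolution).
# Band pairs within one resolution element (1444/1448, 1656/1665) are merged.
center	tolerance	region	assignment
1003	15	fingerprint	phenylalanine ring breathing (protein)
1032	15	fingerprint	phenylalanine C-H in-plane bending (protein)
1084	15	fingerprint	phosphate stretching (lipids, nucleic acids)
1260	15	fingerprint	amide III in-plane deformation (protein, lipid)
1266	15	fingerprint	lipid =C-H / amide III (protein, lipid)
1335	15	fingerprint	guanine deformation (DNA/RNA)
1448	15	fingerprint	CH2 bending (lipids, proteins)
1656	15	fingerprint	amide I alpha-helix / C=C stretching (protein, unsaturated lipid)
1730	15	fingerprint	C=O ester stretching (phospholipids)
2865	15	high_wavenumber	CH2 symmetric stretching (lipids)
2920	15	high_wavenumber	CH3 stretching (proteins)
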