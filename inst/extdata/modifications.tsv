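# Modification registry. Deltas are Unimod-standard monoisotopic masses (Da).
# mode: fixed mods are applied to every target residue automatically;
# variable mods contribute only where declared on a record.
name	delta_mass	targets	mode
Carbamidomethyl	57.021464	C	fixed
Oxidation	15.994915	M	variable
Phospho	79.966331	S	variable
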