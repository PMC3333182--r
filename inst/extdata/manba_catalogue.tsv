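id	species	event_kind	nt_start	nt_end	inserted_bases	deleted_bases	protein_ref	protein_pos	protein_alt	zygosity	observed_phenotype	shared_species	source_note
Hs_E83X	human	nonsense	.	.	.	.	E	83	X	compound_heterozygous	moderate	.	biallelic with Q426X in the same patient
Hs_Y126X	human	nonsense	.	.	.	.	Y	126	X	unknown	severe	.	.
Hs_W192insX	human	insertion	562	572	.	.	W	192	X	unknown	severe	.	10-nt insertion at loci 562-572; frameshift truncates at W192
Hs_W231X	human	nonsense	.	.	.	.	W	231	X	unknown	severe	.	.
Hs_V321X	human	nonsense	.	.	.	.	V	321	X	unknown	severe	.	.
Hs_Q426X	human	nonsense	.	.	.	.	Q	426	X	compound_heterozygous	moderate	.	biallelic with E83X in the same patient
Hs_Y485X	human	nonsense	.	.	.	.	Y	485	X	unknown	severe	.	.
Hs_K616X	human	nonsense	.	.	.	.	K	616	X	heterozygous	mild	.	heterozygote; truncation removes binding residue W657
Hs_V720X	human	nonsense	.	.	.	.	V	720	X	unknown	severe	.	loses the last domain and half the penultimate domain
Hs_R182W	human	missense	.	.	.	.	R	182	W	compound_heterozygous	mild	.	away from active site; minor perturbation
Hs_G392E	human	missense	.	.	.	.	G	392	E	unknown	moderate	.	close to active site; disrupts the ligand binding motif
Hs_S505P	human	missense	.	.	.	.	S	505	P	unknown	severe	.	disturbs catalytic nucleophile E457 via N455
Hs_R641H	human	missense	.	.	.	.	R	641	H	homozygous	moderate	.	ruptures R641-D709 salt bridge; destabilizes the fold
Cp_W466X	goat	nonsense	.	.	.	.	W	466	X	homozygous	severe	human	lethal neonatal onset in Nubian goat; same residue mutated in a mild human compound heterozygote
Bt_W858X	cow	nonsense	.	.	.	.	W	858	X	homozygous	severe	.	near-intact protein (22 residues missing) yet lethal in cattle
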