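input_metabolite	output_metabolite	reaction
FA_ext	AcCoA	FAUP
AcCoA	Cit	CS
OAA	Cit	CS
Cit	ICit	ACONT__fwd
ICit	Cit	ACONT__rev
ICit	AKG	ICDHyr
ICit	CO2	ICDHyr
AKG	SUCCoA	AKGDH
AKG	CO2	AKGDH
SUCCoA	SUCC	SUCOAS__fwd
SUCC	SUCCoA	SUCOAS__rev
SUCC	Fum	SUCDi
Fum	L-Mal	FUM__fwd
L-Mal	Fum	FUM__rev
L-Mal	OAA	MDH__fwd
OAA	L-Mal	MDH__rev
Pyr	AcCoA	PDH
Pyr	CO2	PDH
PEP	Pyr	PYK
Pyr	OAA	PC
CO2	OAA	PC
OAA	PEP	PCK1
OAA	CO2	PCK1
L-Mal	Pyr	ME1
L-Mal	CO2	ME1
PEP	G6P	GNG
G6P	D-Glc	G6PP
D-Glc	D-Glc_ext	GLCex
CO2	CO2_ext	CO2t
ICit	SUCC	ICL
ICit	Glx	ICL
AcCoA	L-Mal	MALS
Glx	L-Mal	MALS
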