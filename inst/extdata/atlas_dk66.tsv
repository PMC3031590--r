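region	hemisphere	abbreviation	name
L.BSTS	left	BSTS	Bank of the superior temporal sulcus
L.CAC	left	CAC	Caudal anterior cingulate
L.CMF	left	CMF	Caudal middle frontal
L.CUN	left	CUN	Cuneus
L.ENT	left	ENT	Entorhinal
L.FP	left	FP	Frontal pole
L.FUSI	left	FUSI	Fusiform gyrus
L.IP	left	IP	Inferior parietal
L.IT	left	IT	Inferior temporal
L.ISTC	left	ISTC	Isthmus of the cingulate
L.LOCC	left	LOCC	Lateral occipital
L.LOF	left	LOF	Lateral orbitofrontal
L.LING	left	LING	Lingual gyrus
L.MOF	left	MOF	Medial orbitofrontal
L.MT	left	MT	Middle temporal
L.PARC	left	PARC	Paracentral lobule
L.PHG	left	PHG	Parahippocampal
L.PERI	left	PERI	Pericalcarine
L.PSTC	left	PSTC	Postcentral gyrus
L.PC	left	PC	Posterior cingulate
L.POPE	left	POPE	Pars opercularis (inferior frontal)
L.PORB	left	PORB	Pars orbitalis (inferior frontal)
L.PTRI	left	PTRI	Pars triangularis (inferior frontal)
L.PREC	left	PREC	Precentral gyrus
L.PCUN	left	PCUN	Precuneus
L.RAC	left	RAC	Rostral anterior cingulate
L.RMF	left	RMF	Rostral middle frontal
L.SF	left	SF	Superior frontal
L.SP	left	SP	Superior parietal
L.ST	left	ST	Superior temporal
L.SMAR	left	SMAR	Supramarginal
L.TP	left	TP	Temporal pole
L.TT	left	TT	Transverse temporal
R.BSTS	right	BSTS	Bank of the superior temporal sulcus
R.CAC	right	CAC	Caudal anterior cingulate
R.CMF	right	CMF	Caudal middle frontal
R.CUN	right	CUN	Cuneus
R.ENT	right	ENT	Entorhinal
R.FP	right	FP	Frontal pole
R.FUSI	right	FUSI	Fusiform gyrus
R.IP	right	IP	Inferior parietal
R.IT	right	IT	Inferior temporal
R.ISTC	right	ISTC	Isthmus of the cingulate
R.LOCC	right	LOCC	Lateral occipital
R.LOF	right	LOF	Lateral orbitofrontal
R.LING	right	LING	Lingual gyrus
R.MOF	right	MOF	Medial orbitofrontal
R.MT	right	MT	Middle temporal
R.PARC	right	PARC	Paracentral lobule
R.PHG	right	PHG	Parahippocampal
R.PERI	right	PERI	Pericalcarine
R.PSTC	right	PSTC	Postcentral gyrus
R.PC	right	PC	Posterior cingulate
R.POPE	right	POPE	Pars opercularis (inferior frontal)
R.PORB	right	PORB	Pars orbitalis (inferior frontal)
R.PTRI	right	PTRI	Pars triangularis (inferior frontal)
R.PREC	right	PREC	Precentral gyrus
R.PCUN	right	PCUN	Precuneus
R.RAC	right	RAC	Rostral anterior cingulate
R.RMF	right	RMF	Rostral middle frontal
R.SF	right	SF	Superior frontal
R.SP	right	SP	Superior parietal
R.ST	right	ST	Superior temporal
R.SMAR	right	SMAR	Supramarginal
R.TP	right	TP	Temporal pole
R.TT	right	TT	Transverse temporal
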