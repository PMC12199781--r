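study_id	finding	n_total	n_affected	excluded_for_bias	n_studies
pooled_grey_matter	grey_matter_injury	893	451	FALSE	22
pooled_white_matter	white_matter_injury	1019	281	FALSE	24
pooled_miscellaneous	miscellaneous	718	91	FALSE	15
pooled_normal	normal	1140	182	FALSE	29
pooled_maldevelopment	maldevelopment	786	74	FALSE	12
pooled_bg_thalamus	bg_thalamus	597	296	FALSE	18
pooled_cortical_subcortical	cortical_subcortical	571	116	FALSE	18
pooled_focal_infarct	focal_infarct	195	8	FALSE	3
pooled_thalamus	thalamus	289	146	FALSE	18
pooled_pallidum	pallidum	190	85	FALSE	14
pooled_putamen	putamen	221	96	FALSE	15
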