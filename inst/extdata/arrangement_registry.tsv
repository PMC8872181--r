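label	iqm_or_qim	hotspot
typical	IQM	tRNA-Pro,CR,tRNA-Phe
V	QIM	CR,tRNA-Pro,tRNA-Phe,CR
IX	QIM	CR,tRNA-Phe,tRNA-Pro,CR,tRNA-Phe,CR
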