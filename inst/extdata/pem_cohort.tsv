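sample_id	patient_id	asbestos_exposure	subtype	has_wes	has_wts	has_ms
MESO-01	MESO-01	unknown	BAP1-intact	yes	no	yes
MESO-02	MESO-02	unknown	BAP1-del	yes	yes	yes
MESO-03	MESO-03	unknown	BAP1-intact	yes	no	yes
MESO-04	MESO-04	unknown	BAP1-intact	yes	no	yes
MESO-05	MESO-05	unknown	BAP1-del	yes	yes	yes
MESO-06	MESO-06	no	BAP1-del	yes	yes	yes
MESO-07	MESO-07	unknown	BAP1-del	yes	yes	yes
MESO-08	MESO-08	no	BAP1-intact	yes	yes	no
MESO-09	MESO-09	no	BAP1-del	yes	yes	yes
MESO-10	MESO-10	no	BAP1-del	yes	yes	yes
MESO-11	MESO-11	no	BAP1-intact	yes	yes	yes
MESO-12	MESO-12	no	BAP1-intact	yes	yes	yes
MESO-13	MESO-13	no	BAP1-intact	yes	yes	yes
MESO-14	MESO-14	no	BAP1-del	yes	yes	yes
MESO-15	MESO-15	no	BAP1-intact	yes	no	no
MESO-17	MESO-17	no	BAP1-del	yes	yes	yes
MESO-18A	MESO-18	no	BAP1-intact	yes	yes	yes
MESO-18E	MESO-18	no	BAP1-intact	yes	yes	yes
MESO-19	MESO-19	yes	BAP1-intact	yes	yes	no
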