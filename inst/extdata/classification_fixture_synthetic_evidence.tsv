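gene	variant	expected_class	contributors	included	exclude_reason	ptc	control_af	patient_af	missense_score	splice_delta	minigene_result	segregation_consistent	genotype_context
GPR98	c.8992_8994delinsAAGTTCC	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
USH2A	c.14475_14484del	Pathogenic	g,a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	yes	NA
USH2A	c.14766delG	Pathogenic	g,a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	yes	NA
CDH23	c.5015_5016delAT	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
USH2A	c.2882delA	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
GPR98	c.2864C>A	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
MYO7A	c.5502G>A	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
GPR98	c.7129C>T	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
GPR98	c.13536_13537delTC	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
USH1C	c.496+1C>T	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
TMC1	c.1165C>T	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
GJB2	c.35delG	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
OTOF	c.1392+1G>T	Pathogenic	a	TRUE	NA	TRUE	NA	NA	NA	NA	NA	NA	NA
CDH23	c.9278+5G>C	UV4	f	TRUE	NA	NA	NA	NA	NA	NA	deleterious	NA	NA
CDH23	c.6829+1G>A	UV4	e	TRUE	NA	NA	NA	NA	NA	0.90	NA	NA	NA
USH2A	c.1055C>T	UV4	c,d	TRUE	NA	NA	NA	0.02	0.90	NA	NA	NA	NA
PDZD7	c.1011C>T	Neutral	b,e	TRUE	NA	NA	0.03	NA	NA	0.05	NA	NA	NA
CLRN1	c.472+4C>T	Neutral	b	TRUE	NA	NA	0.04	NA	NA	NA	NA	NA	NA
MYO15A	c.3413A>G	Neutral	b	TRUE	NA	NA	0.05	NA	NA	NA	NA	NA	NA
USH1C	c.307C>T	UV3	d	TRUE	NA	NA	NA	NA	0.90	NA	NA	NA	NA
CDH23	c.9904G>A	UV3	d	TRUE	NA	NA	NA	NA	0.92	NA	NA	NA	NA
MYO7A	c.472G>A	UV3	d	TRUE	NA	NA	NA	NA	0.88	NA	NA	NA	NA
GPR98	c.10820T>C	UV3	d	TRUE	NA	NA	NA	NA	0.85	NA	NA	NA	NA
CDH23	c.3995T>G	UV3	d	TRUE	NA	NA	NA	NA	0.90	NA	NA	NA	NA
USH2A	c.13010C>T	UV3	d	TRUE	NA	NA	NA	NA	0.85	NA	NA	NA	NA
PCDH15	c.875C>G	UV3	b,d,h	TRUE	NA	NA	0.005	NA	0.90	NA	NA	NA	supports
MYO7A	c.6220C>T	UV2	d	TRUE	NA	NA	NA	NA	0.60	NA	NA	NA	NA
PCDH15	c.1205G>C	UV2	d	TRUE	NA	NA	NA	NA	0.65	NA	NA	NA	NA
TECTA	c.3239A>T	UV2	d	TRUE	NA	NA	NA	NA	0.60	NA	NA	NA	NA
MYO15A	c.9478C>T	UV2	b,d	TRUE	NA	NA	0.005	NA	0.60	NA	NA	NA	NA
GPR98	c.2727C>A	UV2	e	TRUE	NA	NA	NA	NA	NA	0.45	NA	NA	NA
GPR98	c.9366A>G	UV2	e	TRUE	NA	NA	NA	NA	NA	0.50	NA	NA	NA
GPR98	c.17756-4A>G	UV2	e	TRUE	NA	NA	NA	NA	NA	0.40	NA	NA	NA
MYO7A	c.1134C>T	UV2	e	TRUE	NA	NA	NA	NA	NA	0.45	NA	NA	NA
DFNB31	c.1204-17A>G	UV2	e	TRUE	NA	NA	NA	NA	NA	0.50	NA	NA	NA
MYO7A	c.849+7C>G	UV2	e	TRUE	NA	NA	NA	NA	NA	0.40	NA	NA	NA
USH2A	c.14904C>T	UV2	e	TRUE	NA	NA	NA	NA	NA	0.45	NA	NA	NA
MYO15A	c.1656C>T	UV2	e	TRUE	NA	NA	NA	NA	NA	0.50	NA	NA	NA
TECTA	c.3456G>A	UV2	e	TRUE	NA	NA	NA	NA	NA	0.40	NA	NA	NA
PDZD7	c.1452G>T	UV2	e	TRUE	NA	NA	NA	NA	NA	0.45	NA	NA	NA
VEZT	c.1831+4A>G	UV2	e	TRUE	NA	NA	NA	NA	NA	0.45	NA	NA	NA
CDH23	c.9319G>T	UV2	h	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	supports
VEZT	c.1396G>A	UV2	h	TRUE	NA	NA	NA	NA	NA	NA	NA	NA	supports
USH2A	c.14662A>T	UV1	d	TRUE	NA	NA	NA	NA	0.25	NA	NA	NA	NA
PDZD7	c.1916C>G	UV1	d	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	NA
USH1C	c.2585C>T	UV1	d	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	NA
USH2A	c.8575C>T	UV1	d	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	NA
OTOF	c.1966C>T	UV1	d	TRUE	NA	NA	NA	NA	0.25	NA	NA	NA	NA
MYO15A	c.806C>T	UV1	d	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	NA
CDH23	c.4891G>A	UV1	d	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	NA
PCDH15	c.55T>A	UV1	d,h	TRUE	NA	NA	NA	NA	0.30	NA	NA	NA	supports
GJB3	c.94C>T	UV1	b	TRUE	NA	NA	0.005	NA	NA	NA	NA	NA	NA
MYO15A	c.7468G>A	UV1	b	TRUE	NA	NA	0.005	NA	NA	NA	NA	NA	NA
PDZD7	c.2144C>T	UV1	b	TRUE	NA	NA	0.005	NA	NA	NA	NA	NA	NA
MYO15A	c.1385G>A	UV1	b	TRUE	NA	NA	0.005	NA	NA	NA	NA	NA	NA
MYO15A	c.10242C>T	UV1	b,e	TRUE	NA	NA	0.005	NA	NA	0.05	NA	NA	NA
MYO15A	c.54G>A	UV1	b,e	TRUE	NA	NA	0.005	NA	NA	0.05	NA	NA	NA
MYO15A	c.7908C>T	UV1	b,e	TRUE	NA	NA	0.005	NA	NA	0.05	NA	NA	NA
MYO15A	c.5133+15A>G	UV1	b,e	TRUE	NA	NA	0.005	NA	NA	0.05	NA	NA	NA
MYO15A	c.10182G>A	UV1	b,e	TRUE	NA	NA	0.005	NA	NA	0.05	NA	NA	NA
USH1C	c.101A>G	UV2	b	FALSE	frequency value not printed; contributor b maps to UV1 elsewhere	NA	NA	NA	NA	NA	NA	NA	NA
USH2A	c.653T>A	UV3	c,d	FALSE	contributor pair c,d maps to UV4 elsewhere; disambiguating values not printed	NA	NA	NA	NA	NA	NA	NA	NA
USH2A	c.949C>A	UV4	c	FALSE	patient-frequency-only escalation not quantifiable from the printed row	NA	NA	NA	NA	NA	NA	NA	NA
CDH23	c.6050-9G>A	Pathogenic	c	FALSE	pathogenicity rests on prior knowledge of the variant, not the printed evidence	NA	NA	NA	NA	NA	NA	NA	NA
MYO7A	c.687C>T	UV3	e	FALSE	contributor e maps to UV2/UV4 elsewhere; splice score not printed	NA	NA	NA	NA	NA	NA	NA	NA
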