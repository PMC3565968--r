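# Published profiles of the CD (cluster of differentiation) proteins
# identified in the mES E14.Tg2a N-glycoproteome: stoichiometry-normalized
# glycoprotein spectral counts, detected N-glycans (stoichiometry) and
# putative sequons, with TMHMM transmembrane-helix counts.
cd_name	symbol	tms	protein_spectra	detected_glycosites	putative_glycosites
CD107b	Lamp2	1	17.0	9	17
CD108	Sema7a	1	3.5	2	5
CD116	Csf2ra	1	3.5	2	8
CD133	Prom1	5	8.0	5	8
CD147	Bsg	1	17.0	3	4
CD155	Pvr	1	12.0	2	11
CD157	Bst1	1	3.0	1	4
CD166	Alcam	1	9.0	2	8
CD201	Procr	1	10.0	1	5
CD202b	Tek	2	4.0	2	12
CD230	Prnp	2	12.0	1	2
CD276	Cd276	1	50.0	4	4
CD280	Mrc2	1	5.0	4	14
CD315	Ptgfrn	1	11.0	4	4
CD316	Igsf8	1	25.0	3	4
CD317	Bst2	1	65.0	1	2
CD318	Cdcp1	1	1.6	5	14
CD322	Jam2	1	16.0	2	5
CD326	Tacstd1	1	61.0	2	2
CD331	Fgfr1	1	12.0	2	9
CD339	Jag1	1	3.0	2	12
CD49a	Itga1	2	5.1	7	23
CD66a	Ceacam1	1	19.0	8	16
CD90	Thy1	0	19.0	1	4
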