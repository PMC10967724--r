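age	term_id	term_name	n_de	n_term
5d	GO:0003677	DNA binding	5	355
9d	GO:0003677	DNA binding	60	355
9d	GO:0005739	Mitochondrion	41	1044
9d	GO:0005886	Plasma membrane	11	1395
9d	GO:0009190	Cyclic nucleotide biosynthetic process	33	93
9d	GO:0016070	RNA metabolic process	25	720
9d	GO:0016779	Nucleotidyltransferase activity	10	84
9d	GO:0016791	Phosphatase activity	9	159
9d	GO:0016849	Phosphorus-oxygen lyase activity	34	93
9d	GO:0016874	Ligase activity	14	255
9d	GO:0016887	ATPase activity	35	432
9d	GO:0035556	Intracellular signal transduction	36	438
9d	GO:0065008	Regulation of biological quality	11	723
11d	GO:0002376	Immune system process	6	401
11d	GO:0003677	DNA binding	62	355
11d	GO:0005694	Chromosome	8	294
11d	GO:0005739	Mitochondrion	35	1044
11d	GO:0005886	Plasma membrane	16	1395
11d	GO:0006281	DNA repair	6	268
11d	GO:0009190	Cyclic nucleotide biosynthetic process	40	93
11d	GO:0015979	Photosynthesis	11	56
11d	GO:0016070	RNA metabolic process	26	720
11d	GO:0016757	Transferase activity, transferring glycosyl groups	43	121
11d	GO:0016779	Nucleotidyltransferase activity	14	84
11d	GO:0016849	Phosphorus-oxygen lyase activity	42	93
11d	GO:0016887	ATPase activity	42	432
11d	GO:0035556	Intracellular signal transduction	45	438
11d	GO:0042578	Phosphoric ester hydrolase activity	11	190
11d	GO:0042592	Homeostatic process	15	313
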