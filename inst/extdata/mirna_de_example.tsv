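feature_id	log2FoldChange	padj
hsa-miR-10a-5p	4.37	2.43E-18
hsa-miR-141-3p	4.67	1.31E-15
hsa-miR-30a-5p	2.87	1.37E-12
hsa-miR-183-5p	4.62	4.90E-06
hsa-miR-30d-5p	1.63	1.44E-05
hsa-miR-30c-5p	1.98	2.39E-05
hsa-miR-182-5p	3.77	4.94E-04
hsa-miR-98-5p	1.39	2.87E-03
hsa-miR-148b-3p	1.02	6.38E-03
hsa-miR-191-5p	1.24	6.87E-03
hsa-miR-143-3p	-2.81	6.61E-09
hsa-miR-127-3p	-1.91	1.41E-08
hsa-let-7c-5p	-3.09	2.11E-04
hsa-miR-99a-5p	-3.57	1.16E-03
hsa-miR-27b-3p	-1.80	2.87E-03
hsa-miR-199a-3p	-2.38	3.86E-03
hsa-miR-199b-3p	-2.38	3.86E-03
hsa-miR-146b-5p	-2.12	1.18E-02
hsa-miR-199a-5p	-2.18	1.31E-02
hsa-miR-23b-3p	-1.60	4.23E-02
hsa-miR-484	0.40	6.10E-01
hsa-miR-26a-5p	-0.22	8.40E-01
hsa-miR-16-5p	0.95	4.00E-02
hsa-miR-92a-3p	-1.40	2.10E-01
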