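# Gene Family	CSM5FZ3T	CSM5FZ46	CSM5FZ4G
UniRef90_A0A015QIN6	56.1085	5.34637	5.04212
UniRef90_A0A015QIN6|g_Bacteroides.s_Bacteroides_fragilis	34.9527	4.45395	0
UniRef90_A0A015QIN6|g_Bacteroides.s_Bacteroides_ovatus	0	0	1.67376
UniRef90_A0A015QIN6|g_Bacteroides.s_Bacteroides_uniformis	0	0	1.75071
UniRef90_A0A015QIN6|g_Bacteroides.s_Bacteroides_vulgatus	21.1558	0.89242	0
UniRef90_A0A015QIN6|g_Parabacteroides.s_Parabacteroides_distasonis	0	0	1.61765
UniRef90_A0A015QIN6|unclassified	0	0	0
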