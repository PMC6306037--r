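"Gene","Non-unique Gene name","Annotation","No. isolates","No. sequences","Avg sequences per isolate","Genome Fragment","Order within Fragment","Accessory Fragment","Accessory Order with Fragment","QC","Min group size nuc","Max group size nuc","Avg group size nuc","strainA","strainB","strainC","strainD"
"dnaA","","Chromosomal replication initiator protein","4","4","1","1","1","","","","1338","1350","1344","A_00001","B_00001","C_00001","D_00001"
"gyrB","","DNA gyrase subunit B","4","4","1","1","2","","","","2412","2415","2413","A_00002","B_00002","C_00002","D_00002"
"rpoB","","RNA polymerase beta subunit","4","4","1","1","3","","","","4104","4110","4107","A_00003","B_00003","C_00003","D_00003"
"nrps_1","","Non-ribosomal peptide synthetase","2","2","1","","","1","1","","7200","7230","7215","A_00410","","C_00388",""
"tps_geo","","Geosmin synthase","3","3","1","","","1","2","","2190","2196","2193","A_00822","B_00791","","D_00765"
"hyp_77","","hypothetical protein","1","1","1","","","2","1","","450","450","450","","","","D_01544"
"lanM_2","","Lanthipeptide synthetase","1","1","1","","","2","2","","3030","3030","3030","","B_01902","",""
"vgrG","","Type VI secretion spike protein","2","2","1","","","3","1","","1980","1995","1987","A_01203","","","D_01101"
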