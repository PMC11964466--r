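"table","region","phase","dataset","block","odi_km2","q1","q2","q3","n_raw"
1,"Great Britain","GI1DA","A","North",51900,2670,5117,5896,17
1,"N France","GI1DA","A","North",19940,2670,5117,5896,17
1,"Benelux & NW Germany","GI1DA","A","North",94010,2670,5117,5896,17
1,"S Scandinavia","GI1DA","A","North",27700,2670,5117,5896,17
1,"Poland & NE Germany","GI1DA","A","North",133500,2670,5117,5896,17
1,"Czech Rep. & SE Germany","GI1DA","A","Czech/SE Germany",115900,1057,1948,2626,10
1,"Switzerland & SW Germany","GI1DA","A","Alpine/Italy/SE France",33540,2604,3550,8662,19
1,"Italy","GI1DA","A","Alpine/Italy/SE France",15050,2604,3550,8662,19
1,"SE France","GI1DA","A","Alpine/Italy/SE France",25440,2604,3550,8662,19
1,"SW France","GI1DA","A","Southwest",39290,1578,2522,20730,7
1,"Spain & French Pyrenees","GI1DA","A","Southwest",69720,1578,2522,20730,7
1,"Portugal","GI1DA","A","Southwest",9351,1578,2522,20730,7
2,"Great Britain","GS1","A","North",25830,2934,5187,7462,4
2,"N France","GS1","A","North",13950,2934,5187,7462,4
2,"Benelux & NW Germany","GS1","A","North",52500,2934,5187,7462,4
2,"S Scandinavia","GS1","A","North",1350,2934,5187,7462,4
2,"Poland & NE Germany","GS1","A","North",149000,2934,5187,7462,4
2,"Czech Rep. & SE Germany","GS1","A","Czech/SE Germany",53670,970,4959,14826,11
2,"Switzerland & SW Germany","GS1","A","Alpine/Italy/SE France",23050,3160,4336,9988,14
2,"Italy","GS1","A","Alpine/Italy/SE France",32500,3160,4336,9988,14
2,"SE France","GS1","A","Alpine/Italy/SE France",19480,3160,4336,9988,14
2,"SW France","GS1","A","Southwest",24740,2420,4337,13094,10
2,"Spain & French Pyrenees","GS1","A","Southwest",75710,2420,4337,13094,10
2,"Portugal","GS1","A","Southwest",8780,2420,4337,13094,10
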