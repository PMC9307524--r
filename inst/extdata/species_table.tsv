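assembly_group	species	phylum	k	K_max	growth_group	inoculum	kinetics_source
A	Achnanthidium pyrenaicum	Bacillariophyta	0.016	0.161	none	125000	od685
A	Cyclotella meneghiniana	Bacillariophyta	0.017	0.285	none	125000	od685
B	Gomphonema parvulum	Bacillariophyta	0.011	0.231	G1	75000	od685
B	Gomphonema clavatum	Bacillariophyta	0.014	0.211	G1	75000	od685
B	Synedra sp.	Bacillariophyta	0.014	0.195	G1	75000	od685
B	Fragilaria crotonensis	Bacillariophyta	0.016	0.059	G2	125000	od685
B	Fragilaria capucina	Bacillariophyta	0.033	0.048	G2	125000	od685
B	Melosira sp.	Bacillariophyta	0.018	0.051	G2	125000	od685
B	Cymbella cistula	Bacillariophyta	0.018	0.034	G3	133000	od685
B	Tabellaria sp.	Bacillariophyta	0.007	0.142	G3	133000	od685
B	Ulnaria ulna	Bacillariophyta	0.010	0.081	G3	133000	od685
C	Scenedesmus acuminatus	Chlorophyta	0.019	0.797	G1	65000	od685
C	Chlorella vulgaris	Chlorophyta	0.009	0.735	G1	65000	od685
C	Pediastrum boryanum	Chlorophyta	0.011	0.393	G1	65000	od685
C	Merismopedia glauca	Cyanobacteria	0.009	0.747	G1	65000	od685
C	Cyclotella meneghiniana	Bacillariophyta	0.018	0.285	G2	125000	od685
C	Nitzschia palea	Bacillariophyta	0.025	0.197	G2	125000	od685
C	Nitzschia vermicularis	Bacillariophyta	0.012	0.023	G2	125000	cell_count
C	Craticula accomoda	Bacillariophyta	0.019	0.191	G2	125000	od685
C	Sellaphora minima	Bacillariophyta	0.025	0.198	G2	125000	od685
C	Scenedesmus vacuolatus	Chlorophyta	0.017	0.536	G2	125000	od685
C	Pediastrum duplex	Chlorophyta	0.021	0.660	G2	125000	od685
C	Chamaesiphon polonicus	Cyanobacteria	0.007	0.526	G2	125000	od685
C	Phormidium sp.	Cyanobacteria	0.022	0.295	G2	125000	od685
C	Pseudanabaena galeata	Cyanobacteria	0.020	0.520	G2	190000	od685
C	Botryococcus braunii	Chlorophyta	0.005	0.417	G3	300000	od685
C	Craticula cuspidata	Bacillariophyta	0.007	0.066	G3	300000	od685
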