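Type	APOBEC.CT	APOBEC.CG	BG01	BG02	BG03	BG04	BG05	BG06
A[C>A]A	0.001503	0.001503	0	0.010169	0	0	0.156152	0.005256
A[C>A]C	0.001503	0.001503	8.1e-05	0	5.6e-05	3.1e-05	0	4.6e-05
A[C>A]G	0.001503	0.001503	0	5.3e-05	0.001026	0	0	0.056005
A[C>A]T	0.001503	0.001503	0	0	0	0	0	0
C[C>A]A	0.001503	0.001503	0.01804	0.004236	0	0	4e-06	8.5e-05
C[C>A]C	0.001503	0.001503	0	0	0.021424	0	0	0
C[C>A]G	0.001503	0.001503	6.1e-05	1e-06	0.000229	0	3.9e-05	2.3e-05
C[C>A]T	0.001503	0.001503	0.000185	0	1.7e-05	0	0	0.007088
G[C>A]A	0.001503	0.001503	0	0.095019	0.000533	0	0	0.000116
G[C>A]C	0.001503	0.001503	1e-06	1e-06	0	0	0	0.005445
G[C>A]G	0.001503	0.001503	0	0	0	0	0	0
G[C>A]T	0.001503	0.001503	0.002287	0.000584	0	0.036991	0	0
T[C>A]A	0.001503	0.001503	0.011708	7.5e-05	0.000279	0	0	0.000114
T[C>A]C	0.001503	0.001503	0.000619	0	0	0	0	0.004156
T[C>A]G	0.001503	0.001503	0.03584	7e-05	0.000836	0	7.8e-05	0
T[C>A]T	0.001503	0.001503	0.000327	0	0	1.3e-05	3.6e-05	0.000224
A[C>G]A	0.001503	0.001503	0.000831	0	0.000689	0	0.000293	0.002193
A[C>G]C	0.001503	0.001503	0	0	0.000137	0.000831	0.136192	0
A[C>G]G	0.001503	0.001503	0	0	0	0	0.002708	5e-06
A[C>G]T	0.001503	0.001503	0	0.109065	7e-06	0	0.001535	0.000264
C[C>G]A	0.001503	0.001503	0	3.3e-05	0.036573	0.012036	0.012598	0
C[C>G]C	0.001503	0.001503	0	1.5e-05	1e-06	2.7e-05	0.005388	0.003931
C[C>G]G	0.001503	0.001503	0	4e-06	0	0.00011	0	0
C[C>G]T	0.001503	0.001503	0	0	0.001408	4e-05	0	0.000273
G[C>G]A	0.001503	0.001503	0	0	0.000165	0	2.1e-05	0.300117
G[C>G]C	0.001503	0.001503	0	0.026226	8.6e-05	1e-06	0.040433	3e-06
G[C>G]G	0.001503	0.001503	5.3e-05	2.8e-05	0.001773	0	0.094482	0.002417
G[C>G]T	0.001503	0.001503	0	0	0.000212	0	0	0.008407
T[C>G]A	0.001503	0.400802	0.000315	0.000128	0.001146	3e-05	0.000803	0
T[C>G]C	0.001503	0.07014	1e-06	0	1e-05	0	0.004988	0.012207
T[C>G]G	0.001503	0.06012	3e-06	4.7e-05	0.050672	0	3e-06	0
T[C>G]T	0.001503	0.330661	0.127677	0.073443	0	0	0	0.000916
A[C>T]A	0.001503	0.001503	6.6e-05	0.002168	0	0.0037	0	0
A[C>T]C	0.001503	0.001503	0.1112	0	0	0.001139	0	0.014478
A[C>T]G	0.001503	0.001503	3e-06	0.00996	0	8.4e-05	0.001076	0
A[C>T]T	0.001503	0.001503	0.002409	0	0.001172	0	0.018019	0.000652
C[C>T]A	0.001503	0.001503	0	0	2e-06	0	0.004197	0.001299
C[C>T]C	0.001503	0.001503	2.4e-05	0	6e-06	0	2.4e-05	0.00012
C[C>T]G	0.001503	0.001503	0	0	0	8.6e-05	0	0.000489
C[C>T]T	0.001503	0.001503	0	0	0.004002	0.008146	0.009073	0.007674
G[C>T]A	0.001503	0.001503	1e-06	0.00437	8e-06	0.01676	0	4.1e-05
G[C>T]C	0.001503	0.001503	0.218544	0	0	0	0.018369	0.001343
G[C>T]G	0.001503	0.001503	4.3e-05	0	0	0.011993	3.2e-05	0.000108
G[C>T]T	0.001503	0.001503	0	0.000271	3e-06	0.000508	0	0.013396
T[C>T]A	0.400802	0.001503	0.000547	0	1e-06	0	0	0.001162
T[C>T]C	0.07014	0.001503	0	0.009023	0	0.026148	0.000277	0
T[C>T]G	0.06012	0.001503	0.000132	1e-06	0.000467	6.7e-05	0.000972	0.000558
T[C>T]T	0.330661	0.001503	1e-06	0.054044	0.128354	0.000245	0.000698	0.001384
A[T>A]A	0.001503	0.001503	0	0.000578	0.000315	0	0	0
A[T>A]C	0.001503	0.001503	7e-06	0.000549	0.00052	0.014442	0.022884	3.9e-05
A[T>A]G	0.001503	0.001503	0.001838	0.002762	0	0	0.004008	4e-06
A[T>A]T	0.001503	0.001503	0.00231	1e-06	0	0	0.030722	1e-06
C[T>A]A	0.001503	0.001503	0.003095	0	2.6e-05	0	5.4e-05	0
C[T>A]C	0.001503	0.001503	0.001109	1.8e-05	1.4e-05	0.011425	1e-05	0.074126
C[T>A]G	0.001503	0.001503	0.001029	0	0	0	0.002312	0.200576
C[T>A]T	0.001503	0.001503	0	0.027481	0	0	0.000496	0
G[T>A]A	0.001503	0.001503	0.001654	0.000147	0	0.016166	0.002836	0
G[T>A]C	0.001503	0.001503	9e-06	0.000134	2.1e-05	3e-06	0	0
G[T>A]G	0.001503	0.001503	0.008718	0.066045	0	0.000719	0.002245	0.036425
G[T>A]T	0.001503	0.001503	4e-06	1e-06	0.114458	0.000132	0.000839	0.006171
T[T>A]A	0.001503	0.001503	0	0	2e-06	0	5e-06	7e-06
T[T>A]C	0.001503	0.001503	0	0	0.000178	0.074719	0	0.083553
T[T>A]G	0.001503	0.001503	0.001013	0.253249	5.8e-05	1e-06	7e-05	0
T[T>A]T	0.001503	0.001503	0.000384	0	0.054347	2e-06	0	0.08767
A[T>C]A	0.001503	0.001503	0	0.016514	0.004504	0.003831	0.191206	0.002907
A[T>C]C	0.001503	0.001503	0.000771	0.000192	0	0.512014	0	0.011276
A[T>C]G	0.001503	0.001503	3.8e-05	0	0.11191	0.000992	0	3e-06
A[T>C]T	0.001503	0.001503	0.001932	1e-06	0.004711	0.0127	0.175603	0.008376
C[T>C]A	0.001503	0.001503	0.026792	0	0.387401	9e-06	0.001526	0
C[T>C]C	0.001503	0.001503	0.000114	0.00192	0	0	1e-06	0.001498
C[T>C]G	0.001503	0.001503	0	1e-04	0	0	0.001012	0
C[T>C]T	0.001503	0.001503	0.000628	0	0.008481	0	0.000345	0
G[T>C]A	0.001503	0.001503	0.233386	0.000216	0.004396	0.000539	0.000147	0.008128
G[T>C]C	0.001503	0.001503	0.000981	5e-06	0.008543	0.01018	2e-06	0.003816
G[T>C]G	0.001503	0.001503	0.000329	4e-06	2.4e-05	0	0.00567	6e-06
G[T>C]T	0.001503	0.001503	0.00011	1e-06	0.000606	4.1e-05	5e-06	0
T[T>C]A	0.001503	0.001503	6.1e-05	0	1.5e-05	0.144516	0.00928	0.002054
T[T>C]C	0.001503	0.001503	0.0024	0.000661	0.01961	0.000477	0	0.009026
T[T>C]G	0.001503	0.001503	0.008037	1.2e-05	0	0	0.004715	0
T[T>C]T	0.001503	0.001503	0	0.107811	2.3e-05	0.068978	0	0
A[T>G]A	0.001503	0.001503	0.044707	0.002043	0	0	0.000346	0
A[T>G]C	0.001503	0.001503	0.001865	4.9e-05	0	0	0.008287	0
A[T>G]G	0.001503	0.001503	0.000582	0	0.004106	2.1e-05	5e-06	0
A[T>G]T	0.001503	0.001503	0	0	0.003649	0.000516	0	0
C[T>G]A	0.001503	0.001503	0.062193	0.000458	0.001287	0	0	0.000499
C[T>G]C	0.001503	0.001503	0.001317	0	7.1e-05	0	1e-06	0
C[T>G]G	0.001503	0.001503	0	0.031214	0.001619	0	0.001181	0.004895
C[T>G]T	0.001503	0.001503	0.001429	0.032883	0	3.7e-05	2.4e-05	0.000226
G[T>G]A	0.001503	0.001503	0	0	0.002857	0	0.005701	0
G[T>G]C	0.001503	0.001503	0	0.027016	0.000134	3.5e-05	0	8e-06
G[T>G]G	0.001503	0.001503	1e-05	2.9e-05	0	0	0	0.006683
G[T>G]T	0.001503	0.001503	0	1.7e-05	0	0	2e-06	0
T[T>G]A	0.001503	0.001503	0.02077	0.022767	0	0	0.002131	1.1e-05
T[T>G]C	0.001503	0.001503	0.013573	1.7e-05	0.014823	0	0.000513	0
T[T>G]G	0.001503	0.001503	0.025808	0.00482	0	0.001631	0.01708	2e-05
T[T>G]T	0.001503	0.001503	0	0.001252	0	0.006892	0.000247	0
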