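Type	SBS1	SBS2	SBS3	SBS13	SBS18
A[C>A]A	0	0	0.01528	0	0.045685
A[C>A]C	0	0	0.015572	0	0.045685
A[C>A]G	0	0	0.012957	0	0.045685
A[C>A]T	0	0	0.009031	0	0.045685
C[C>A]A	0	0	0.006306	0	0.045685
C[C>A]C	0	0	0.006367	0	0.045685
C[C>A]G	0	0	0.008741	0	0.045685
C[C>A]T	0	0	0.01131	0	0.045685
G[C>A]A	0	0	0.011957	0	0.071066
G[C>A]C	0	0	0.010196	0	0.045685
G[C>A]G	0	0	0.007533	0	0.045685
G[C>A]T	0	0	0.006307	0	0.045685
T[C>A]A	0	0	0.007875	0	0.091371
T[C>A]C	0	0	0.011528	0	0.045685
T[C>A]G	0	0	0.014959	0	0.045685
T[C>A]T	0	0	0.015953	0	0.081218
A[C>G]A	0	0	0.014006	0.006173	0.00203
A[C>G]C	0	0	0.010677	0.006173	0.00203
A[C>G]G	0	0	0.008394	0.006173	0.00203
A[C>G]T	0	0	0.008629	0.006173	0.00203
C[C>G]A	0	0	0.010822	0.006173	0.00203
C[C>G]C	0	0	0.01285	0.006173	0.00203
C[C>G]G	0	0	0.012704	0.006173	0.00203
C[C>G]T	0	0	0.010068	0.006173	0.00203
G[C>G]A	0	0	0.006617	0.006173	0.00203
G[C>G]C	0	0	0.004795	0.006173	0.00203
G[C>G]G	0	0	0.005986	0.006173	0.00203
G[C>G]T	0	0	0.009465	0.006173	0.00203
T[C>G]A	0	0	0.012927	0.360082	0.00203
T[C>G]C	0	0	0.014181	0.123457	0.00203
T[C>G]G	0	0	0.012756	0.102881	0.00203
T[C>G]T	0	0	0.010188	0.339506	0.00203
A[C>T]A	0.01	0.045455	0.008799	0	0.00203
A[C>T]C	0.01	0.045455	0.009887	0	0.00203
A[C>T]G	0.22	0	0.012709	0	0.00203
A[C>T]T	0.01	0.045455	0.015036	0	0.00203
C[C>T]A	0.01	0.045455	0.014849	0	0.00203
C[C>T]C	0.01	0.045455	0.011904	0	0.00203
C[C>T]G	0.22	0	0.007967	0	0.00203
C[C>T]T	0.01	0.045455	0.005543	0	0.00203
G[C>T]A	0.01	0.045455	0.00604	0	0.00203
G[C>T]C	0.01	0.045455	0.008767	0	0.00203
G[C>T]G	0.22	0	0.011494	0	0.00203
G[C>T]T	0.01	0.045455	0.012166	0	0.00203
T[C>T]A	0.01	0.045455	0.010454	0	0.00203
T[C>T]C	0.01	0.045455	0.007983	0	0.00203
T[C>T]G	0.22	0.454545	0.007055	0	0.00203
T[C>T]T	0.01	0.045455	0.008849	0	0.00203
A[T>A]A	0	0	0.012465	0	0.00203
A[T>A]C	0	0	0.015543	0	0.00203
A[T>A]G	0	0	0.015997	0	0.00203
A[T>A]T	0	0	0.013562	0	0.00203
C[T>A]A	0	0	0.009983	0	0.00203
C[T>A]C	0	0	0.007708	0	0.00203
C[T>A]G	0	0	0.008071	0	0.00203
C[T>A]T	0	0	0.010335	0	0.00203
G[T>A]A	0	0	0.01231	0	0.00203
G[T>A]C	0	0	0.012079	0	0.00203
G[T>A]G	0	0	0.009503	0	0.00203
G[T>A]T	0	0	0.006369	0	0.00203
T[T>A]A	0	0	0.00506	0	0.00203
T[T>A]C	0	0	0.00675	0	0.00203
T[T>A]G	0	0	0.010492	0	0.00203
T[T>A]T	0	0	0.013886	0	0.00203
A[T>C]A	0	0	0.014842	0	0.00203
A[T>C]C	0	0	0.013092	0	0.00203
A[T>C]G	0	0	0.010335	0	0.00203
A[T>C]T	0	0	0.008898	0	0.00203
C[T>C]A	0	0	0.009944	0	0.00203
C[T>C]C	0	0	0.01258	0	0.00203
C[T>C]G	0	0	0.014549	0	0.00203
C[T>C]T	0	0	0.01397	0	0.00203
G[T>C]A	0	0	0.010819	0	0.00203
G[T>C]C	0	0	0.007005	0	0.00203
G[T>C]G	0	0	0.004992	0	0.00203
G[T>C]T	0	0	0.005993	0	0.00203
T[T>C]A	0	0	0.009091	0	0.00203
T[T>C]C	0	0	0.011956	0	0.00203
T[T>C]G	0	0	0.012606	0	0.00203
T[T>C]T	0	0	0.010883	0	0.00203
A[T>G]A	0	0	0.008525	0	0.00203
A[T>G]C	0	0	0.007795	0	0.00203
A[T>G]G	0	0	0.0097	0	0.00203
A[T>G]T	0	0	0.013171	0	0.00203
C[T>G]A	0	0	0.015819	0	0.00203
C[T>G]C	0	0	0.015712	0	0.00203
C[T>G]G	0	0	0.012827	0	0.00203
C[T>G]T	0	0	0.009082	0	0.00203
G[T>G]A	0	0	0.006919	0	0.00203
G[T>G]C	0	0	0.00751	0	0.00203
G[T>G]G	0	0	0.009934	0	0.00203
G[T>G]T	0	0	0.011937	0	0.00203
T[T>G]A	0	0	0.011692	0	0.00203
T[T>G]C	0	0	0.00923	0	0.00203
T[T>G]G	0	0	0.006432	0	0.00203
T[T>G]T	0	0	0.005604	0	0.00203
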