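category_id	copy_number	alpha0	codons
C01	4	0.26	AUU UUU AAA GAU GUU ACU GUU AAU GCU AUU UUU GCC GGC GCC UCU GUU AAU ACU UCU GCU GGC CCA AAU AAU GAU GGU GGC GAU AUU AUU CCA GAU UUU CCA GGC GUU GAA GGC GCC UUU UCU GGC AUU AAU GGU UCU GCU UCU GGC GUU GUU GCU AGA GAU GGC GUU GAU GCC ACU UUU AAA GUU UCU GAA UUA UUU UUA UUA GCC AAA UUU UUA GCU AGA GAU ACU UUA AAA AAA AGA UAA
C02	2	0.2	GAA GAA UUA GGU AAU AAA UUU AAA GGU UCU UCU AAU GUU UCU GAA GGU GAA GAU CCA UUU GAU GGU GGU UUA UUA UUA UUU ACU UCU GCU GAU CCA ACU GAA UUU UUA GCU GGU ACU UUU UUU AGA GCC UUU GGC AGA GGU GAA GGU UCU GGC GAA AAA UCU UUU GGC GAA GGC CCA GAA UCU GAA GAU GGC GGC GCU GCU GAA GCU AUU CCA ACU GAA AAA AAA UCU GGC GAA GGU GCU UAA
C03	1	0.14	AAU AAA CCA GGC ACU ACU GUU GAA AUU AAU UUA AAA UUA CAG GCU ACU AAA UUA UCU AAU GAA CCA UCU AAA AAA GAA CCA AAA GAA UUA AGA UCU AUU AAA UUU CCA GCU UUA UUU GCU GAU GUU GAU GGU AAU CCA CAA UUA GAU ACU AUU AAU GCC UUU ACU GCU GAA GCU GAA GGC ACU AGA AAU ACU AGA GAA GCC AAU AAA GCU AGA GCC GGU UCU UUA GCU GCU AAA CCA UUU UAA
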