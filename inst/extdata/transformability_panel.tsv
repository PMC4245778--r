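id	efficiency	control	figure
pIMP1	3.7e4	pIMP1	1
pSY6catP	3.7e0	pIMP1	1
pMTL007C-E2	1.9e1	pMTL85141	1
pMTL007C-E6	3.2e0	pMTL85141	1
pMTL85141	1.5e4	pMTL85141	1
pLtrB	4.6e3	pIMP1	1
pLtrA	1.4e1	pIMP1	1
pDelPptb	2.1e1	pIMP1	1
pDel2dcm	0	pIMP1	1
pMB	8.8e3	pIMP1	1
pNS	2.8e1	pIMP1	1
pNM	4.2e1	pIMP1	1
pFrag1	7.1e1	pIMP1	2
pFrag2	3.5e4	pIMP1	2
pFrag3	9.7e3	pIMP1	2
pSY334	0	pMTL85141	2
pMut98	3.2e3	pSY6catP	2
pDelCpaAII	1.6e3	pSY6catP	2
pCpaAII	0	pMTL85141	2
pMTLCP-E2	1.9e3	pMTL007C-E2	1
pMTLCP-E6	2.7e3	pMTL007C-E6	1
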