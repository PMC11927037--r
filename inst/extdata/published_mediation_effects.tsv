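gene	ensembl_id	estimate	se	ci_low	ci_high
THOC6	ENSG00000131652	0.528537929	0.146587279	0.270349911	0.842467754
SCRT2	ENSG00000215397	0.528369276	0.159124611	0.250335962	0.871043373
LINC00863	ENSG00000224914	0.428609697	0.102347927	0.242730276	0.643212118
PSMA4	ENSG00000041357	0.408480231	0.087526865	0.243171387	0.586442599
RNF8	ENSG00000112130	0.313543069	0.080215658	0.170336067	0.483764696
JAKMIP3	ENSG00000188385	0.307312411	0.09005709	0.149626611	0.500961309
ALDH4A1	ENSG00000159423	0.301374235	0.0650878	0.178857672	0.434097964
WNK2	ENSG00000165238	0.280059593	0.085178087	0.13132544	0.463575069
LINC00908	ENSG00000266256	0.273575672	0.066563915	0.153316475	0.413666391
EVI5L	ENSG00000142459	0.217545779	0.048960468	0.126874325	0.318720419
LSM2	ENSG00000204392	0.206760981	0.052036423	0.113529442	0.316914886
TSPAN31	ENSG00000135452	0.200308695	0.045613421	0.116192414	0.294875944
GLIPR2	ENSG00000122694	0.196960348	0.063245409	0.08679654	0.333484278
LOC100129534	ENSG00000269896	0.192085843	0.054037444	0.097075309	0.307950314
OSGIN2	ENSG00000164823	0.180425923	0.048057425	0.095274538	0.282930021
AGAP1	ENSG00000157985	0.172155512	0.054303271	0.077508216	0.289315451
TATDN3	ENSG00000203705	0.166987385	0.037033471	0.098021989	0.243179188
WIPI2	ENSG00000157954	0.152771276	0.032239801	0.091470689	0.217930376
COPS6	ENSG00000168090	0.133873367	0.036258185	0.069798456	0.211348938
TPK1	ENSG00000196511	0.133637607	0.028207504	0.08000875	0.19065172
WASHC2A	ENSG00000099290	0.111529997	0.032153266	0.055146036	0.1805964
ENGASE	ENSG00000167280	0.105496715	0.027700751	0.056292667	0.164481726
ZC3H12C	ENSG00000149289	0.102334481	0.031776109	0.046911909	0.170854345
CCDC88B	ENSG00000168071	0.081069052	0.022234108	0.041848686	0.128636906
SLC12A7	ENSG00000113504	0.063459851	0.019910433	0.028749466	0.106409254
C2CD2L	ENSG00000172375	-0.096409301	0.028390227	-0.157474144	-0.046719791
BEGAIN	ENSG00000183092	-0.105020811	0.028333391	-0.165538596	-0.054920787
TM2D1	ENSG00000162604	-0.108036915	0.029122406	-0.170234451	-0.056534997
SLC66A3	ENSG00000162976	-0.120165064	0.027687981	-0.177745918	-0.069312574
COPB1	ENSG00000129083	-0.123983838	0.037988977	-0.205857229	-0.057678281
GINS2	ENSG00000131153	-0.128118848	0.035620656	-0.204420064	-0.065399074
EMB	ENSG00000170571	-0.138703792	0.037213028	-0.218140794	-0.072844923
RMC1	ENSG00000141452	-0.148978829	0.03831752	-0.230351253	-0.0806463
PCNX4	ENSG00000126773	-0.159968845	0.035096835	-0.23192693	-0.094331707
NDUFV3	ENSG00000160194	-0.177345736	0.045689535	-0.274395854	-0.095893887
KCNK13	ENSG00000152315	-0.179201351	0.052756082	-0.292673162	-0.086863824
RNFT1	ENSG00000189050	-0.184077345	0.05009639	-0.291173922	-0.095611102
PLXNB2	ENSG00000196576	-0.185289721	0.058012307	-0.31042083	-0.08414605
TUBGCP2	ENSG00000130640	-0.186409733	0.047527998	-0.287217056	-0.101498301
ITIH2	ENSG00000151655	-0.188967611	0.039539804	-0.268594601	-0.113494395
LINC01857	ENSG00000224137	-0.191983976	0.058853657	-0.318827339	-0.089264328
RPS18	ENSG00000231500	-0.197442023	0.040076805	-0.277006452	-0.119824302
PDK2	ENSG00000005882	-0.293512406	0.059998715	-0.413049774	-0.177713565
ZNF790-AS1	ENSG00000267254	-0.327953418	0.070443946	-0.471313316	-0.195048112
LOC105379362	ENSG00000247134	-0.339512189	0.074451414	-0.492132876	-0.200247515
GAMT	ENSG00000130005	-0.385787966	0.077663542	-0.539307778	-0.234752819
TIGD6	ENSG00000164296	-0.462131371	0.096682522	-0.656822392	-0.277572014
PKD1P3	ENSG00000183458	-0.471124831	0.093480737	-0.654422114	-0.287925984
MAP3K3	ENSG00000198909	-0.630369271	0.127025479	-0.881596474	-0.383460432
ERVH48-1	ENSG00000233056	-0.660367865	0.131184623	-0.917770773	-0.403505101
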