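>g0001|p001
DLKQIVWSIHRFQLISHCRGMEVGWYRSPFSRVVHLYRNGKRGNHVFDGVDQVDLYVFMHYDVESCPVAALCCLTRRDCQ
WKEMQANHPKKLYFTLECNFETVFVTCQPKWSLVKQLCTPEYISGATSSECCEDE
>g0001|p002
CMMWYACREWCPLEVQWLMWMHVEEDPWMGTTLSFYRPPFLRVRRPFYIIFLVGTNEENELHHRCFDPSHPNFAAFDEDS
MQEKASPEPGKAAVCTWASPKVSWFEQMSADWQGVCHQKKDGAQCAQ
>g0001|p003
MYMKYAKFHAPSCNWYAYKQVYIKPKRNWNWTPGTVKSTDQRSVHPKRTYVCKQHDREHIERSLWQYKSFWERWAWCTNW
RAGDPPVTFLGMPVVLRDGASVHACISARGTQRYHYWN
>g0001|p004
HMYGPWMMNEPTMHRLKSSVYHTKLIKQMCNDMHIGNSFVPTWKYEWMFLAYHTQWEWPVALPIVCKMQWDDPVLFSMEA
LEMNDSYRNKKPRVFSAGETSILRDQGESQNNHYDNF
>g0001|p005
TMVSNPQYDPFSTIPGCNKWFATGCTKARINQQTCYWEYESPRTTHRKSWHYVRSMLTAPKYSRMDDDWFTANIYMHNWW
MHIEEPPRDGSALLCFPTVCRKTNQHNYCINWEDRYPCHNLRVHQDLQMNHTDYIEN
>g0001|p006
RFEYYCIQTETDGICHIWTLTEWGESLGSAGEHTRRHFPWNDSMGFAEIMITLLNRLPLDIMADFSPTLNQANMYLRDDC
TMLPWANATEVKEQYDSPIKLQDGLGAFTGPPGLVFCHPMMNQNTIYNNGTHTGTFNPE
>g0001|p007
HGGDMSQCKYVMQIKVRKEYKDQTNYWAWYKVQFLVKVADGFQHIMQHVYPLMISSNILEYIGPLIPEMVMFRCPTTVCR
HTLEDWCSWSESMWWDNMCPQYEAKHPTFLHKIMILIMMMCGNHHSNQ
>g0001|p008
AHWGPSRFCQALVPRIIVAMWLRRLLDFSPSHQVNDSSRTKGSTINSAKGLCKASMSESNGRKFKVRHEFPHMKNLFCFG
VIGGPCWKWAYEWTETTQSFTEFLTSEPAAWLKGVCFP
>g0001|p009
TEVIMQSEYINYTTRGFKDNMTYRLRCLQLIPDCDYIKLRMYPAHHVMMCDQAMDRWPECTFQFYTSDSTYYGHALSWKD
NELTLCAFRTMPTPLFRAHYRN
>g0001|p010
SEGDIRPKCKIKKYDRMKLCDYRSVPRPYGWMMCKMMIYEDWSHLYPRWFEVEAQNHPMTEELKMGKLGVNKDESLWLGD
NFKCSKEGYWSESTEPTYNGHII
>g0002|p001
TVTYPWDTFLAYIPCHVIGYINKLSKWTHRKQLYNNSGHCPMVMCERQGLVLMFICRDLKKGGCITFRMIMYSEDKLQRA
QYAGSKLCSMNVHEE
>g0002|p002
YKHLYTDVCTMGGIPATACDSFHWQLTFNIREMMLHHSQSIINIQNKQFYKKPLEAESTPPVDENHYTFWHYEMNFERVA
YLYTVAVNEDEKVWNRNANEFLSDNVLHVEFNSLNKDWWIILFSMAW
>g0002|p003
MCWRICMEPYETAQFHLTCNLYCRGVKQQVCHKGIVTTIQMMKTVTERELRSTNPRYALYHAMTNWEYRLAFCRVKKTEI
VCSWAEVKWNFCWILALSWWIFEYWPEPHQPDYQHIVAKYEYNFLMRNERGM
>g0002|p004
LVFKINMCSFHWWHKRLTENFMPIDDLDVKFPQCHSDFWHFVDPAQAKCFVEYIWCRQAAFAQANIAGKPDERFYHGMKI
IKESDKHCPPRHKIWYMWGDNHWITMLCFRYEAAHAPDNRHNTL
>g0002|p005
CQKFPCSNSQRGYISNVAIAYTHYFGVHCKPWAMWCNLRWHKDHPCVQNQHILKNWAGMQLQELSHMQGMS
>g0002|p006
SPHNFRWPWSLVGNLIDKACCTAVDYLHCWLEWVQAQPYYFPPFPGSFHWNFHKTQCWHMCRSFPSGAVYECESCGLDPQ
RLMNPVLWDGVTPCVIYKVKEQPCIDSVCHIECKPRVP
>g0002|p007
DPDWHGSCPDRPYKHCNDSQQNWCKFLKRFKTSKLETSGWFCKILDGTTMVIMFRKDLSGKFWDGRKHSRGSQEAKSCNG
KTHGMDGPTMNIHCYLPMRLFENAGA
>g0002|p008
HKGGRFPQHELEKHPYLDYWPMCCEWCNAKYPLWMSFEDDMIPSNPIMVKLAEKPSEHQTIVEPDMAFWCACPSHIAPML
TYGCEINWVRHYYTPLWNATKGHYVPTTGPHNDYPIGLLWYQICDWN
>g0002|p009
INNTFFICITEKPTCFRLQMGYGNHAWYAMKDMPHYPFMEHKVAIGEPIMYAIHMPPDMTMNLSYFSIVTFCYTIVQALI
PLWYGAWFLTHPSYLE
>g0002|p010
IAEPQHATDYDLYKQQDHPKIITNILYFLMHMPYNYLNIDQASFMMNVEIMECYLNRDWEYQREIPWEVLSFMCWMTQGC
SDANLWIISP
>g0003|p001
WDESYRNMMWVWKFWSSGYAMCLAEAFVMFEETFDNWDFKIRFYNRSRRDRTTSHWMTARRMVPIHDTEKASQHFRIRLC
AFPQQILVQLSCNHMLPSNNFLITGKGTDRAHRPVRTTGHMQECCHNPQIRDWLCYM
>g0003|p002
YFYMFWILPPFKMEWGQDCCVMAWLIYHFKEVIMVSVAKVHNEYQKGRSGCECKWEGWTGCARYPAQCDITSINKCGSVF
NRQALSTEMRDHSVMVRKHAYRCTVVQACWLQTRVMIYYNTMIPS
>g0003|p003
GGTLMKDPQQTEFWMFDPGAVKEQPGWRLLLAFNRRFMMCQVKEKGYAYQASIHTFSEHEIIPTIWQKHIAHEGTTMTWY
AYYGHRPWGMDAAERWQHHRQWMGDGFMLSGPAWEQGTKHLKFLLVMYGKVWHYHE
>g0003|p004
FIKMFVHWLANKPNVTYDMWRTQFENRHKWYHLMWEHYCTWIYRESDKIAGQANPCKYYQICNMRQGCMEQTPQVSRNPL
GMSQVPMYENLLKYRQPNDQANDNNGYKDYQTTWKAD
>g0003|p005
QGLVGINKFPYVPLHWMFSPLAEPMRNNQAYIRKQIKHEQKAYVRKHNFHMPKWVHECNLFLVMWWVTYKRWYSQHPALQ
GHVICTFEEMGGLWHRWADNILGDFCLPLQISSGMAWLQTAEQKLN
>g0003|p006
DWMLVAQYCRNYPLPGLLIKYAQHWSRRKTLFTAIAFCVQTYSYVRMMGNGEHGNGFYYSYRDKKEGMHFSGYQMAWHRR
MCYVYRMSRCSISERCH
>g0003|p007
CMDWCYRKSDISFMNLWHKCNKSVQYNRTPCETDNTTIQIRGGDTHMTCQHPWYECKSYQFGFMDVWDNEKHIVYRESVC
LPVLMLHNTWGIRCATFIHSFNGIVYEDLSCTFRQSYE
>g0003|p008
TWTTQEYDQQSDTSTSGNGMKEASIHDSKGCRKQSKACVAHVPVTNYCLMGDWMPSYGDHSRLQRVMTCFVQSHHFFCNP
QYNETGIHHKITETMKTHEHEREATCRKWSEQIERTWIMSSAPTCGGPWH
>g0003|p009
PYCNIAFCTYWTEFPVLAYRGETQKYGGNDQWLKMDDDEYMMTNGTHSHGMCNSFFYEEVVKAKCERRVHRHNQIFGREI
FTVQTGSFN
>g0003|p010
HFNNGGFAMSIYIMSSLLYTTWKNTDSNCIYKHNLGMPATFNNQINSEEMKTSYIQFLDFEIPMWSAFYILIMPYQSLEG
AIIRCCVMREDYDPPPVCYWFTNMFGEHDWETDSWQYI
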