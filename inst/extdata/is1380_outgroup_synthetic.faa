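>IS1380_01 clade=outgroup synthetic outgroup stand-in
MYEVISVRDYFPEVAGNQHYEMILLGSFWCIHITLDPRCEWYLPQRNSMAQDCKNPKPMWTRYEWFKQVA
MICPTTWRTKRLAFVACCFFIGKHYSFYTCFKSMCHIFLVEISTIFGVYMLCMECCFQMQMRQMGWMMDM
KWRQNHFRRDNVGGMVTHSCWYKYGVLYPYFWSCEQWPTGIGKKAFRITDDVRVKFCKLMVQHFCWNGQV
YPWENRMSPYKPCVDVIGPDRLITYEGGVELARDFPREEHPYFWSCWMDNMEPYEKFICTYRKPKWTNRK
ISCSPVYHYFLSDKDNFQQAADYALHFVCIHDDKDQFHVLDFPQRWLIAEGIEDMSQRYLMIGYQAPRCR
EYHSMILIANQGNWYAETVEKCCAPMTCQKAWITHKKTWQGMSCEDTHHASYVWCSQDAPIGFIKGFPAN
WCYDMGRWRGLTGICVVWGIMFQMEEFVYG
>IS1380_02 clade=outgroup synthetic outgroup stand-in
MYHDISVCDYSPEVAGYQHYEGILPGFAWPIIATLYPFCRWYLTQRESMAQDCKNKKPVWMVYHWFNQVH
NICWTTWRLKRLAMHEALFFSWKHYSFYTIFCHMMHIFLSEDEKGYHKYMLCCEAGFYLQMRQGYRMMDM
YWRQNHFSRDNVGGMLTHSCWYQYQWLYWYFGTCEQWTTYHGKKPRRIKDPTEVKMCKLMVQHFCDNGQV
YIWEERMSPYHPRVDVAGPDALWYYEGGVELARDFYRVEQPPFESCWMDNWIPYEDFNCTNRKWKWVNRF
INCSNVRHYFESDKDNAQQSADYAHHFDCIHDDEKQFHVLDPPCMWLITEGIEDMSQRYLEIGYQAPRCR
HHHSQTLRAWRGNWYAETVEVPKAPMTSQKVQIARKKTWYNTKCSQTNHAVYVWVNHDCPQGCIKAFPMN
WCIDMGRKRMIYGICVTYGWMFGMEEFVYG
>IS1380_03 clade=outgroup synthetic outgroup stand-in
MYHVISVCDYFPEVAGKQHYEGILLGFAWPIHIWLYPKCYWYLTQRNSMAQDCKNKKTVWMRYMWFKQVH
AICWTMWRTKRLAMHAKLFFIGKHYSFPAWFKHMQHIFLSEDQAGFHKYMLCMEAQFQLQMRQMYWPMDM
KWRQNHFSRVNVWGEAEHSCDYQYIVLYPGFGSCEQWPTYHGKKPRRITDDVEVKSCKLGVQHFSHVGGT
LKWEEDMSPCKCPMDVIGTDALILYEGGVELARDFYRVEQPDFEDCWMDNWEPYEKGCCTNRNPKWVVRF
INHSNVMHKFESDNDCAQQAADYAHIFDCGHDGTKGFDVFDFPCMWLITEGIEDMSMRYLMIRYQAPRIR
EYHSMILDANQGNWGAETVEKPKAPMTSQKPQIARKHTGYGTSCWDTNHAIYTGGNQDCFQGCIKAFPCN
WCTIMGRWRMVTGICVDYGWMQYRESHVYG
>IS1380_04 clade=outgroup synthetic outgroup stand-in
MYHVITVCDCFYEVAYHQHYEWILLGFAWPIHITLYPKERWYYTPRNSMAQVCKNKKPVWMRYMWFKQVH
LLCWTHGRTFRLALHACLFFIGDHYSFYYIFKHQCHIFTSEDENGFHKYMLCMEAGFAHQSRQMYWMMPM
MMRQNHFRCDNVGGMLTQSCWNQYGVLYCRFGSCMQWPAYCGKKPRRITDDVEVKFCKRGVQHFCWNAQV
YPWEERMSRYKPPVDVIGPDALINYEGGVELTRDFYRVWQPYFISKWMANTELYECRCLTNRKPKWPNRF
INCSNVMSKFESDGDNAQQAADYDHAFDCIHDDTKQFHVGSFPCMWLIHEMIESKSQRYLNIGYQAPKDR
EYHSMILYANQGNWYAEIVSKYKTPMTSQKPQIARKWTWYGCWCYDTNEAVAVWGNYKCPQGCIKAFPAN
WHDDDGRWRKPTMICHDYYHMFQGEEFVYG
>IS1380_05 clade=outgroup synthetic outgroup stand-in
MYHVISGCAYFPYCAHNQHYEGEDLGFAWPIHITLYPNCRWYLTQRNSMHQDMKHKKPQFARYDWDKQVH
AICTTTWRTKRLAMHYCLFEIGKHYSFYTIFKHMGHIGLTEDTQGFHKYGLNMEMGFQLQMMAMYWFMDM
KWRQCHPRRDWCGGMMTHSCWYQYGVLYPYFGSCTQWPGYHGKKPMRIFDDVEVKFCKPMVQGFCWNGPV
YPWEERMSPFKPPDDYIGPDALPPYEGGVELARDFYRVEDPYFESCWMDNWGSYEKFCRTNRKPKWGNRF
INCSNVMHKFESHKDNAQEFADQAHHFQFIHNITMQFHWGFFPCMWLITEGLEDMSQRYLVIQYQAPRVR
EYHSCILRANQIWWYAETVEKPKARMTIQKPQIHRKKTWYGTSCEDTNHAVNVWANVDCPQGCIKAFPAN
WCHDMGNDRMITGACVRYGWMFQPEEIVYG
>IS1380_06 clade=outgroup synthetic outgroup stand-in
MYHVISVCHYFMELAVCQHYIVILLFFAWPIKITLYPKCRWYLTQRNSMAQAGKIKKPVNPRYMWDRQVH
DICWTTWMHKRLSMHACLFFIGNHISFYTIEKHDCHHGLTEDCCGFLKYMSCLEGGFQLQMRPMRWMLDM
KCSQNHKYTDWVYGMLGHSCQYIMGVLYPYDSSSEQKPTYYTWKQRRITDPYEVKFCKLMVQHNCWGAQV
YPWEQRLSEYKPPVDVISKTAVFNYEGGVELTRDFYRVEQPYFESSQADQGEPYECFCCTNRIQKWVNRA
INCSHVGHKFESNKLNAQQAIFYAHHFIRIHDDTKQHHPLDFPGMWLITGGIEDDSQRYLMIGYQAKRHR
GNHSMILRCNQGNWYAECVEKPKAPMFSQKPQAKRKKTWYGTSFEDTNHADYVWGNQDCFAGPIFYFPAN
WCDDNGRWTMITGICVDYRWMFQMEEFVYG
>IS1380_07 clade=outgroup synthetic outgroup stand-in
MYHKISVPDYFHIVAANQHYEGPLEGFAWPIHITLYPKCKWYAFLRNSMYQDCKNKKPVWYRYMWFKQVH
AICWTTKRTKRLAMHACLNFINKHYSFCTIFKHMFHIFLSEDEMEFHKYMLEYEAHFQLQRGQMYWMMEM
KDRQNHFRRDNVGGMLTHMCWHQYGVLYPYFGCCEQWPTYKFKKPRRICDDVEVKFCKLMVCHFCWNGQV
GPWERGMSPYKPPVDVIGEDALINYEGGVEAARHSYRVEQPYFESCWSDNWEPYEKHCCKNVKPQWTDRF
TNQSTVMHKFESDKDRAQQAADYPHHFDCIHDDTIQLHVLDFPCMHLISEGIEQMSQRYLVIGYQAPNCR
EYINMISRLNQGNWYAETGEKPKAPMTSKSSQIARKKTNYGTSCEDTNHAVYVVLNQDPHVGCIKAQFAK
WCDDVGRWRMITGICVDYGWDFQMEECVYG
>IS1380_08 clade=outgroup synthetic outgroup stand-in
MYHVISVCRYFPEVAGNQIYEGIPLPFAWPIHITLYEKCVWYITQRNSMAQDCKNKKPVWMRYMWFKNVH
AIRWWTWRTKVLCMHLCLFFIGKIGSFYTIFKHMNHIFLSKDECGFHFYMLNMELGFQLQMRAMYWMMSM
KWRQPHFRHDNVGGMLRHGVWYQYGVLYEYFGSCEQWPVYQGKKPRRIADDVFNQFCKLMHQHRCWNGDV
INWEERMSPYMPPVDVIGPDALINYFGGVALARDFYRVEQLYFEQCWCDNWEPYEKFCCTNRCPKWVNRF
INCSNVMWRFESDKDNAHQAADYAHHFDCIHEDTKQFHVLDAPCMWRITEGIEDMSQRDEMQGFQVERCR
EYHSMIQRANQINDYAETVERPLEPMCSQKPEIAYKKIGYGTSCLDTKDAVYVWGHQDCPQGCKKAFPAN
ECDDMGTWRMITGICVDYGSMAQMAEFVYM
>IS1380_09 clade=outgroup synthetic outgroup stand-in
MYHVISVCDWYPEVAGNQHYEGDLLGTAWPQHITLYPKCIRWLTQQNSMAQDCKPKKPVWLRYMWFKQVH
AICWTTWRTKRLAMHACGFFIGKHQSFYTIFKYMCHIISSEDECMDHKYMLCMENGFQLQWRQPIPMMDM
KWQQLHFRRDNIGMMLNLDCWYQWGNLYPYFGSCEQGPTYHGKKWRRITDDPEVKFCKNHMQHFKWAYMF
YPWEEVASPQKPPVPVIGRDALINYEGGVELARSFMRVKQKYMEKWWWDNWEPYEKFCCTNRWPKWVNRF
IPCSNVMHYKESGKDNAQQAPDYAHHFDCIHDDTKQFHVLDFPCMWLITEGCEDMSQRYLMIGYQAPRCR
EYHSMILRANQGNWVAKWVEKTKADETSQKPQQAKKYTWQGTWCEDTNHNVYDWGNQDCCIGIIKASPAN
WCDNMKRWRMITGICVDYGWMFQMEEIVYG
>IS1380_10 clade=outgroup synthetic outgroup stand-in
MYHYISVCDYFPRVAGNSHYEGANLGFAWPEHITLYPKERWYLYERNSMPQDCKNKKPLWMRSMWFKQVH
KICWTTTRTKRQGMHTVIFFIGKHYSFYTIMKHMSHSFLSEDECNFHKYLACMMAGFQLQMRHERWMMDM
KWDRNHFHRINVTGMLTHSCWYQYGVLYPYIGNSTLWPYSHLKKFRIITCDVVVKKCKLMVASVCHVEQV
YWEEFRMSPRKPSVDVQGPDALINYVGGGEDARKFYNVEQPYVESEWSQNWEGYEKTCCTNRKPKWVNRF
NNLSHVMHKFESDKDHAQQEADYAHHFPCIHDDTKQFLVLDFPCMWLITEGIEDMSQRYLMIGYQAPRCR
HAHSNILRANQGNWYARTVEKPYAWMTNQKPQIARKKTWYGTSKEDTNLVVFNRGMQICPQGCITAFPAN
WDDDMGRWLIITGICVDWGRMFSMQEFSYH
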