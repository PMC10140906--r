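>PBcons_A clade=A synthetic clade-consensus stand-in
MEMCQDMGKCFSMGGTWRFSCMMNQALEIWNGLVCQKYVESNRPSQSTKTMFTSDWPLDQCLRVAESSMV
AKQDNKQQQTCTKQYKQKQKCKDLWMRHLLAIMHNMQVDAEGTMVCNCGPMSDWVQQHHQTIPFQLRLIK
YPGHSFNLQRMDVATDCAANAPYWSWMWLSFIPRCRCFYPYHPVRRNGHFMMQRESNFHTKPDIAKGKMP
PWSIAMDNEKSGANNRLCEVGPHQWFHCNVDCIQMQDMYICDGCTKHIVMRHTNPNWDGPDLASCSNGRL
NKYRYVMNWRPDMKIGPLCYIRWMPVTTFFTTHWGYTLQPCNWWVDASEQRWNRLYHDFCPFRITDCHSA
VAYHIVYVTSDYIHMWTYHHWQQAQAFFMDLSCQCWRVLRITDPCYNGGEHEIIWWQFLGSMWKAWFEKK
ARVSWSRCSWLGTYCCRKCMRTWRFTDKRPYLWVCNNWLEMKIVTLTEVVQCDCISLECCDVMKWDVIQD
NMQMHMYPEFSKWDHFKEFPLPMHSYGDREKQFCRHSAHKCDIYYIRCREVDLEFKVCGKNIVFCWCATW
MCHTEYWAVTGCNNLNCYIF
>PBcons_B clade=B synthetic clade-consensus stand-in
MMAVQHSDLFTMNLLPELQPNIASHSMAFYNTYMTNLCTKAAEGDNRVHHTFHCPCVPAFKCVKAMCRSE
SKTWQPTMVQGWRIRNPKNEMHFEACKNGLLRISHGIAMMWWHSSCLYQGPSDWFREVVQLGPHWFMYIT
PPTSANNLHHWVVHTWIDAKPGTWFWMKESFLSLLPDPMFSKHQCRHFHFMQERKWRDQFKHYPCKHDDP
ILLECKWTVKWGKEFKLCKVVAPIENACAPALYCMYFMMSVIGCPFQWGWGKSMCGEDLDDYLSCFNSDS
DKELYCSLTRPMRWIGPLVIERWDPRDTTFTTATHLTCIPSNKWVDASEKRWPRLPPHFKPFTITDQQSE
WAFAIFYETSDLYHSTSVHLRQEASTFTQQFSPYCWRVLRQTDPCYKNKEHEIIWTHFLGSMSQDQCHHD
GRPICSTNSILCTYEPTDIKRTQLHTDAMPSDQMHMKWLPKNDSIHTNMPYSIHCTTANGDPAKIMCNSY
CCFMHEYAEQSHWMEFIVGPFTWHVPSNREGQACDASSPSCTAETIDCTQTEFEFKQCFNVWQHCGQITD
MCPYPMFQYFWCNFENFYII
>PBcons_C clade=C synthetic clade-consensus stand-in
MSAECDKRCSTAMTNCFFFCREKLITPWWHWKYGMEAEWVCWFPDLNKQGNPTGTWFLDWAAYGAWMIAD
RIIPAMTCHTDQAFDQNTSRFQDFIMRKAKNVQYSMIYYNPKMALPEAEPCMCWRWIHHDTILPYYPDIK
YNDHMNVYTRMFMMTDMALSECDFFWLMQSYTKMVRDSMWYYKFNKINTKTMQAHDADQQKSYIVTQDDP
NKSFSMVKKKSIAEGPDMTFQPKWHWWMWYVCVTVKDNQSCTCVPCRMVLDGHMCVDDMDMYVLCAKTDQ
QKYRYAMGARPFIIIGVCCYIRLMHCFETFTINNANTHFPSNWWSDKHYKPWHRYMINYVPFRINDLFSY
FAYDIFYAYSMTYTMANLHDRQRAQAACSNLSPTCWRVSRQTDPCYNGGEHEIIWTQFLGSMLIWGFTNR
ARPTLNTNWGLCGKQCCDDHLTETHTDQQPAWHKPYRWLKLKDSHVAFWRVCAKYWVEIHHKPHTLCNCK
LSQKHYQPDPSDKIYFKEFAMHIRLTSKRGGRWCDIASEKCTICIITCTQHCLEFKRCWYNGQHCKSARK
MCQPHYHKGFWCERLNFYYC
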