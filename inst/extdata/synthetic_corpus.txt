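>syn0001
DDMTKIWSHPPHIWNCQPNNLCYCDV
CCCCCCCCCHHHHHHCTTTTCCHHHC
>syn0002
IEFKWTWREYDLDGREEHLKRIPLQQLDE
CCTTTTTCTTTTCCCTTTCHHHHHHHHCC
>syn0003
TTLKTIAPNFFGKFHPHEVLHLREYNWYNNNKEEQYM
CCCCCCCTTTCEEEEEEEEEEECCEEEEECCCEEEEC
>syn0004
SQKAIQCYVPEWQKSPFCTWKAFNDIQYHMPVWDLSDPHKY
CHHHHHHHHHHHHHHHHHHHHHCCCCCCCCEEEEECCCCCC
>syn0005
TAYWEQIHPSEMMPWQCNKFACAEFWMPPADASAPGK
CEEEECCCEEEECCCCCTTTCCEEEECHHHHHCCCCC
>syn0006
CCAYMQISGWMRDKQDDDLHKDYQKPGNSVRVR
CCEEECHHHHCHHHHHHHHHHHHCCCCHHHHHC
>syn0007
DTRDSHANYGEVQVAIRFTNLRPTHH
CCTTTCCHHHHCCCCCCTTTTCCCCC
>syn0008
NYWLEQTFEGDTDPECFAQIWHHMQTNGVKHYGCA
CCTTTTTCCCCHHHHHCHHHHHHHHCCCEEEEEEC
>syn0009
SCYSGEMQFCRKWYRTFAYNWRFDTKPCTMFRDQQDTKCN
CCHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHCCCCC
>syn0010
VYEMHHHINRVCMPHIDECLIESPLAELGASIKQDIHK
CEEEEEEECTTTCCCCCEEECCCHHHHHCCTTTTCCCC
>syn0011
FKDYYKRRVLCATENCLWVHFCFGKR
CHHHHHHHHHHHCCEEEEEEEEEEEC
>syn0012
RRAEHQACEMSDCMNCFLAFMSFKKEKCKRLKIVKH
CTTTCCCCTTTCCTTTTTCEEECCCCCCCCCCCCCC
>syn0013
ADVTYLEAYMVTATETQQDETEWWHELHMRLDWVASHKAIGL
CCCTTTTCEEECCCCCHHHHHCHHHHHHCCCCCTTTTTCCCC
>syn0014
WIKAMGENKHNVCTKDTFYRRFKTMFKTRYHINRWGLDEWMWRGQ
CCCHHHHCCCTTTTCCHHHCCEEECEEEEEEECCCCCCCCCCCCC
>syn0015
THPQCNELSMKARFCHNIYPKIHPA
CCTTTCCEEEECCTTTCCCCCCCCC
>syn0016
FNCKLYHHRLVGEIWGKCCCVIIEKPCPYFHSTVF
CCEEEEEEEECTTTCCCCCTTTCCCCCHHHHHHHC
>syn0017
RHGNPDDDPWYCHGVTTQKFKAKYDRK
CHHHHCCCCCHHHHHHHCCCEEEEECC
>syn0018
DQHPMFFKAGVRHGPKFCAWFQLNELDDQKNSA
CCCCTTTCEEEEEEEECCCCCCCEEECCCEEEC
>syn0019
NRYCWQRPTGGEQWLGRDYCDWLLTVDYVTYWCAEDTR
CCHHHCCCHHHHHHHHHHHHHHHHHHHHHHHHHCTTTC
>syn0020
LSARHTNWWWCVCFDCIETPNVHQYAVLMVDTTFATCWQPD
CTTTTCCCCCCCCCHHHHHHHHHHHHHHHHHHHHCCCCCCC
>syn0021
FNHDYIAYFRAPCCVRFPHNIYFTREHKNPSLQVARPFVH
CCCEEEEEECCHHHHHHHHHHHHHCTTTCTTTTTCCCCCC
>syn0022
FHNQFSDYPEITYHHNIANDNDNFCCSWQREKLKTDHLYCCSVQ
CEEEEECHHHHCCCCTTTTCCCHHHHHHHCCCTTTCCCHHHHCC
>syn0023
THEVCPKWIVEDCAHDIELSPYDNEMYCCDGTRQYYKCQYNFLI
CEEECCCCCEEEEEEEEEECCHHHHCCCCEEECTTTTTCEEECC
>syn0024
VKPYLVQKHMVFLRNIGEGHWVRTNDIQMRYVAGA
CTTTTCCCCCTTTCEEEEEECCCHHHHHHHHHHHC
>syn0025
TYCNEWVLCRDRGHKIDLECEHCDEDCDFWMYSMGCFHGNFPVF
CHHHHHHHHHCCCCCHHHHHHHCCTTTCCCCEEEEECEEEEEEC
>syn0026
TPQQNWMDMYQDVSVKDTQLRNLEKKYHWRYCWREPKILGSCSS
CCCHHHHHHHHHHHHHHHHHHHHHCHHHHHHHHCCEEEEEEEEC
>syn0027
WRWGDYKAVDNSYHHYDCPIFRDDVVVRTHDKGW
CEEEEEEECEEEEEEEEEEEECCHHHHHHHCCCC
>syn0028
EEHNLDVKDFDFHCMWNKMLLWLNDFDF
CCEEEECCHHHHHHHCCEEEEECCEEEC
>syn0029
TCPWTNDKSVFQEIDYWFPTFVMLGFHSYDR
CCEEECTTTCHHHHCCCCCCEEEEEEEEECC
>syn0030
SPQNHWQFHHDSQANPQVTHQLDPHCGWTYACVQLWKDAVDLRA
CCHHHHHHHHHHHCCCTTTTTCCCCCCCCHHHHHHHHHHHHHHC
>syn0031
TIILWDEPCHKDKHDQAKGYSFNPYDYLTDDWRSPHVYSDPQHWH
CCCCCEEEEEEEEECCCCTTTCCHHHHHHCCCCCCCHHHCHHHHC
>syn0032
NPWIVPQMLHPDDLRCCLHQDGLSQPQCFYVPCDTWGNHK
CCCCCCTTTTTTCHHHHHHHHHHHHHHHHHHHHHHHCCCC
>syn0033
DETEKDFIAVKDRYAKKQLFTHTYMFQDAYWILWQKYLVTMCVA
CCCEEEECEEECCHHHHHHHHHHHHCCEEECTTTTTTTTCHHHC
>syn0034
MYVKHNNLAPTVHTSWNSSIRGWDHGR
CCCCCHHHHHHHHHHCCTTTCCCTTTC
>syn0035
NDIIVQRLKPWDRSNRHDPQLNNQVH
CCCEEEEEEECTTTCCCCTTTTCCCC
>syn0036
DVKGGHYCSLATFLDQADWRYQFQGDTSVVFHSQLKNFCDN
CCCHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHHC
>syn0037
NHCPHPWLHYYRGCGSSHVYQIQKAAMNQWACFEHHHVTAS
CCHHHHHCTTTCCHHHHHHHHCHHHHCCCCHHHHHHHHHHC
>syn0038
IHSDVVRLQQYDTIGHCTQMRFARTWW
CCHHHHHHHHHHCHHHHHHHCCEEEEC
>syn0039
DYWRMDIWPFLHGCPKLYLDGDDTH
CCCTTTCCCHHHCCCCEEEEECCCC
>syn0040
SLIGCHLQEITEKTQPKSAEKWASMHAGEQ
CCCCCCCCTTTCCCCCHHHHHHHCCCHHHC
>syn0041
DPFMADTTKNLQPASEHAVLVLMGGPYGWWLWGTMEWDMEEQSD
CCHHHHHHCCCCHHHHHHHHHHHHCCCCCCTTTTCCCEEEEECC
>syn0042
PVYMLIDWIPANTMYMFVMCMFPDIADEVWYVD
CCEEECCCCCEEEEEECTTTCCTTTCCEEEECC
>syn0043
DDFLQACNANLGFCYFNKDRKYWIALPPLEIHPKIKSDE
CCTTTTCTTTTCCTTTCCCCCEEEECCEEEEEEEEEEEC
>syn0044
FDCQWKVETDWMIEHRRTDVRCECHSGRQGNCMEDPY
CEEEEEEECCCCCTTTCTTTCCEEEECCCHHHCCCCC
>syn0045
EDMGIFQVIIWSREADEYWVQKLLLDYLTSYRSCELWIKH
CHHHCCTTTTTCCHHHHHHHHHHHHHHHHHHHHCCCCCCC
>syn0046
WEKAGTFMLAKWQQKFLVIQQPADEHVPLQAHIFG
CCTTTCEEECCCTTTTTCCCCCHHHHHHHHHHCCC
>syn0047
MHEVFMEANDQSDAHHTTTNYRFNHWTFECFLLYHDGIENFCIVS
CCTTTCCTTTTTTCCCTTTTTCHHHHHHCCCCEEEEECCHHHHHC
>syn0048
DYMHPAVYAGCHWCNWWREWLNGMWW
CCCCHHHHHCCCHHHHHCEEECCCCC
>syn0049
DQEHSHYDFKFICFKPKRYKMYSQYGALDLDMEWSLYPEIQ
CEEECCEEEEEEECCCCEEECEEEEEEEECCEEEEEEEECC
>syn0050
FYLKANCLKYVVYTVKLKTVKMYVIIGTSHQQGGTSDEFKVDI
CHHHHHHHHHHHHHHHHHHHHCEEEEEEEECTTTTCEEEECCC
>syn0051
FEVRGKDNRVPRGVEKTDMAVDDKRLLKHHDEFILC
CCEEEECCCCCHHHHHCCCEEEEEEEEEEECCCCCC
>syn0052
QTVFYHDMTGEQLCQENDIENRACDFRKA
CEEEEEECTTTTTTTCHHHHCCEEECCCC
>syn0053
TPFAGTDKPNYPEKFKPCCIDSLMKFWPDWHNKLPDFYVS
CCTTTTCCCEEEEECCHHHHHHCCCCCCEEEEECHHHHHC
>syn0054
VCIKKATHSDEYVRFGQWSKMNIHAHVDKT
CCEEECTTTCTTTCEEEEEEEEEEEECCCC
>syn0055
FNGMQPCCVKNKAGVTLRFLEVQGFEH
CCCCCCCCCHHHHHHHHHHHHHHHCCC
>syn0056
FWWPNPPVSTDLHSLLTCLMQKSHD
CCHHHHHHHCHHHHHHHHHCCCCCC
>syn0057
NFQWYSQWNESLVPVYNYLWDAVAQQKMELVDYVP
CTTTTCHHHHHHHHHHHHHHHHHHCCCHHHHHHCC
>syn0058
LHYLWRCHYKQESLQHHIFCNLGVYPELLILCQFMKDKHHHWI
CTTTTCCTTTCCCCCCTTTTCEEEECCCEEEECEEEEECCCCC
>syn0059
RHKYNNRSLKYYFTHQYLYANRAVYMVQECDCK
CCCHHHHHHHHHHHHHHHHHHHHHHHHHHHCCC
>syn0060
SMMFEMSTEQVMMAEGYEHQATLSDQV
CHHHHHHHCCTTTCHHHHHHHHHHHHC
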