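>ref_I_1
MANTELVLVDPNNHRVQEEAYFEFTQQYQPACYGTFQAKKTDLGGDFGQAFRRILDEAFI
SSCWDFTIHGLWPDNRITDNVQQVCQNALPHEHVQQEAETYTIICWPDLTKSRHDWAYLR
SATFNGEQKEAASAKPNLSAICSAVFWPIKHGTCSQFYLVKSSDEQDDTSTKELDERHRT
HEHLPGRTWGSFPNLTAWCYRGRVYSEDIEPMNPDLCLFA
>ref_I_2
MANTELVLVDPNNHRVQEKAYFEFTQQYQPACYGTFQAEKTELGGDFGQAFERILKEAFI
SSCWDFTIHGLWPDNRITDNVQQVCQNALPHEHVQQEAETYTIICWPDLTKSRHDWAYLD
SATFNGEQKEAASAKPNLSAICSAVFWPIKHGTCSQFYLVESSDEQDRTSTEELDRRHRT
HEHLPGETWGSFPNLTAWCYRGRVYSEDIEPMNPDLCLFA
>ref_I_3
MANTELVLVDPNNHRVQEKAYFEFTQQYQPACYGTFQAKKTKLGGDFGQAFRRILKEAFI
SSCWDFTIHGLWPDNDITDNVQQVCQNALPHEHVQQEAETYTIICWPDLTKSRHDWAYLR
SATFNGEQKEAASAKPNLSAICSAVFWPIKHGTCSQFYLVKSSDEQDRTSTEELDRDHRT
HEHLPGRTWGSFPNLTAWCYRGDVYSEDIRPMNPDLCLFA
>ref_II_1
MTLGKIGERTAEENAGVTTGYFQFTQQYQPACDPTEKRKYQKGMQLRQRFDTFQEQLIFT
LVCWNFTIHGLWPDNTTAEPCVYPQGGGSPKGNSGVNTAGRGMDCWPDLTSSRHDWRTNE
PVTSMDSVVAEGGQFRDMWENAIPDVWEIKHGSCCQFYVTTRQPVQEDQAKDEKSVKGSL
RQFVGEIDWGAFPNLTSWCYRVRIETSAATANRTRNQPKL
>ref_II_2
MTLGKIGERTAEENAGVTTGYFQFTQQYQPACDPTEKRKYQKGMQLRQRFDTFQEQLIFT
LVCWNFTIHGLWPDNTTAEPCVYPQGGGSPKGNSGVNTAGEGMDCWPDLTSSRHDWRTNE
PVTSMDSVVAEGGQFRDMWENAIPDVWEIKHGSCCQFYVTTRQPVQEDQAKDEKSVKGSL
RQFVGEIDWGAFPNLTSWCYRVRIETSAATANRTRNQPKL
>ref_II_3
MTLGKIGERTAEENAGVTTGYFQFTQQYQPACDPTEKRKYQKGMQLRQRFDTFQEQLIFT
LVCWNFTIHGLWPDNTTAEPCVYPQGGGSPKGNSGVNTAGEGMDCWPDLTSSRHDWRTNE
PVTSMDSVVAEGGQFRDMWENAIPDVWEIKHGSCCQFYVTTRQPVQEDQAKKEKSVKGSL
RQFVGEIDWGAFPNLTSWCYRVRIETSAATANRTRNQPKL
>ref_III_1
MQVITMRREEFPSAEGKENTYFEFTQQYQPACTQKQVQSEKGAIELRLRNQNLTKGIEGI
KDCWDFTIHGLWPDSKWTIVEYGIDLIMKNSWQKNDGTRRHLNCCWPDLTSSRHDWRKIL
TSEQPAAYPASEVVEAVRPGMAKLPGWPIKHGTCSQFYFNFQKEARRVNLGMLRHPNVTQ
IKVSPVCVWGAFPNLTSWCYQPLENSGNQQNPCKAILQSQ
>ref_III_2
MQVITMDRREFPSAKGKRNTYFEFTQQYQPACTQRQVQSEKGAIRLRLRNQNLTRGIRGI
KDCWDFTIHGLWPDSKWTIVEYGIDLIMKNSWQKNDGTRRHLNCCWPDLTSSRHDWRKIL
TSEQPAAYPASEVVEAVRPGMAKLPGWPIKHGTCSQFYFNFQKEADRVNLGMLRHPNVTQ
IDVSPVCVWGAFPNLTSWCYQPLENSGNQQNPCEAILQSQ
>ref_III_3
MQVITMKREEFPSAEGKRNTYFEFTQQYQPACTQEQVQSEKGAIELRLRNQNLTDGIKGI
KDCWDFTIHGLWPDSKWTIVEYGIDLIMKNSWQKNKGTRRHLNCCWPDLTSSRHDWRKIL
TSEQPAAYPASEVVEAVRPGMAKLPGWPIKHGTCSQFYFNFQKEADRVNLGMLRHPNVTQ
IRVSPVCVWGAFPNLTSWCYQPLENSGNQQNPCEAILQSQ
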